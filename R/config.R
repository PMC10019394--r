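## Configuration file handling, run manifests and the programmatic entry
## points behind the command-line wrappers (inst/scripts/gcsim.R).

#' Load / write a simulation configuration as YAML
#'
#' The YAML mirrors [gcConfig()]: scalar entries at the top level plus
#' optional `shape`, `grn` and `fate_tree` blocks. Unknown keys are
#' rejected with the offending field named. Loading an incomplete file
#' expands defaults, so `loadConfig(writeConfig(cfg))` equals `cfg`.
#'
#' @param path YAML file path.
#' @return `loadConfig()` returns a `gc_config` list.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  args <- raw
  args$shape <- NULL; args$grn <- NULL; args$fate_tree <- NULL
  args$grnInit <- if (!is.null(raw$grnInit)) unlist(raw$grnInit) else NULL
  args <- args[!vapply(args, is.null, logical(1))]
  if (!is.null(raw$shape)) args$shape <- do.call(shapeSpaceConfig, raw$shape)
  if (!is.null(raw$grn)) args$grn <- do.call(grnParameters, raw$grn)
  if (!is.null(raw$fate_tree)) {
    ft <- raw$fate_tree
    ep <- do.call(rbind, ft$effect_prob[REGION_LEVELS])
    colnames(ep) <- EFFECT_LEVELS
    args$fateTree <- fateTree(
      unlist(ft$region_prob)[REGION_LEVELS],
      unlist(ft$replacement_prob)[REGION_LEVELS], ep)
  }
  tryCatch(do.call(gcConfig, args),
           error = function(e) stop("invalid configuration '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' @rdname loadConfig
#' @param cfg a `gc_config` list.
#' @export
writeConfig <- function(cfg, path) {
  out <- unclass(cfg)
  out$pool <- NULL
  out$shape <- unclass(cfg$shape)
  out$grn <- unclass(cfg$grn)
  ft <- cfg$fateTree
  out$fateTree <- NULL
  out$grnInit <- as.list(cfg$grnInit)
  out$fate_tree <- list(
    region_prob = as.list(ft@regionProb),
    replacement_prob = as.list(ft@replacementProb),
    effect_prob = lapply(setNames(REGION_LEVELS, REGION_LEVELS),
                         function(r) as.numeric(ft@effectProb[r, ])))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run manifest
#'
#' Records what produced a set of output files: the md5 of the expanded
#' configuration, the master seed and derived stream seeds, wall-clock
#' start/end, the package version, and an md5 checksum per output file.
#' Identical configuration + seed yield identical output checksums.
#'
#' @param cfg the expanded `gc_config`.
#' @param seed master seed.
#' @param files character vector of output file paths.
#' @param started,finished POSIXct timestamps.
#' @return manifest list.
#' @export
runManifest <- function(cfg, seed, files, started = Sys.time(),
                        finished = Sys.time()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeConfig(cfg, tmp)
  streams <- rngStreams(seed)
  list(
    config_hash = unname(tools::md5sum(tmp)),
    master_seed = as.integer(seed),
    stream_seeds = lapply(streams, function(s) s$seed),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("gcabm")),
    files = as.list(setNames(unname(tools::md5sum(files)),
                             basename(files))))
}

#' Simulate from a configuration file and write all outputs
#'
#' Runs the full simulation and writes: `time_series.csv`,
#' `output_cells.tsv`, DNA- and RNA-mode clone tables
#' (`clones_dna.tsv`, `clones_rna.tsv`), per-mode statistics
#' (`stats.json`), the sequence-affinity registry (`registry.tsv`), the
#' lineage forest (`lineage/`), the expanded configuration
#' (`config_used.yaml`) and a `manifest.json`.
#'
#' @param configPath optional YAML configuration (defaults used if NULL).
#' @param seed master seed.
#' @param outDir output directory.
#' @param durationOverride,dtOverride optional overrides of the horizon and
#'   step size (all other settings come from the file, keeping manifests
#'   honest).
#' @param pcFactor PC mRNA factor for the RNA-mode outputs.
#' @return the manifest, invisibly.
#' @export
cliSimulate <- function(configPath = NULL, seed = 1L, outDir,
                        durationOverride = NULL, dtOverride = NULL,
                        pcFactor = 100) {
  started <- Sys.time()
  cfg <- if (is.null(configPath)) gcConfig() else loadConfig(configPath)
  if (!is.null(durationOverride)) cfg$duration <- durationOverride
  if (!is.null(dtOverride)) cfg$dt <- dtOverride
  cfg <- do.call(gcConfig, unclass(cfg))   # re-validate after overrides
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  res <- runGC(cfg, seed = seed)

  files <- character(0)
  f <- file.path(outDir, "time_series.csv")
  utils::write.csv(res@timeSeries, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(outDir, "output_cells.tsv")
  write.table(res@outputCells, f, sep = "\t", quote = FALSE,
              row.names = FALSE); files <- c(files, f)
  f <- file.path(outDir, "registry.tsv")
  write.table(res@registry, f, sep = "\t", quote = FALSE,
              row.names = FALSE); files <- c(files, f)

  stats <- list()
  if (nrow(res@cells) + nrow(res@outputCells) > 0) {
    dna <- buildRepertoire(res, "DNA", pcFactor)
    rna <- buildRepertoire(res, "RNA", pcFactor)
    f <- file.path(outDir, "clones_dna.tsv")
    writeCloneTable(dna, f); files <- c(files, f)
    f <- file.path(outDir, "clones_rna.tsv")
    writeCloneTable(rna, f); files <- c(files, f)
    stats <- list(DNA = repertoireStats(dna), RNA = repertoireStats(rna))
  }
  f <- file.path(outDir, "stats.json")
  jsonlite::write_json(stats, f, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, f)

  files <- c(files, exportLineageForest(res, file.path(outDir, "lineage")),
             file.path(outDir, "lineage", "lineage_nodes.tsv"))
  f <- file.path(outDir, "config_used.yaml")
  writeConfig(cfg, f); files <- c(files, f)

  manifest <- runManifest(cfg, seed, files, started, Sys.time())
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Standalone repertoire statistics from a table on disk
#'
#' Accepts either a clone-table TSV (columns `clone_id`, `cb`, `cc`, `mbc`,
#' `pc`) or an AIRR-style rearrangement TSV (columns `v_call`, `j_call`,
#' `junction`/`cdr3`, optional `duplicate_count`), which is first grouped
#' into clones by the V-J / CDR3-length / 85%-identity rule.
#'
#' @param path input TSV.
#' @param mode `"DNA"` or `"RNA"`.
#' @param pcFactor PC mRNA factor used in RNA mode.
#' @param out optional JSON output path.
#' @return the statistics list, invisibly if `out` is given.
#' @export
cliStats <- function(path, mode = c("DNA", "RNA"), pcFactor = 100,
                     out = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- names(read.delim(path, nrows = 1, check.names = FALSE))
  if (length(hdr) == 0) stop("empty input file: ", path)
  if (any(c("v_call") %in% hdr)) {
    rec <- groupClonesAirr(readAirrRearrangements(path))
    rec <- rec[!is.na(rec$clone_id), , drop = FALSE]
    if (nrow(rec) == 0) stop("no groupable records in ", path)
    dup <- if ("duplicate_count" %in% names(rec)) rec$duplicate_count else
      rep(1L, nrow(rec))
    cnt <- tapply(dup, rec$clone_id, sum)
    sub <- data.frame(
      clone_id = names(cnt),
      subclone_id = paste0(names(cnt), ".1"),
      sequence = sprintf("S%04d", seq_along(cnt)),
      cb = as.integer(cnt), cc = 0L, mbc = 0L, pc = 0L,
      affinity = NA_real_, stringsAsFactors = FALSE)
    table <- new("CloneTable", subclones = sub, mode = mode,
                 pcFactor = pcFactor)
  } else {
    table <- readCloneTable(path, mode, pcFactor)
  }
  stats <- repertoireStats(table)
  if (!is.null(out)) {
    jsonlite::write_json(stats, out, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(stats))
  }
  stats
}

#' Deterministic test fixtures
#'
#' Writes a synthetic germline pool (FASTA + annotation TSV), a toy clone
#' table and a toy AIRR rearrangement TSV under `dir`, all derived from one
#' seed, so repeated calls are byte-identical.
#'
#' @param dir output directory.
#' @param poolSize number of germline sequences.
#' @param seed integer seed.
#' @return named character vector of the file paths, invisibly.
#' @export
cliFixtures <- function(dir, poolSize = 20, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- generateGermlinePool(poolSize, seed = seed)
  fa <- file.path(dir, "germline_pool.fasta")
  tsv <- file.path(dir, "germline_pool.tsv")
  writeGermlinePool(pool, fa, tsv)

  rng <- newRngStream(seed + 104729L)
  counts <- withStream(rng, {
    nClone <- 6L
    data.frame(
      clone_id = as.character(rep(seq_len(nClone), each = 2L)),
      cb = rpois(2L * nClone, 8), cc = rpois(2L * nClone, 5),
      mbc = rpois(2L * nClone, 1), pc = rpois(2L * nClone, 1),
      stringsAsFactors = FALSE)
  })
  counts$cb <- counts$cb + 1L   # no all-zero subclones
  counts$sequence <- sprintf("TOY%03d", seq_len(nrow(counts)))
  counts$subclone_id <- paste(counts$clone_id,
                              stats::ave(seq_len(nrow(counts)),
                                         counts$clone_id, FUN = seq_along),
                              sep = ".")
  counts$affinity <- round(withStream(rng, runif(nrow(counts))), 3)
  ct <- new("CloneTable",
            subclones = counts[, c("clone_id", "subclone_id", "sequence",
                                   "cb", "cc", "mbc", "pc", "affinity")],
            mode = "DNA", pcFactor = 100)
  toy <- file.path(dir, "toy_clone_table.tsv")
  writeCloneTable(ct, toy)

  cdr3 <- withStream(rng, {
    base <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                  collapse = "")
    vapply(1:12, function(i) {
      s <- base
      k <- sample(0:4, 1)
      if (k > 0) {
        pos <- sample(21, k)
        for (p in pos) substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }, character(1))
  })
  airr <- data.frame(
    sequence_id = sprintf("seq%02d", 1:12),
    v_call = rep(c("IGHV3-23", "IGHV1-2"), each = 6),
    j_call = "IGHJ4",
    junction = cdr3,
    duplicate_count = 1L, stringsAsFactors = FALSE)
  airrPath <- file.path(dir, "toy_airr.tsv")
  write.table(airr, airrPath, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(fasta = fa, annotation = tsv, clone_table = toy,
              airr = airrPath))
}
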