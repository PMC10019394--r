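## Clone/subclone tables, DNA- vs RNA-based repertoires, dominance calls,
## diversity statistics, and lightweight AIRR-style clonal grouping.

#' Build a clone/subclone table from simulated cells
#'
#' A subclone is the set of cells carrying an identical BcR nucleotide
#' sequence; a clone is all subclones descending from one founder. DNA mode
#' counts every cell once (each BcR represents a single cell); RNA mode
#' counts each plasma cell `pcFactor` times (default 100), emulating the
#' elevated BcR mRNA content of PCs.
#'
#' @param x a [GCSimResult-class], or a `data.frame` with columns
#'   `clone_id`, `sequence`, `type` (CB/CC/MBC/PC) and `affinity`.
#' @param mode `"DNA"` or `"RNA"`.
#' @param pcFactor PC mRNA inflation factor (>= 1).
#' @return a [CloneTable-class].
#' @examples
#' cells <- data.frame(clone_id = 1, sequence = "AAA",
#'                     type = c("CB", "CB", "PC"), affinity = 0.5)
#' sum(cloneCounts(buildRepertoire(cells, "DNA")))   # 3
#' sum(cloneCounts(buildRepertoire(cells, "RNA")))   # 102
#' @export
buildRepertoire <- function(x, mode = c("DNA", "RNA"), pcFactor = 100) {
  mode <- match.arg(mode)
  stopifnot(pcFactor >= 1)
  if (is(x, "GCSimResult")) {
    live <- x@cells
    cells <- data.frame(clone_id = live$clone_id, sequence = live$sequence,
                        type = live$state, affinity = live$affinity,
                        stringsAsFactors = FALSE)
    cells$type[cells$type %in% c("CC", "selCC")] <- "CC"
    if (nrow(x@outputCells)) {
      oc <- x@outputCells
      cells <- rbind(cells, data.frame(
        clone_id = oc$clone_id, sequence = oc$sequence, type = oc$type,
        affinity = oc$affinity, stringsAsFactors = FALSE))
    }
  } else {
    cells <- x
  }
  need <- c("clone_id", "sequence", "type", "affinity")
  if (!all(need %in% names(cells)))
    stop("cells need columns ", paste(need, collapse = ", "))
  if (anyNA(cells$clone_id) || anyNA(cells$sequence))
    stop("cells with missing clone id or sequence")
  if (!all(cells$type %in% c("CB", "CC", "MBC", "PC")))
    stop("cell type must be CB, CC, MBC or PC")

  key <- paste(cells$clone_id, cells$sequence, sep = "\r")
  tab <- table(key, factor(cells$type, levels = c("CB", "CC", "MBC", "PC")))
  ks <- strsplit(rownames(tab), "\r", fixed = TRUE)
  sub <- data.frame(
    clone_id = vapply(ks, `[`, character(1), 1L),
    sequence = vapply(ks, `[`, character(1), 2L),
    cb = as.integer(tab[, "CB"]), cc = as.integer(tab[, "CC"]),
    mbc = as.integer(tab[, "MBC"]), pc = as.integer(tab[, "PC"]),
    stringsAsFactors = FALSE)
  aff <- tapply(cells$affinity, key, function(a) a[1L])
  sub$affinity <- as.numeric(aff[rownames(tab)])
  sub <- sub[order(sub$clone_id, -(sub$cb + sub$cc + sub$mbc + sub$pc)), ]
  sub$subclone_id <- stats::ave(seq_len(nrow(sub)), sub$clone_id,
                                FUN = seq_along)
  sub$subclone_id <- paste(sub$clone_id, sub$subclone_id, sep = ".")
  rownames(sub) <- NULL
  new("CloneTable",
      subclones = sub[, c("clone_id", "subclone_id", "sequence", "cb", "cc",
                          "mbc", "pc", "affinity")],
      mode = mode, pcFactor = pcFactor)
}

#' Per-subclone and per-clone abundances of a CloneTable
#'
#' `subcloneCounts()` returns one abundance per subclone in the table's
#' counting mode; `cloneCounts()` sums them per clone (the frequency of a
#' clone is the sum of the frequencies of its subclones).
#'
#' @param table a [CloneTable-class].
#' @return named numeric vector.
#' @export
subcloneCounts <- function(table) {
  s <- table@subclones
  dna <- s$cb + s$cc + s$mbc + s$pc
  cnt <- if (table@mode == "RNA") dna + (table@pcFactor - 1) * s$pc else dna
  setNames(cnt, s$subclone_id)
}

#' @rdname subcloneCounts
#' @export
cloneCounts <- function(table) {
  s <- table@subclones
  cnt <- subcloneCounts(table)
  out <- tapply(cnt, s$clone_id, sum)
  setNames(as.numeric(out), names(out))
}

#' Dominant-clone calls
#'
#' Two conventions: `"percentile75"` flags clones whose abundance is at or
#' above the 75th percentile of clone abundances (linear-interpolation
#' percentile, ties included); `"frac0.5pct"` flags clones holding at least
#' 0.5% of all sequences.
#'
#' @param table a [CloneTable-class].
#' @param method dominance convention.
#' @return character vector of dominant clone ids.
#' @examples
#' # counts 600,300,90,6,3,1: the 0.5% threshold (5) admits four clones
#' @export
dominantClones <- function(table, method = c("percentile75", "frac0.5pct")) {
  method <- match.arg(method)
  cnt <- cloneCounts(table)
  if (length(cnt) == 0L) stop("empty clone table")
  thr <- switch(method,
    percentile75 = quantile(cnt, 0.75, type = 7, names = FALSE),
    frac0.5pct = 0.005 * sum(cnt))
  names(cnt)[cnt >= thr]
}

#' D50 clonal diversity
#'
#' The fraction of clones that account for 50% of the BcR sequences: sort
#' clone abundances in decreasing order, take the smallest prefix whose sum
#' reaches at least half the total, and divide its length by the number of
#' clones.
#'
#' @param table a [CloneTable-class].
#' @return fraction in (0, 1].
#' @export
d50 <- function(table) {
  cnt <- sort(cloneCounts(table), decreasing = TRUE)
  if (length(cnt) == 0L) stop("empty clone table")
  k <- which(cumsum(cnt) >= 0.5 * sum(cnt))[1L]
  unname(k / length(cnt))
}

#' Berger-Parker dominance
#'
#' The fraction of cells (sequences) belonging to the single most abundant
#' clone.
#'
#' @param table a [CloneTable-class].
#' @return fraction in (0, 1].
#' @export
bergerParker <- function(table) {
  cnt <- cloneCounts(table)
  if (length(cnt) == 0L) stop("empty clone table")
  max(cnt) / sum(cnt)
}

#' Pielou's evenness of clone sizes
#'
#' Normalised Shannon entropy `H' / ln(S)` over clone proportions: 0 for no
#' evenness, 1 for completely even clone sizes. Undefined (NA) for a single
#' clone, where the normalisation is 0/0.
#'
#' @param table a [CloneTable-class].
#' @return value in `[0, 1]`, or `NA` for a single clone.
#' @export
pielouEvenness <- function(table) {
  cnt <- cloneCounts(table)
  if (length(cnt) == 0L) stop("empty clone table")
  if (length(cnt) == 1L) return(NA_real_)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(cnt))
}

#' Chao1 richness estimator
#'
#' Classic Chao1 from singleton (F1) and doubleton (F2) species counts:
#' `S_obs + F1^2 / (2 F2)`, falling back to the bias-corrected form
#' `S_obs + F1 (F1 - 1) / 2` when no doubletons are present. Always at
#' least `S_obs`.
#'
#' @param counts non-negative species (clone) counts.
#' @return estimated richness.
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), 5, 9, 10, 12))  # S_obs 10, F1 4, F2 2 -> 14
#' @export
chao1 <- function(counts) {
  stopifnot(all(counts >= 0))
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all-zero abundance vector")
  sObs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) sObs + f1^2 / (2 * f2) else sObs + f1 * (f1 - 1) / 2
}

#' Median affinity of a clone
#'
#' DNA mode takes the median over one affinity per cell. RNA mode weights
#' each plasma cell's affinity by the PC mRNA factor, so PC-rich subclones
#' pull the median (weighted median; at an exact half-split the two
#' straddling values are averaged).
#'
#' @param table a [CloneTable-class].
#' @param cloneId clone identifier.
#' @param mode counting mode (defaults to the table's).
#' @return median affinity.
#' @export
medianCloneAffinity <- function(table, cloneId, mode = table@mode) {
  s <- table@subclones[table@subclones$clone_id == cloneId, , drop = FALSE]
  if (nrow(s) == 0L) stop("empty clone: ", cloneId)
  pcw <- if (mode == "RNA") table@pcFactor else 1
  w <- (s$cb + s$cc + s$mbc) + pcw * s$pc
  .weightedMedian(s$affinity, w)
}

.weightedMedian <- function(x, w) {
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1L]
  if (abs(cw[i] - half) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2
  else x[i]
}

#' One-call repertoire statistics report
#'
#' @param table a [CloneTable-class].
#' @return list with the clone count, dominant-clone counts under both
#'   conventions, D50, Berger-Parker, Pielou evenness and Chao1.
#' @export
repertoireStats <- function(table) {
  cnt <- cloneCounts(table)
  list(
    mode = table@mode,
    pc_factor = table@pcFactor,
    clones = length(cnt),
    dominant_percentile75 = length(dominantClones(table, "percentile75")),
    dominant_frac0.5pct = length(dominantClones(table, "frac0.5pct")),
    d50 = d50(table),
    berger_parker = bergerParker(table),
    pielou = pielouEvenness(table),
    chao1 = chao1(cnt))
}

#' Write / read a clone table as TSV
#'
#' Columns: `clone_id`, `subclone_id`, `sequence`, `cb`, `cc`, `mbc`, `pc`,
#' `dna_count`, `rna_count`, `affinity`.
#'
#' @param table a [CloneTable-class].
#' @param path file path.
#' @export
writeCloneTable <- function(table, path) {
  s <- table@subclones
  s$dna_count <- s$cb + s$cc + s$mbc + s$pc
  s$rna_count <- s$dna_count + (table@pcFactor - 1) * s$pc
  write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCloneTable
#' @param mode,pcFactor counting mode of the reconstructed table.
#' @export
readCloneTable <- function(path, mode = c("DNA", "RNA"), pcFactor = 100) {
  mode <- match.arg(mode)
  s <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "cb", "cc", "mbc", "pc")
  if (!all(need %in% names(s)))
    stop("clone table must have columns ", paste(need, collapse = ", "))
  if (!"sequence" %in% names(s)) s$sequence <- sprintf("S%06d", seq_len(nrow(s)))
  if (!"subclone_id" %in% names(s))
    s$subclone_id <- paste(s$clone_id, stats::ave(seq_len(nrow(s)),
                           s$clone_id, FUN = seq_along), sep = ".")
  if (!"affinity" %in% names(s)) s$affinity <- NA_real_
  s$clone_id <- as.character(s$clone_id)
  new("CloneTable",
      subclones = s[, c("clone_id", "subclone_id", "sequence", "cb", "cc",
                        "mbc", "pc", "affinity")],
      mode = mode, pcFactor = pcFactor)
}

#' Group AIRR rearrangement records into clones
#'
#' The standard lightweight clonal-grouping rule for heavy-chain
#' rearrangements: stratify by V gene, J gene and CDR3 length, then
#' single-linkage cluster records whose CDR3 nucleotide identity (Hamming,
#' same length) is at least `threshold` (default 85%).
#'
#' @param records `data.frame` with columns `v_call`, `j_call` and
#'   `junction` (or `cdr3`).
#' @param threshold minimum CDR3 identity to merge.
#' @return the records with a `clone_id` column added; records missing a
#'   required field are skipped (NA clone) with a warning.
#' @export
groupClonesAirr <- function(records, threshold = 0.85) {
  cdr3col <- if ("junction" %in% names(records)) "junction" else "cdr3"
  if (!all(c("v_call", "j_call", cdr3col) %in% names(records)))
    stop("records need v_call, j_call and junction/cdr3 columns")
  cdr3 <- toupper(records[[cdr3col]])
  ok <- !is.na(records$v_call) & !is.na(records$j_call) & !is.na(cdr3) &
    records$v_call != "" & records$j_call != "" & cdr3 != ""
  if (any(!ok))
    warning(sum(!ok), " record(s) skipped: missing v_call/j_call/CDR3")
  records$clone_id <- NA_character_
  strata <- paste(records$v_call, records$j_call, nchar(cdr3), sep = "|")
  cloneNum <- 0L
  for (st in unique(strata[ok])) {
    idx <- which(ok & strata == st)
    memb <- .singleLinkageIdentity(cdr3[idx], threshold)
    records$clone_id[idx] <- sprintf("clone_%04d", cloneNum + memb)
    cloneNum <- cloneNum + max(memb)
  }
  records
}

## single-linkage clusters of same-length sequences at >= threshold
## Hamming identity; components via igraph
.singleLinkageIdentity <- function(seqs, threshold) {
  g <- length(seqs)
  if (g == 1L) return(1L)
  m <- do.call(rbind, strsplit(seqs, ""))
  len <- ncol(m)
  edges <- integer(0)
  for (i in seq_len(g - 1L)) {
    same <- colSums(t(m[(i + 1L):g, , drop = FALSE]) == m[i, ])
    hits <- which(same / len >= threshold)
    if (length(hits))
      edges <- c(edges, rbind(i, hits + i))
  }
  gr <- igraph::make_empty_graph(n = g, directed = FALSE)
  if (length(edges))
    gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  as.integer(match(comp, unique(comp)))
}

#' Read an AIRR-style rearrangement TSV
#'
#' @param path TSV path with at least `sequence_id`, `v_call`, `j_call` and
#'   `junction` (or `cdr3`) columns.
#' @return `data.frame` of records.
#' @export
readAirrRearrangements <- function(path) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  if (!any(c("junction", "cdr3") %in% names(rec)))
    stop("no junction/cdr3 column in ", path)
  rec
}
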