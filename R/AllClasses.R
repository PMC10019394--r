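#' @import methods
#' @importFrom Biostrings DNAStringSet width
#' @importFrom stats rnorm runif rpois median quantile setNames
#' @importFrom utils read.delim write.table head tail
NULL

## Canonical ordering of the seven IgH regions, FWR1 -> FWR4.
REGION_LEVELS <- c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3", "FWR4")

EFFECT_LEVELS <- c("affinity", "lethal", "neutral")

#' GermlinePool: annotated germline IgH V-CDR3-J sequences
#'
#' Container for the pool of germline immunoglobulin heavy-chain sequences
#' that seed founder B cells. Each sequence carries an annotation of the four
#' framework regions (FWR1-4) and three complementarity-determining regions
#' (CDR1-3) as 0-based half-open nucleotide intervals that tile the full
#' sequence, plus synthetic V- and J-gene labels. Founder draws are without
#' replacement; the draw state lives in the `drawn` environment so a pool
#' instance never returns the same sequence twice.
#'
#' @slot sequences a [Biostrings::DNAStringSet] named by sequence identifier.
#' @slot regions `data.frame` with columns `sequence_id`, `region`, `start`,
#'   `end` (0-based half-open).
#' @slot frame named integer vector of reading-frame offsets (0-2).
#' @slot vCall,jCall named character vectors of gene labels.
#' @slot drawn environment holding the without-replacement draw state.
#' @export
setClass("GermlinePool",
  slots = c(
    sequences = "DNAStringSet",
    regions   = "data.frame",
    frame     = "integer",
    vCall     = "character",
    jCall     = "character",
    drawn     = "environment"
  )
)

setValidity("GermlinePool", function(object) {
  ids <- names(object@sequences)
  if (length(ids) == 0L) return("pool must contain at least one sequence")
  if (anyDuplicated(ids)) return("sequence identifiers must be unique")
  chars <- unique(unlist(strsplit(as.character(object@sequences), "")))
  if (!all(chars %in% c("A", "C", "G", "T")))
    return("sequences must use only A, C, G, T")
  need <- c("sequence_id", "region", "start", "end")
  if (!all(need %in% names(object@regions)))
    return("regions must have columns sequence_id, region, start, end")
  for (id in ids) {
    ann <- object@regions[object@regions$sequence_id == id, , drop = FALSE]
    len <- width(object@sequences)[match(id, ids)]
    msg <- .checkRegionAnnotation(ann, len, object@frame[[id]], id)
    if (!is.null(msg)) return(msg)
  }
  if (!all(ids %in% names(object@vCall)) || !all(ids %in% names(object@jCall)))
    return("every sequence needs a v_call and j_call")
  TRUE
})

## RegionAnnotation invariants: ordered FWR1->FWR4, contiguous, non-empty,
## tiling [0, len), and (len - frame) divisible by 3.
.checkRegionAnnotation <- function(ann, len, frame, id = "<sequence>") {
  if (nrow(ann) != 7L)
    return(sprintf("%s: expected 7 region rows, got %d", id, nrow(ann)))
  ord <- match(REGION_LEVELS, ann$region)
  if (anyNA(ord))
    return(sprintf("%s: regions must be exactly FWR1..FWR4, CDR1..CDR3", id))
  ann <- ann[ord, , drop = FALSE]
  if (any(ann$end <= ann$start))
    return(sprintf("%s: empty region interval (%s)", id,
                   ann$region[which(ann$end <= ann$start)[1L]]))
  if (ann$start[1L] != 0L || ann$end[7L] != len)
    return(sprintf("%s: regions do not tile the sequence (len %d)", id, len))
  if (any(ann$start[-1L] != ann$end[-7L]))
    return(sprintf("%s: regions overlap or leave gaps", id))
  if (is.na(frame) || frame < 0L || frame > 2L)
    return(sprintf("%s: frame offset must be 0, 1 or 2", id))
  if ((len - frame) %% 3L != 0L)
    return(sprintf("%s: (length - frame) must be a multiple of 3", id))
  NULL
}

#' FateTree: somatic-hypermutation fate probabilities
#'
#' Three-level categorical tree routing each somatic hypermutation to a
#' region (FWR1-4/CDR1-3), a mutation type (replacement or silent), and, for
#' replacements, an effect (affinity-changing, lethal, neutral). Only CDR
#' replacement mutations may change affinity; lethal (nonsense) outcomes are
#' confined to regions whose effect row gives them mass.
#'
#' @slot regionProb named numeric, P(region), summing to 1.
#' @slot replacementProb named numeric, P(replacement | region); the silent
#'   probability is the complement.
#' @slot effectProb 7 x 3 matrix, P(effect | region, replacement) with
#'   columns `affinity`, `lethal`, `neutral`, rows summing to 1.
#' @export
setClass("FateTree",
  slots = c(
    regionProb      = "numeric",
    replacementProb = "numeric",
    effectProb      = "matrix"
  )
)

setValidity("FateTree", function(object) {
  tol <- 1e-12
  rp <- object@regionProb
  if (!identical(names(rp), REGION_LEVELS))
    return("regionProb must be named FWR1,CDR1,FWR2,CDR2,FWR3,CDR3,FWR4")
  if (any(rp < 0) || abs(sum(rp) - 1) > tol)
    return("region probabilities must be non-negative and sum to 1")
  pr <- object@replacementProb
  if (!identical(names(pr), REGION_LEVELS) || any(pr < 0 | pr > 1))
    return("replacementProb must be per-region probabilities in [0,1]")
  ep <- object@effectProb
  if (!identical(rownames(ep), REGION_LEVELS) ||
      !identical(colnames(ep), EFFECT_LEVELS))
    return("effectProb must be a 7x3 matrix (regions x affinity/lethal/neutral)")
  if (any(ep < 0) || any(abs(rowSums(ep) - 1) > tol))
    return("effect probabilities must be non-negative and each row sum to 1")
  fwr <- grepl("^FWR", REGION_LEVELS)
  if (any(ep[fwr, "affinity"] != 0))
    return("only CDR replacement mutations may change affinity")
  TRUE
})

#' CloneTable: clone/subclone census of a repertoire
#'
#' One row per subclone (cells sharing an identical BcR nucleotide
#' sequence), with counts by cell type and the subclone's registered
#' affinity. The counting mode determines abundances: `"DNA"` counts every
#' cell once; `"RNA"` counts each plasma cell `pcFactor` times, emulating
#' the elevated BcR mRNA content of PCs in RNA-based repertoire sequencing.
#'
#' @slot subclones `data.frame` with columns `clone_id`, `subclone_id`,
#'   `sequence`, `cb`, `cc`, `mbc`, `pc`, `affinity`.
#' @slot mode `"DNA"` or `"RNA"`.
#' @slot pcFactor numeric BcR mRNA inflation factor for plasma cells.
#' @export
setClass("CloneTable",
  slots = c(
    subclones = "data.frame",
    mode      = "character",
    pcFactor  = "numeric"
  )
)

setValidity("CloneTable", function(object) {
  need <- c("clone_id", "subclone_id", "sequence", "cb", "cc", "mbc", "pc",
            "affinity")
  if (!all(need %in% names(object@subclones)))
    return(paste("subclones must have columns", paste(need, collapse = ", ")))
  cnt <- as.matrix(object@subclones[, c("cb", "cc", "mbc", "pc")])
  if (nrow(cnt) > 0 && (any(cnt < 0) || any(rowSums(cnt) == 0)))
    return("subclone counts must be >= 0 and not all zero")
  if (!object@mode %in% c("DNA", "RNA")) return("mode must be DNA or RNA")
  if (object@pcFactor < 1) return("pcFactor must be >= 1")
  TRUE
})

#' GCSimResult: output of a germinal-center simulation
#'
#' @slot config the fully expanded configuration list used for the run.
#' @slot seed integer master seed.
#' @slot timeSeries `data.frame` of population summaries over time.
#' @slot cells `data.frame` of live B cells at the end of the run.
#' @slot outputCells `data.frame` of exported memory B cells and plasma cells.
#' @slot lineage `data.frame` of every cell ever created (id, parent, clone,
#'   birth time, affinity, fate).
#' @slot registry `data.frame` snapshot of the sequence-affinity registry.
#' @slot counters named numeric: cells created, apoptosed, exported.
#' @export
setClass("GCSimResult",
  slots = c(
    config      = "list",
    seed        = "integer",
    timeSeries  = "data.frame",
    cells       = "data.frame",
    outputCells = "data.frame",
    lineage     = "data.frame",
    registry    = "data.frame",
    counters    = "numeric"
  )
)

setMethod("show", "GermlinePool", function(object) {
  n <- length(object@sequences)
  cat(sprintf("GermlinePool with %d sequence%s\n", n, if (n == 1) "" else "s"))
  cat(sprintf("  mean length: %.1f nt, mean CDR3: %.1f nt\n",
              mean(width(object@sequences)),
              mean(with(object@regions, end - start)[
                object@regions$region == "CDR3"])))
  cat(sprintf("  V genes: %d, J genes: %d, drawn: %d\n",
              length(unique(object@vCall)), length(unique(object@jCall)),
              sum(unlist(as.list(object@drawn)))))
})

setMethod("show", "FateTree", function(object) {
  cat("SHM FateTree (region : P(region), P(repl|region), P(affinity|repl))\n")
  for (r in REGION_LEVELS) {
    cat(sprintf("  %-4s : %.3f, %.3f, %.3f\n", r, object@regionProb[[r]],
                object@replacementProb[[r]], object@effectProb[r, "affinity"]))
  }
  cat(sprintf("  P(affinity change per mutation) = %.4f\n",
              affinityChangeProbability(object)))
})

setMethod("show", "CloneTable", function(object) {
  cc <- cloneCounts(object)
  cat(sprintf("CloneTable (%s mode, pcFactor %g): %d clones, %d subclones, %g cells/sequences\n",
              object@mode, object@pcFactor, length(cc),
              nrow(object@subclones), sum(cc)))
})

setMethod("show", "GCSimResult", function(object) {
  cat(sprintf("GCSimResult: %g h simulated (dt = %g h), seed %d\n",
              object@config$duration, object@config$dt, object@seed))
  cat(sprintf("  cells created %d, live %d, exported %d (PC %d / MBC %d), apoptosed %d\n",
              object@counters[["created"]], nrow(object@cells),
              object@counters[["exported"]],
              sum(object@outputCells$type == "PC"),
              sum(object@outputCells$type == "MBC"),
              object@counters[["apoptosed"]]))
  cat(sprintf("  clones live %d, distinct sequences registered %d\n",
              length(unique(object@cells$clone_id)), nrow(object@registry)))
})
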