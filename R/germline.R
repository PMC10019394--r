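## Germline IgH V-CDR3-J pool: synthetic generation, I/O, founder draws and
## codon translation. Coordinates are 0-based half-open throughout.

## Default per-region mean lengths (nt, codon-aligned), chosen so the total
## is ~400 nt and the CDR3 ~48 nt, with the remaining regions at
## IMGT-typical sizes.
.REGION_MEAN_NT <- c(FWR1 = 84, CDR1 = 30, FWR2 = 51, CDR2 = 30,
                     FWR3 = 114, CDR3 = 48, FWR4 = 45)

.V_CATALOGUE <- c("IGHV1-2", "IGHV1-69", "IGHV3-23", "IGHV3-30",
                  "IGHV4-34", "IGHV4-59", "IGHV5-51")
.J_CATALOGUE <- paste0("IGHJ", 1:6)

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.senseCodons <- function() {
  nt <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  setdiff(all3, .STOP_CODONS)
}

#' Generate a synthetic germline IgH sequence pool
#'
#' Builds `n` distinct, annotated heavy-chain V-CDR3-J nucleotide sequences
#' emulating a reconstructed germline pool: seven contiguous regions
#' (FWR1, CDR1, FWR2, CDR2, FWR3, CDR3, FWR4), an in-frame coding sequence
#' free of stop codons, and V/J labels drawn from a small synthetic gene
#' catalogue. Region lengths are codon-aligned draws centred on configurable
#' means (defaults give a mean total of ~400 nt and mean CDR3 of ~48 nt).
#'
#' @param n number of sequences (>= 1).
#' @param meanTotalLength target mean total length in nt.
#' @param meanCdr3Length target mean CDR3 length in nt.
#' @param seed optional integer seed (ignored if `rng` given).
#' @param rng optional [newRngStream()] stream.
#' @return a [GermlinePool-class] object.
#' @examples
#' pool <- generateGermlinePool(10, seed = 1)
#' pool
#' @export
generateGermlinePool <- function(n, meanTotalLength = 402,
                                 meanCdr3Length = 48,
                                 seed = NULL, rng = NULL) {
  stopifnot(n >= 1, meanTotalLength > 0, meanCdr3Length > 0,
            meanCdr3Length < meanTotalLength)
  if (is.null(rng)) rng <- newRngStream(if (is.null(seed)) 760001L else seed)

  meanCodons <- .regionMeanCodons(meanTotalLength, meanCdr3Length)
  minCodons <- sum(pmax(1L, meanCodons - 2L))
  # crude capacity guard: 61 sense codons per codon position
  if (log(n) > minCodons * log(61))
    stop("requested pool size exceeds the distinct-sequence capacity ",
         "at the configured region lengths")

  sense <- .senseCodons()
  seqs <- character(n)
  regions <- vector("list", n)
  vCall <- character(n)
  jCall <- character(n)
  ids <- sprintf("GL%04d", seq_len(n))

  withStream(rng, {
    for (i in seq_len(n)) {
      for (attempt in seq_len(100L)) {
        lens <- 3L * pmax(1L, meanCodons + sample(-2L:2L, 7L, replace = TRUE))
        s <- paste(sample(sense, sum(lens) / 3L, replace = TRUE),
                   collapse = "")
        if (!s %in% seqs[seq_len(i - 1L)]) break
        if (attempt == 100L)
          stop("could not generate ", n, " distinct sequences; ",
               "pool size exceeds capacity at the configured lengths")
      }
      seqs[i] <- s
      ends <- cumsum(lens)
      regions[[i]] <- data.frame(
        sequence_id = ids[i], region = REGION_LEVELS,
        start = c(0L, ends[-7L]), end = ends, stringsAsFactors = FALSE)
      vCall[i] <- sample(.V_CATALOGUE, 1L)
      jCall[i] <- sample(.J_CATALOGUE, 1L)
    }
  })

  newGermlinePool(
    sequences = setNames(DNAStringSet(seqs), ids),
    regions = do.call(rbind, regions),
    frame = setNames(integer(n), ids),
    vCall = setNames(vCall, ids),
    jCall = setNames(jCall, ids))
}

.regionMeanCodons <- function(meanTotalLength, meanCdr3Length) {
  cdr3 <- max(1L, round(meanCdr3Length / 3))
  others <- .REGION_MEAN_NT[setdiff(REGION_LEVELS, "CDR3")]
  scale <- (meanTotalLength - 3 * cdr3) / sum(others)
  codons <- pmax(round(others * scale / 3), 1L)  # pmax keeps arg-1 names
  out <- setNames(integer(7L), REGION_LEVELS)
  out[names(codons)] <- as.integer(codons)
  out[["CDR3"]] <- as.integer(cdr3)
  out
}

#' @rdname GermlinePool-class
#' @param sequences,regions,frame,vCall,jCall see slot documentation.
#' @export
newGermlinePool <- function(sequences, regions, frame, vCall, jCall) {
  drawn <- new.env(parent = emptyenv())
  drawn$flags <- setNames(logical(length(sequences)), names(sequences))
  frame <- setNames(as.integer(frame), names(frame))
  new("GermlinePool", sequences = sequences, regions = regions,
      frame = frame, vCall = vCall, jCall = jCall, drawn = drawn)
}

#' @rdname GermlinePool-class
#' @param pool a `GermlinePool`.
#' @export
poolSize <- function(pool) length(pool@sequences)

#' @rdname GermlinePool-class
#' @export
remainingFounders <- function(pool) sum(!pool@drawn$flags)

#' @rdname GermlinePool-class
#' @export
regionTable <- function(pool) pool@regions

#' Write / read a germline pool
#'
#' The pool is stored as a FASTA file of nucleotide sequences plus a sidecar
#' TSV of region annotations (`sequence_id`, `region`, `start`, `end`,
#' `frame`, `v_call`, `j_call`; 0-based half-open coordinates).
#' `readGermlinePool(writeGermlinePool(pool))` is the identity (draw state
#' excluded).
#'
#' @param pool a [GermlinePool-class].
#' @param fastaPath,annotPath output/input file paths.
#' @return `writeGermlinePool` returns the paths invisibly;
#'   `readGermlinePool` returns a fresh [GermlinePool-class].
#' @export
writeGermlinePool <- function(pool, fastaPath, annotPath) {
  Biostrings::writeXStringSet(pool@sequences, fastaPath)
  ann <- pool@regions
  ids <- ann$sequence_id
  ann$frame <- pool@frame[ids]
  ann$v_call <- pool@vCall[ids]
  ann$j_call <- pool@jCall[ids]
  write.table(ann, annotPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fastaPath, annotation = annotPath))
}

#' @rdname writeGermlinePool
#' @export
readGermlinePool <- function(fastaPath, annotPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- read.delim(annotPath, stringsAsFactors = FALSE)
  need <- c("sequence_id", "region", "start", "end", "frame", "v_call",
            "j_call")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  missing <- setdiff(names(seqs), ann$sequence_id)
  extra <- setdiff(ann$sequence_id, names(seqs))
  if (length(missing) || length(extra))
    stop("FASTA/annotation identifier mismatch: ",
         paste(c(missing, extra), collapse = ", "))
  firstRow <- ann[!duplicated(ann$sequence_id), ]
  pool <- newGermlinePool(
    sequences = seqs,
    regions = ann[, c("sequence_id", "region", "start", "end")],
    frame = setNames(firstRow$frame, firstRow$sequence_id)[names(seqs)],
    vCall = setNames(firstRow$v_call, firstRow$sequence_id)[names(seqs)],
    jCall = setNames(firstRow$j_call, firstRow$sequence_id)[names(seqs)])
  validObject(pool)
  pool
}

#' Draw a founder sequence without replacement
#'
#' Each founder B cell receives a germline sequence drawn uniformly from the
#' sequences of the pool not yet drawn by this pool instance. Once the pool
#' is exhausted the draw fails: simulations must be configured with a pool at
#' least as large as the expected founder count.
#'
#' @param pool a [GermlinePool-class].
#' @param rng optional [newRngStream()] stream (global RNG otherwise).
#' @return a list with elements `id`, `sequence` (character), `regions`
#'   (7-row `data.frame`), `frame`, `v_call`, `j_call`.
#' @export
drawFounderSequence <- function(pool, rng = NULL) {
  left <- names(which(!pool@drawn$flags))
  if (length(left) == 0L)
    stop("germline pool exhausted: no undrawn founder sequences remain")
  pick <- if (is.null(rng)) sample(left, 1L) else
    withStream(rng, sample(left, 1L))
  pool@drawn$flags[[pick]] <- TRUE
  list(id = pick,
       sequence = as.character(pool@sequences[[pick]]),
       regions = pool@regions[pool@regions$sequence_id == pick, ,
                              drop = FALSE],
       frame = pool@frame[[pick]],
       v_call = pool@vCall[[pick]],
       j_call = pool@jCall[[pick]])
}

#' Translate the codon containing a nucleotide position
#'
#' Returns the amino acid encoded by the codon that contains `position`
#' (0-based), for the current sequence and, optionally, after substituting
#' `newNt` at that position. Used to decide whether a candidate substitution
#' is silent (synonymous), a replacement, or nonsense (stop).
#'
#' @param sequence nucleotide string (A/C/G/T).
#' @param frame reading-frame offset (0-2).
#' @param position 0-based nucleotide position.
#' @param newNt optional replacement nucleotide.
#' @return list with `codon`, `aa`, and (if `newNt` given) `codonNew`,
#'   `aaNew`. Stop codons translate to `"*"`.
#' @examples
#' translateCodonWindow("GGT", 0, 2, "C")  # Gly -> Gly, silent
#' @export
translateCodonWindow <- function(sequence, frame, position, newNt = NULL) {
  len <- nchar(sequence)
  if (position < 0 || position >= len)
    stop("position out of range [0, ", len, ")")
  if (position < frame)
    stop("position lies before the reading frame offset")
  codonStart <- frame + 3L * ((position - frame) %/% 3L)
  if (codonStart + 3L > len)
    stop("position falls in an incomplete trailing codon")
  codon <- substr(sequence, codonStart + 1L, codonStart + 3L)
  out <- list(codon = codon, aa = .translate1(codon))
  if (!is.null(newNt)) {
    stopifnot(newNt %in% c("A", "C", "G", "T"))
    idx <- position - codonStart + 1L
    codonNew <- codon
    substr(codonNew, idx, idx) <- newNt
    out$codonNew <- codonNew
    out$aaNew <- .translate1(codonNew)
  }
  out
}

.translate1 <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}
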