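# Fixtures are built in code; nothing is read from disk.

# CloneTable from per-subclone counts (one subclone per clone by default)
makeCloneTable <- function(cb, cc = 0L, mbc = 0L, pc = 0L,
                           clone = as.character(seq_along(cb)),
                           affinity = rep(0.5, length(cb)),
                           mode = "DNA", pcFactor = 100) {
  n <- length(cb)
  if (n == 0L) {
    empty <- data.frame(clone_id = character(), subclone_id = character(),
                        sequence = character(), cb = integer(),
                        cc = integer(), mbc = integer(), pc = integer(),
                        affinity = numeric(), stringsAsFactors = FALSE)
    return(new("CloneTable", subclones = empty, mode = mode,
               pcFactor = pcFactor))
  }
  rec <- function(x) rep_len(as.integer(x), n)
  sub <- data.frame(
    clone_id = as.character(clone),
    subclone_id = paste0(clone, ".", stats::ave(seq_len(n), clone,
                                                FUN = seq_along)),
    sequence = sprintf("SEQ%04d", seq_len(n)),
    cb = rec(cb), cc = rec(cc), mbc = rec(mbc), pc = rec(pc),
    affinity = affinity, stringsAsFactors = FALSE)
  new("CloneTable", subclones = sub, mode = mode, pcFactor = pcFactor)
}

# minimal annotated coding sequence: seven regions of `codonsPerRegion`
# codons each, all built from `codon`
uniformCodonRegions <- function(codon = "ATG", codonsPerRegion = 1L) {
  regions <- c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3", "FWR4")
  len <- 3L * codonsPerRegion
  ends <- cumsum(rep(len, 7L))
  list(
    sequence = paste(rep(codon, 7L * codonsPerRegion), collapse = ""),
    regions = data.frame(region = regions, start = c(0L, ends[-7L]),
                         end = ends, stringsAsFactors = FALSE),
    frame = 0L)
}

# brute-force diversity oracles, straight from the definitions
oracleD50 <- function(counts) {
  counts <- sort(counts, decreasing = TRUE)
  total <- sum(counts)
  acc <- 0
  for (k in seq_along(counts)) {
    acc <- acc + counts[k]
    if (acc >= total / 2) return(k / length(counts))
  }
}
oracleBergerParker <- function(counts) max(counts) / sum(counts)
oraclePielou <- function(counts) {
  if (length(counts) == 1L) return(NA_real_)
  p <- counts / sum(counts)
  H <- 0
  for (pi in p) if (pi > 0) H <- H - pi * log(pi)
  H / log(length(counts))
}
oracleChao1 <- function(counts) {
  counts <- counts[counts > 0]
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  if (f2 > 0) length(counts) + f1 * f1 / (2 * f2)
  else length(counts) + f1 * (f1 - 1) / 2
}
oracleDominantFrac <- function(counts) {
  names(counts)[counts >= 0.005 * sum(counts)]
}
oracleDominantP75 <- function(counts) {
  thr <- unname(quantile(counts, 0.75, type = 7))
  names(counts)[counts >= thr]
}
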