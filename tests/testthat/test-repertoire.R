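test_that("DNA and RNA repertoire counting follow the stated rules", {
  cells <- data.frame(clone_id = "1", sequence = "AAA",
                      type = c("CB", "CB", "PC"), affinity = 0.5,
                      stringsAsFactors = FALSE)
  dna <- buildRepertoire(cells, "DNA")
  rna <- buildRepertoire(cells, "RNA", pcFactor = 100)
  expect_equal(unname(cloneCounts(dna)), 3)
  expect_equal(unname(cloneCounts(rna)), 102)     # 2 B cells + 100 * 1 PC
  # pcFactor 1 collapses the two modes
  rna1 <- buildRepertoire(cells, "RNA", pcFactor = 1)
  expect_equal(cloneCounts(rna1), cloneCounts(dna))
  # a PC-free repertoire is mode-invariant
  noPc <- data.frame(clone_id = c("1", "2"), sequence = c("AAA", "CCC"),
                     type = "CC", affinity = 0.2, stringsAsFactors = FALSE)
  expect_equal(cloneCounts(buildRepertoire(noPc, "DNA")),
               cloneCounts(buildRepertoire(noPc, "RNA")))
  # clone frequency is the sum over its subclones
  multi <- data.frame(clone_id = c("1", "1", "1"),
                      sequence = c("AAA", "AAC", "AAC"),
                      type = c("CB", "CC", "PC"), affinity = 0.2,
                      stringsAsFactors = FALSE)
  tab <- buildRepertoire(multi, "DNA")
  expect_equal(unname(cloneCounts(tab)), sum(subcloneCounts(tab)))
  expect_error(buildRepertoire(data.frame(clone_id = 1, sequence = "A",
                                          type = "XX", affinity = 1)),
               "cell type")
})

test_that("dominance conventions match their definitions", {
  # 0.5% threshold on counts 600,300,90,6,3,1 (threshold 5) -> four clones
  t1 <- makeCloneTable(c(600, 300, 90, 6, 3, 1))
  expect_setequal(dominantClones(t1, "frac0.5pct"), c("1", "2", "3", "4"))
  # 75th percentile of 1,2,3,4 is 3.25 (linear interpolation) -> only "4"
  t2 <- makeCloneTable(c(1, 2, 3, 4))
  expect_setequal(dominantClones(t2, "percentile75"), "4")
  # uniform counts: every clone >= 0.5% when each holds >= 0.5%
  t3 <- makeCloneTable(rep(25, 4))
  expect_setequal(dominantClones(t3, "frac0.5pct"), c("1", "2", "3", "4"))
  expect_error(dominantClones(makeCloneTable(integer(0))), "empty")
})

test_that("diversity indices match hand-computed cases", {
  expect_equal(d50(makeCloneTable(rep(25, 4))), 0.5)
  expect_equal(d50(makeCloneTable(c(97, 1, 1, 1))), 0.25)
  expect_equal(d50(makeCloneTable(42)), 1.0)
  expect_equal(bergerParker(makeCloneTable(c(30, 10, 10))), 0.6)
  expect_equal(bergerParker(makeCloneTable(rep(7, 5))), 1 / 5)
  # scale invariance
  expect_equal(bergerParker(makeCloneTable(c(3, 1, 1) * 1000)), 0.6)
  expect_equal(pielouEvenness(makeCloneTable(c(50, 50))), 1.0)
  expect_equal(pielouEvenness(makeCloneTable(c(1, 1, 1, 1))), 1.0)
  p <- c(999, 1) / 1000
  expect_equal(pielouEvenness(makeCloneTable(c(999, 1))),
               -sum(p * log(p)) / log(2))
  expect_true(is.na(pielouEvenness(makeCloneTable(10))))
})

test_that("Chao1 handles singletons, doubletons and the fallback", {
  expect_equal(chao1(c(5, 8, 12)), 3)                        # F1 = 0
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), 5, 9, 10, 12)), 14)
  # F2 = 0 fallback: S_obs + F1 (F1 - 1) / 2
  expect_equal(chao1(c(1, 1, 1, 5)), 4 + 3 * 2 / 2)          # = 7
  expect_error(chao1(c(0, 0)), "all-zero")
  set.seed(1)
  for (i in 1:25) {
    cnt <- rpois(20, 2)
    if (all(cnt == 0)) next
    expect_gte(chao1(cnt), sum(cnt > 0))                     # >= S_obs
  }
})

test_that("Chao1 agrees with vegan where the variants coincide (F2 = 0)", {
  skip_if_not_installed("vegan")
  cnt <- c(1, 1, 3, 5, 9)              # no doubletons
  # vegan's bias-corrected form S + F1(F1-1)/(2(F2+1)) equals the fallback
  v <- unname(vegan::estimateR(cnt)["S.chao1"])
  expect_equal(chao1(cnt), v)
})

test_that("clone median affinity is PC-weighted in RNA mode", {
  sub <- data.frame(clone_id = "1", subclone_id = c("1.1", "1.2"),
                    sequence = c("A", "C"),
                    cb = c(1L, 0L), cc = 0L, mbc = 0L, pc = c(0L, 1L),
                    affinity = c(0.1, 0.9), stringsAsFactors = FALSE)
  tab <- new("CloneTable", subclones = sub, mode = "DNA", pcFactor = 100)
  expect_equal(medianCloneAffinity(tab, "1", mode = "DNA"), 0.5)
  expect_equal(medianCloneAffinity(tab, "1", mode = "RNA"), 0.9)
  # PC-free clone is mode-invariant; singleton returns its own affinity
  t2 <- makeCloneTable(c(4, 9), affinity = c(0.3, 0.8))
  expect_equal(medianCloneAffinity(t2, "1", "DNA"),
               medianCloneAffinity(t2, "1", "RNA"))
  expect_equal(medianCloneAffinity(t2, "2", "DNA"), 0.8)
  # brute-force weighted median on a random table
  set.seed(2)
  aff <- runif(5)
  pcs <- c(2L, 0L, 1L, 3L, 0L)
  sub3 <- data.frame(clone_id = "z", subclone_id = paste0("z.", 1:5),
                     sequence = letters[1:5], cb = c(1L, 4L, 0L, 2L, 3L),
                     cc = 0L, mbc = 0L, pc = pcs, affinity = aff,
                     stringsAsFactors = FALSE)
  t3 <- new("CloneTable", subclones = sub3, mode = "RNA", pcFactor = 10)
  expanded <- rep(aff, times = sub3$cb + 10L * pcs)
  expect_equal(medianCloneAffinity(t3, "z"), median(expanded))
})

test_that("AIRR clonal grouping stratifies by V-J and 85% CDR3 identity", {
  base <- strrep("ACGTG", 4)           # length 20
  mut <- function(s, k, from = 1L) {
    # flip k consecutive positions (starting at `from`) to a different base
    for (p in seq.int(from, from + k - 1L)) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  # s4: 17/20 identical to base; s5: 16/20 to base and 13/20 to s4, so it
  # cannot merge even transitively
  rec <- data.frame(
    sequence_id = paste0("s", 1:5),
    v_call = c("IGHV1", "IGHV1", "IGHV2", "IGHV1", "IGHV1"),
    j_call = "IGHJ4",
    junction = c(base, base, base, mut(base, 3), mut(base, 4, from = 5L)),
    stringsAsFactors = FALSE)
  out <- groupClonesAirr(rec)
  # identical CDR3, same V-J -> one clone; same CDR3, different V -> split
  expect_equal(out$clone_id[1], out$clone_id[2])
  expect_false(out$clone_id[3] == out$clone_id[1])
  # 17/20 = 85% identity merges; 16/20 = 80% splits
  expect_equal(out$clone_id[4], out$clone_id[1])
  expect_false(out$clone_id[5] == out$clone_id[1])
  # single linkage: a chain 0 -> 3 -> 6 mismatches merges transitively
  chain <- data.frame(
    sequence_id = paste0("c", 1:3), v_call = "IGHV1", j_call = "IGHJ1",
    junction = c(base, mut(base, 3), mut(base, 6)), stringsAsFactors = FALSE)
  outc <- groupClonesAirr(chain)
  expect_equal(length(unique(outc$clone_id)), 1L)
  # records missing fields are skipped with a warning
  rec$v_call[2] <- NA
  expect_warning(out2 <- groupClonesAirr(rec), "skipped")
  expect_true(is.na(out2$clone_id[2]))
})

test_that("clone tables round-trip through TSV", {
  tab <- makeCloneTable(c(10, 5, 2), pc = c(1, 0, 0), affinity = c(0.2, 0.5, 0.9))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCloneTable(tab, path)
  back <- readCloneTable(path, "DNA", 100)
  expect_equal(cloneCounts(back), cloneCounts(tab))
  expect_equal(back@subclones$affinity, tab@subclones$affinity)
  onDisk <- read.delim(path)
  expect_equal(onDisk$rna_count - onDisk$dna_count, 99 * onDisk$pc)
})
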