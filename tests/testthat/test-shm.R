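test_that("fate trees are validated level by level", {
  expect_s4_class(defaultFateTree(), "FateTree")
  t <- defaultFateTree()
  expect_equal(sum(t@regionProb), 1)
  expect_true(all(abs(rowSums(t@effectProb) - 1) < 1e-12))
  # region probabilities not summing to one
  rp <- t@regionProb; rp[["FWR1"]] <- rp[["FWR1"]] + 0.1
  expect_error(fateTree(rp, t@replacementProb, t@effectProb), "sum to 1")
  # affinity mass on a framework region
  ep <- t@effectProb; ep["FWR1", ] <- c(0.5, 0.25, 0.25)
  expect_error(fateTree(t@regionProb, t@replacementProb, ep),
               "only CDR replacement")
})

test_that("the printed fate-tree anchors hold", {
  t <- defaultFateTree()
  # CDR branch: 0.1*0.79 + 0.03*0.76 + 0.19*0.75
  expect_equal(affinityChangeProbability(t), 0.2443, tolerance = 1e-12)
  expect_equal(unname(t@regionProb[c("CDR1", "CDR2", "CDR3")]),
               c(0.10, 0.03, 0.19))
})

test_that("a forced branch is always taken and frequencies match the tree", {
  lethalTree <- fateTree(
    c(FWR1 = 0, CDR1 = 0, FWR2 = 0, CDR2 = 0, FWR3 = 0, CDR3 = 1, FWR4 = 0),
    c(FWR1 = 0.75, CDR1 = 0.79, FWR2 = 0.75, CDR2 = 0.76, FWR3 = 0.75,
      CDR3 = 1, FWR4 = 0.75),
    {
      ep <- defaultFateTree()@effectProb
      ep["CDR3", ] <- c(0, 1, 0)
      ep
    })
  rng <- newRngStream(1)
  for (i in 1:25) {
    f <- sampleFate(lethalTree, rng)
    expect_equal(f$region, "CDR3")
    expect_equal(f$type, "replacement")
    expect_equal(f$effect, "lethal")
  }

  # Monte-Carlo branch frequencies against the exact tree probabilities
  t <- defaultFateTree()
  n <- 50000L
  rng <- newRngStream(2)
  draws <- withStream(rng, {
    region <- sample(names(t@regionProb), n, replace = TRUE,
                     prob = t@regionProb)
    region
  })
  # (independent draw path above is the oracle; now the implementation)
  rng2 <- newRngStream(3)
  fates <- vector("list", n)
  for (i in seq_len(n)) fates[[i]] <- sampleFate(t, rng2)
  regions <- vapply(fates, `[[`, character(1), "region")
  for (r in names(t@regionProb)) {
    p <- t@regionProb[[r]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(regions == r) - p), max(4 * se, 1e-3))
  }
  affChanging <- vapply(fates, function(f) f$effect == "affinity", logical(1))
  p <- affinityChangeProbability(t)
  expect_lt(abs(mean(affChanging) - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("Poisson mutation counts reproduce the division-level rates", {
  rng <- newRngStream(4)
  m <- replicate(10000, sampleMutationCount(0.4, rng))
  pGe1 <- 1 - exp(-0.4)                      # 0.3297
  expect_lt(abs(mean(m >= 1) - pGe1), 3 * sqrt(pGe1 * (1 - pGe1) / 1e4))
  expect_lt(abs(mean(m) - 0.4), 3 * sqrt(0.4 / 1e4))
})

test_that("substitutions respect the drawn mutation type", {
  fix <- uniformCodonRegions("GGT", 2L)      # every codon 4-fold degenerate
  rng <- newRngStream(5)
  # silent at a degenerate third position succeeds and preserves the protein
  mut <- mutateSequence(fix$sequence, fix$regions, fix$frame, "CDR3",
                        type = "silent", rng = rng)
  expect_equal(sum(strsplit(mut$sequence, "")[[1]] !=
                   strsplit(fix$sequence, "")[[1]]), 1L)
  expect_equal(
    as.character(Biostrings::translate(Biostrings::DNAString(mut$sequence))),
    as.character(Biostrings::translate(Biostrings::DNAString(fix$sequence))))
  # replacement changes the protein, never to a stop
  mut <- mutateSequence(fix$sequence, fix$regions, fix$frame, "CDR1",
                        type = "replacement", rng = rng)
  aaNew <- as.character(
    Biostrings::translate(Biostrings::DNAString(mut$sequence)))
  expect_false(grepl("\\*", aaNew))
  expect_false(identical(aaNew, as.character(
    Biostrings::translate(Biostrings::DNAString(fix$sequence)))))
  # lethal creates an in-frame stop ("GGT" region: G GA/TGA reachable? use TAC)
  fixy <- uniformCodonRegions("TAC", 2L)
  mut <- mutateSequence(fixy$sequence, fixy$regions, fixy$frame, "FWR2",
                        type = "replacement", lethal = TRUE, rng = rng)
  expect_true(grepl("\\*", as.character(
    Biostrings::translate(Biostrings::DNAString(mut$sequence)))))
})

test_that("the retry protocol exhausts impossible types (ATG has no synonym)", {
  # enumerate: all 9 single substitutions of ATG are nonsynonymous, non-stop
  subs <- expand.grid(pos = 0:2, nt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  classes <- apply(subs, 1, function(s) {
    tw <- translateCodonWindow("ATG", 0, as.integer(s[["pos"]]), s[["nt"]])
    if (tw$codonNew == "ATG") NA_character_
    else if (tw$aaNew == tw$aa) "silent"
    else if (tw$aaNew == "*") "lethal"
    else "replacement"
  })
  expect_setequal(na.omit(classes), "replacement")

  fix <- uniformCodonRegions("ATG", 1L)
  rng <- newRngStream(6)
  expect_error(mutateSequence(fix$sequence, fix$regions, fix$frame, "CDR2",
                              type = "silent", rng = rng),
               "no silent substitution")
  expect_error(mutateSequence(fix$sequence, fix$regions, fix$frame, "CDR2",
                              type = "replacement", lethal = TRUE, rng = rng),
               "no lethal")
  mut <- mutateSequence(fix$sequence, fix$regions, fix$frame, "CDR2",
                        type = "replacement", rng = rng)
  expect_equal(sum(strsplit(mut$sequence, "")[[1]] !=
                   strsplit(fix$sequence, "")[[1]]), 1L)
})

test_that("the registry keeps affinity a function of sequence", {
  reg <- newSequenceRegistry()
  first <- registryRegister(reg, "AAA", c(1, 2, 3, 4), 0.5)
  expect_equal(first$affinity, 0.5)
  # first registration wins
  again <- registryRegister(reg, "AAA", c(9, 9, 9, 9), 0.5)
  expect_equal(again$position, c(1, 2, 3, 4))
  # conflicting affinity is an invariant breach
  expect_error(registryRegister(reg, "AAA", c(1, 2, 3, 4), 0.9), "conflict")
  expect_equal(registrySize(reg), 1L)
  snap <- registrySnapshot(reg)
  expect_equal(snap$affinity, 0.5)
})

test_that("SHM leaves affinity untouched when CDR branches are switched off", {
  fwrOnly <- fateTree(
    c(FWR1 = 0.4, CDR1 = 0, FWR2 = 0.2, CDR2 = 0, FWR3 = 0.3, CDR3 = 0,
      FWR4 = 0.1),
    defaultFateTree()@replacementProb,
    {
      ep <- defaultFateTree()@effectProb
      ep[c("FWR1", "FWR2", "FWR3", "FWR4"), ] <-
        rep(c(0, 0, 1), each = 4)            # neutral only: isolate affinity
      ep
    })
  pool <- generateGermlinePool(1, seed = 21)
  gl <- drawFounderSequence(pool)
  cfg <- shapeSpaceConfig()
  reg <- newSequenceRegistry()
  pos <- positionAtDistance(6, cfg)
  aff <- affinityFromDistance(6, cfg$gamma)
  registryRegister(reg, gl$sequence, pos, aff)
  rng <- newRngStream(7)
  seqNow <- gl$sequence; posNow <- pos; affNow <- aff
  mutated <- FALSE
  for (i in 1:100) {
    res <- applySHM(seqNow, gl$regions, gl$frame, posNow, affNow, fwrOnly,
                    reg, cfg, lambda = 1, rng = rng)
    if (!identical(res$sequence, seqNow)) mutated <- TRUE
    expect_false(res$apoptosis)
    expect_equal(res$affinity, aff)
    expect_equal(res$position, pos)
    seqNow <- res$sequence; posNow <- res$position; affNow <- res$affinity
  }
  expect_true(mutated)   # sequences did evolve, affinity did not
})

test_that("lethal outcomes zero the affinity and flag DZ apoptosis", {
  lethalTree <- fateTree(
    c(FWR1 = 0, CDR1 = 0, FWR2 = 0, CDR2 = 0, FWR3 = 1, CDR3 = 0, FWR4 = 0),
    c(FWR1 = 1, CDR1 = 1, FWR2 = 1, CDR2 = 1, FWR3 = 1, CDR3 = 1, FWR4 = 1),
    {
      ep <- defaultFateTree()@effectProb
      ep["FWR3", ] <- c(0, 1, 0)
      ep
    })
  pool <- generateGermlinePool(1, seed = 22)
  gl <- drawFounderSequence(pool)
  cfg <- shapeSpaceConfig()
  reg <- newSequenceRegistry()
  pos <- positionAtDistance(6, cfg)
  rng <- newRngStream(8)
  hit <- FALSE
  for (i in 1:50) {
    res <- applySHM(gl$sequence, gl$regions, gl$frame, pos, 0.01, lethalTree,
                    reg, cfg, lambda = 2, rng = rng)
    if (res$m > 0) {
      expect_true(res$apoptosis)
      expect_equal(res$affinity, 0)
      hit <- TRUE
      break
    }
  }
  expect_true(hit)
})

test_that("a cell re-deriving a known sequence inherits its affinity", {
  # registry contract exercised through applySHM: pre-register the sequence
  # that the mutation will produce, with a sentinel affinity
  fix <- uniformCodonRegions("GGG", 2L)
  silentOnly <- fateTree(
    c(FWR1 = 0, CDR1 = 0, FWR2 = 0, CDR2 = 0, FWR3 = 0, CDR3 = 1, FWR4 = 0),
    c(FWR1 = 0, CDR1 = 0, FWR2 = 0, CDR2 = 0, FWR3 = 0, CDR3 = 0, FWR4 = 0),
    defaultFateTree()@effectProb)
  cfg <- shapeSpaceConfig()
  reg <- newSequenceRegistry()
  # enumerate the possible silent edits of the CDR3 and register them all
  cdr3 <- fix$regions[fix$regions$region == "CDR3", ]
  sentinelPos <- c(1, 1, 1, 1)
  for (p in seq.int(cdr3$start, cdr3$end - 1L)) {
    for (nt in c("A", "C", "G", "T")) {
      tw <- translateCodonWindow(fix$sequence, 0L, p, nt)
      if (tw$aaNew == tw$aa && tw$codonNew != tw$codon) {
        edited <- fix$sequence
        substr(edited, p + 1L, p + 1L) <- nt
        registryRegister(reg, edited, sentinelPos, 0.123)
      }
    }
  }
  rng <- newRngStream(9)
  for (i in 1:50) {
    res <- applySHM(fix$sequence, fix$regions, fix$frame, c(5, 5, 5, 5),
                    0.7, silentOnly, reg, cfg, lambda = 1, rng = rng)
    if (res$m > 0) {
      expect_equal(res$affinity, 0.123)    # registered, not recomputed
      expect_equal(res$position, sentinelPos)
      break
    }
  }
})
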