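test_that("the influx law reproduces its analytic anchors", {
  cfg <- gcConfig()
  expect_equal(round(influxProbability(0, cfg), 3), 0.004)
  expect_equal(influxProbability(cfg$influxAlpha, cfg),
               cfg$influxMu * cfg$dt / 2)                 # logistic midpoint
  expect_lt(influxProbability(300, cfg), 1e-12)
  # deterministic founder total: step sum vs closed-form integral
  total <- expectedFounders(cfg)
  integral <- integrate(function(t) cfg$influxMu /
                          (1 + exp((t - cfg$influxAlpha) / cfg$influxBeta)),
                        0, cfg$duration, rel.tol = 1e-10)$value
  expect_equal(total, integral, tolerance = 1e-4)
  expect_gt(total, 190); expect_lt(total, 200)
})

test_that("an influx-free GC stays empty", {
  res <- runGC(smokeConfig(influxMu = 0, duration = 2), seed = 1)
  expect_equal(res@counters[["created"]], 0L)
  expect_equal(nrow(res@cells), 0L)
  expect_equal(nrow(res@outputCells), 0L)
})

test_that("founders enter with unique clones at the configured affinity", {
  res <- runGC(smokeConfig(duration = 20, founderDistance = 6,
                           shmStart = 1e6), seed = 3)
  founders <- res@lineage[res@lineage$parent == 0L, ]
  expect_gt(nrow(founders), 2)
  expect_equal(anyDuplicated(founders$clone_id), 0L)
  # distance 6 with gamma 2.8: affinity ~0.01, identical for all founders
  expect_true(all(abs(founders$affinity -
                        affinityFromDistance(6, 2.8)) < 1e-12))
})

test_that("with SHM off every sequence is germline and clones never split", {
  res <- runGC(smokeConfig(duration = 36, shmStart = 1e6), seed = 4)
  founders <- res@lineage[res@lineage$parent == 0L, ]
  expect_gt(res@counters[["created"]], nrow(founders))   # divisions happened
  allSeq <- c(res@cells$sequence, res@outputCells$sequence)
  expect_lte(length(unique(allSeq)), nrow(founders))
  expect_equal(nrow(res@registry), nrow(founders))
  ts <- res@timeSeries
  expect_true(all(ts$clones <= nrow(founders)))
  expect_true(all(ts$subclones <= ts$clones))
})

test_that("closing the asymmetric-division path closes all export", {
  res <- runGC(smokeConfig(duration = 36, asymProb = 0), seed = 5)
  expect_equal(res@counters[["exported"]], 0L)
  expect_equal(nrow(res@outputCells), 0L)
})

test_that("identical seeds give identical runs; different seeds differ", {
  cfg <- smokeConfig(duration = 24)
  a <- runGC(cfg, seed = 11)
  b <- runGC(cfg, seed = 11)
  c <- runGC(cfg, seed = 12)
  expect_identical(a@timeSeries, b@timeSeries)
  expect_identical(a@cells, b@cells)
  expect_identical(a@outputCells, b@outputCells)
  expect_identical(a@lineage, b@lineage)
  expect_false(identical(a@timeSeries, c@timeSeries))
})

test_that("cell accounting and lineage partition are conserved", {
  res <- runGC(smokeConfig(duration = 36), seed = 6)   # conservation checked
  expect_equal(nrow(res@cells) + res@counters[["exported"]] +
                 res@counters[["apoptosed"]], res@counters[["created"]])
  lin <- res@lineage
  # every cell walks up to exactly one founder of its own clone
  rootOf <- function(id) {
    while (lin$parent[id] != 0L) id <- lin$parent[id]
    id
  }
  for (id in lin$id) {
    root <- rootOf(id)
    expect_equal(lin$clone_id[id], lin$clone_id[root])
    expect_gte(lin$birth[id], lin$birth[root])          # time-ordered edges
  }
  # live cells carry their registry affinity (cross-module consistency)
  regAff <- setNames(res@registry$affinity, res@registry$sequence)
  expect_true(all(abs(res@cells$affinity -
                        regAff[res@cells$sequence]) < 1e-12))
})

test_that("both PC and MBC output routes are reachable", {
  pc <- runGC(smokeConfig(duration = 36), seed = 1)
  expect_gt(sum(pc@outputCells$type == "PC"), 0)
  # with an unreachable BLIMP1 threshold every asymmetric export is an MBC
  mbc <- runGC(smokeConfig(duration = 36, grn = grnParameters(thetaPC = 1)),
               seed = 1)
  expect_gt(nrow(mbc@outputCells), 0)
  expect_true(all(mbc@outputCells$type == "MBC"))
})

test_that("the lineage forest exports to Newick and parses back", {
  res <- runGC(smokeConfig(duration = 36), seed = 7)
  dir <- withr::local_tempdir()
  paths <- exportLineageForest(res, dir)
  nodes <- read.delim(file.path(dir, "lineage_nodes.tsv"))
  expect_equal(nrow(nodes), res@counters[["created"]])
  expect_length(paths, length(unique(res@lineage$clone_id)))
  # pick a clone with at least two cells and verify parent/child relations
  sizes <- table(res@lineage$clone_id)
  cl <- as.integer(names(sizes)[which(sizes >= 2)[1]])
  tree <- ape::read.tree(file.path(dir, sprintf("clone_%d.nwk", cl)))
  sub <- res@lineage[res@lineage$clone_id == cl, ]
  expect_equal(ape::Ntip(tree) + tree$Nnode, nrow(sub))
  labs <- c(tree$tip.label, tree$node.label)
  edges <- apply(tree$edge, 1, function(e)
    paste(labs[e[1]], labs[e[2]]))
  want <- with(sub[sub$parent != 0L, ],
               paste(paste0("c", parent), paste0("c", id)))
  expect_setequal(edges, want)
  # a founder that never divided exports as a single-leaf tree
  singles <- as.integer(names(sizes)[sizes == 1])
  if (length(singles)) {
    nwk <- readLines(file.path(dir, sprintf("clone_%d.nwk", singles[1])))
    id <- sub$id[1]
    expect_match(nwk, "^c[0-9]+:")
  }
})

test_that("a pool smaller than the founder demand fails loudly", {
  expect_error(runGC(smokeConfig(duration = 40, poolSize = 1, influxMu = 5),
                     seed = 8),
               "exhausted")
})
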