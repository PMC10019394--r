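## Agent-based germinal-center reaction: founder influx, DZ proliferation
## with SHM, LZ selection through FDC antigen capture and Tfh help,
## recycling, asymmetric-division output of MBCs/PCs, and apoptosis.
##
## Agents live in an environment of parallel vectors (one slot per live
## cell) so every per-step phase is vectorised; per-event work (divisions,
## founder entries) loops only over the cells concerned.

#' Germinal-center simulation configuration
#'
#' Returns the full parameter ledger of the simulator with documented
#' defaults; any entry can be overridden by name. Durations and rates are in
#' hours; lengths in micrometres; GRN concentrations in M. The defaults
#' describe the production condition: a 504 h (21-day) reaction at
#' dt = 0.002 h with founder influx mu = 2 cells/h until ~96 h (~200
#' founders), SHM switched on at 24 h, founders placed at shape-space
#' distance 6 (affinity ~0.01).
#'
#' Kinetic entries (cell-cycle length, divisions per selection round,
#' contact rates, asymmetric-division probability, selection threshold,
#' migration speeds) form one annotated ledger; see the package vignette
#' for the reasoning behind each default.
#'
#' @param ... named overrides of any default.
#' @return a classed list (`gc_config`).
#' @examples
#' cfg <- gcConfig(duration = 48, dt = 0.02)
#' cfg$influxMu
#' @export
gcConfig <- function(...) {
  cfg <- list(
    # horizon and resolution
    duration = 504, dt = 0.002, recordEvery = 0.5,
    # founder influx (logistic switch-off)
    influxMu = 2, influxAlpha = 96, influxBeta = 6,
    # germline pool
    poolSize = 250, meanTotalLength = 402, meanCdr3Length = 48,
    pool = NULL,
    # SHM
    shmStart = 24, shmLambda = 0.4, fateTree = NULL,
    # shape space and founder placement
    shape = NULL, founderDistance = 6,
    # geometry and migration
    radius = 160, speed = 150, turnRate = 2, zonalDrift = 0.5,
    # proliferation
    cycleTime = 7, founderDivisions = 6, divisionsPerRound = 6,
    # output via asymmetric division
    asymProb = 0.72, agExportThreshold = 1,
    # light-zone selection
    ccLifespan = 10, fdcContactRate = 3, captureScale = 1,
    tfhContactRate = 3, contactDuration = 0.6, selectionThreshold = 1e-8,
    # GRN
    grn = NULL, grnInit = c(p = 0.45e-8, b = 5.4e-8, r = 0.13e-8))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config entr",
                        if (length(bad) > 1) "ies: " else "y: ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (is.null(cfg$fateTree)) cfg$fateTree <- defaultFateTree()
  if (is.null(cfg$shape)) cfg$shape <- shapeSpaceConfig()
  if (is.null(cfg$grn)) cfg$grn <- grnParameters()
  nStep <- cfg$duration / cfg$dt
  if (abs(nStep - round(nStep)) > 1e-9)
    stop("duration/dt must give an integer step count")
  rates <- c(cfg$influxMu, cfg$turnRate, cfg$fdcContactRate,
             cfg$tfhContactRate, cfg$speed)
  if (any(rates < 0)) stop("rates must be >= 0")
  structure(cfg, class = "gc_config")
}

#' Scaled-down smoke configuration
#'
#' A 48 h configuration at dt = 0.02 h with a reduced founder influx, a
#' shorter cell cycle, fewer divisions per round and founders placed close
#' to the antigen, so that proliferation, SHM, selection, recycling and
#' asymmetric-division export all occur within the short horizon. Intended
#' for exercising every code path quickly (tests, examples) - it is an
#' accelerated caricature, not a study condition.
#'
#' @param ... named overrides applied on top of the smoke defaults.
#' @return a `gc_config` list.
#' @export
smokeConfig <- function(...) {
  base <- list(duration = 48, dt = 0.02, recordEvery = 1,
               influxMu = 0.4, poolSize = 40, founderDistance = 2,
               cycleTime = 4, founderDivisions = 4, divisionsPerRound = 4,
               ccLifespan = 8, fdcContactRate = 4, tfhContactRate = 4,
               selectionThreshold = 5e-9, shmStart = 24)
  ov <- list(...)
  base[names(ov)] <- ov
  do.call(gcConfig, base)
}

#' Founder influx probability per time step
#'
#' Logistic switch-off of founder entry:
#' `p(t) = mu * dt / (1 + exp((t - alpha) / beta))`. With the default
#' constants (mu = 2 cells/h, alpha = 96 h, beta = 6 h, dt = 0.002 h) this
#' gives p(0) = 0.004, ~2 cells in the first hour, and a deterministic
#' expected total of ~192 founders over 504 h.
#'
#' @param t simulation time(s), h.
#' @param cfg a [gcConfig()] (its `influxMu`, `influxAlpha`, `influxBeta`,
#'   `dt` entries are used).
#' @return per-step entry probability.
#' @examples
#' influxProbability(0, gcConfig())           # 0.004
#' influxProbability(96, gcConfig())          # 0.002 (logistic midpoint)
#' @export
influxProbability <- function(t, cfg = gcConfig()) {
  stopifnot(all(t >= 0))
  cfg$influxMu * cfg$dt / (1 + exp((t - cfg$influxAlpha) / cfg$influxBeta))
}

#' Deterministic expected founder total
#'
#' Sum of [influxProbability()] over every step of the configured horizon.
#'
#' @param cfg a [gcConfig()].
#' @return expected number of founder cells.
#' @export
expectedFounders <- function(cfg = gcConfig()) {
  t <- seq(0, cfg$duration - cfg$dt, by = cfg$dt)
  sum(influxProbability(t, cfg))
}

## ---- internal simulation state ------------------------------------------

.newSimState <- function(cfg, seed) {
  sim <- new.env(parent = emptyenv())
  sim$cfg <- cfg
  sim$seed <- as.integer(seed)
  sim$streams <- rngStreams(seed)
  sim$pool <- if (!is.null(cfg$pool)) cfg$pool else
    generateGermlinePool(cfg$poolSize, cfg$meanTotalLength,
                         cfg$meanCdr3Length, rng = sim$streams$germline)
  sim$registry <- newSequenceRegistry()
  sim$t <- 0
  sim$nextClone <- 1L
  sim$nextId <- 1L
  # per-live-cell parallel vectors
  sim$id <- integer(0); sim$clone <- integer(0)
  sim$state <- character(0)                       # "CB", "CC", "selCC"
  sim$x <- numeric(0); sim$y <- numeric(0); sim$z <- numeric(0)
  sim$dx <- numeric(0); sim$dy <- numeric(0); sim$dz <- numeric(0)
  sim$seq <- character(0); sim$aff <- numeric(0)
  sim$shapePos <- matrix(numeric(0), ncol = cfg$shape$dimensions)
  sim$p <- numeric(0); sim$b <- numeric(0); sim$r <- numeric(0)
  sim$ag <- numeric(0); sim$cycleT <- numeric(0); sim$divLeft <- integer(0)
  sim$ccTimer <- numeric(0); sim$sigBCR <- numeric(0)
  sim$sigCD40 <- numeric(0); sim$intSig <- numeric(0)
  sim$recycled <- logical(0)
  # per-clone germline annotation (regions/frame shared down the lineage)
  sim$cloneRegions <- list(); sim$cloneFrame <- integer(0)
  sim$cloneGermline <- character(0)
  # lineage bookkeeping, indexed by cell id
  sim$lin_parent <- integer(0); sim$lin_clone <- integer(0)
  sim$lin_birth <- numeric(0); sim$lin_aff <- numeric(0)
  sim$lin_fate <- character(0)
  # output cells
  sim$oc_id <- integer(0); sim$oc_clone <- integer(0)
  sim$oc_type <- character(0); sim$oc_seq <- character(0)
  sim$oc_aff <- numeric(0); sim$oc_time <- numeric(0)
  # counters
  sim$created <- 0L; sim$apoptosed <- 0L; sim$exported <- 0L
  # time series accumulator
  sim$ts <- list()
  class(sim) <- "gc_sim"
  sim
}

.addCell <- function(sim, parent, clone, x, y, z, seqStr, aff, shapePos,
                     p, b, r, ag, cycleT, divLeft, recycled) {
  id <- sim$nextId
  sim$nextId <- id + 1L
  sim$created <- sim$created + 1L
  n <- length(sim$id) + 1L
  sim$id[n] <- id; sim$clone[n] <- clone; sim$state[n] <- "CB"
  sim$x[n] <- x; sim$y[n] <- y; sim$z[n] <- z
  dir <- .randUnit3()
  sim$dx[n] <- dir[1]; sim$dy[n] <- dir[2]; sim$dz[n] <- dir[3]
  sim$seq[n] <- seqStr; sim$aff[n] <- aff
  sim$shapePos <- rbind(sim$shapePos, shapePos)
  sim$p[n] <- p; sim$b[n] <- b; sim$r[n] <- r
  sim$ag[n] <- ag; sim$cycleT[n] <- cycleT; sim$divLeft[n] <- divLeft
  sim$ccTimer[n] <- 0; sim$sigBCR[n] <- 0; sim$sigCD40[n] <- 0
  sim$intSig[n] <- 0; sim$recycled[n] <- recycled
  sim$lin_parent[id] <- parent; sim$lin_clone[id] <- clone
  sim$lin_birth[id] <- sim$t; sim$lin_aff[id] <- aff
  sim$lin_fate[id] <- "alive"
  id
}

.randUnit3 <- function() {
  repeat {
    v <- runif(3, -1, 1)
    n <- sqrt(sum(v^2))
    if (n > 1e-6 && n <= 1) return(v / n)
  }
}

#' Introduce one founder B cell
#'
#' Draws an undrawn germline sequence from the pool, opens a fresh clone,
#' places the cell at a uniformly random dark-zone grid position and at the
#' configured shape-space distance from the antigen (default 6, affinity
#' ~0.01), initialises its GRN at the BCL6-high naive state, and registers
#' the founder sequence with its affinity.
#'
#' @param sim internal simulation state (see [runGC()]).
#' @return the new cell id, invisibly.
#' @export
spawnFounder <- function(sim) {
  cfg <- sim$cfg
  gl <- drawFounderSequence(sim$pool, sim$streams$germline)
  clone <- sim$nextClone
  sim$nextClone <- clone + 1L
  sim$cloneRegions[[clone]] <- gl$regions
  sim$cloneFrame[clone] <- gl$frame
  sim$cloneGermline[clone] <- gl$id
  shapePos <- positionAtDistance(cfg$founderDistance, cfg$shape,
                                 sim$streams$germline)
  aff <- affinityFromDistance(cfg$founderDistance, cfg$shape$gamma)
  registryRegister(sim$registry, gl$sequence, shapePos, aff)
  pos <- withStream(sim$streams$influx, {
    repeat {
      v <- runif(3, -1, 1) * cfg$radius
      if (sqrt(sum(v^2)) <= cfg$radius && v[3] <= 0) break
    }
    v
  })
  id <- withStream(sim$streams$migration,
    .addCell(sim, parent = 0L, clone = clone,
             x = pos[1], y = pos[2], z = pos[3],
             seqStr = gl$sequence, aff = aff, shapePos = shapePos,
             p = cfg$grnInit[["p"]], b = cfg$grnInit[["b"]],
             r = cfg$grnInit[["r"]],
             ag = 0, cycleT = cfg$cycleTime,
             divLeft = cfg$founderDivisions, recycled = FALSE))
  invisible(id)
}

#' Advance the simulation by one time step
#'
#' Fixed sub-phase order: founder influx; migration (persistent random walk
#' with drift towards each cell's target zone); centroblast cycling and
#' division with SHM (after the SHM start time) and asymmetric-division
#' export; CB to CC differentiation; CC-FDC antigen capture (probability
#' proportional to affinity); CC-Tfh contact with affinity-scaled CD40; the
#' selection decision by integrated CD40 signal; recycling of selected CCs
#' reaching the dark zone; CC apoptosis on timeout; removal of dead cells;
#' one GRN integration step for all live cells; time advance.
#'
#' @param sim internal simulation state created by [runGC()].
#' @return the state, invisibly.
#' @export
gcStep <- function(sim) {
  cfg <- sim$cfg
  dt <- cfg$dt

  ## (1) founder influx
  pIn <- influxProbability(sim$t, cfg)
  if (withStream(sim$streams$influx, runif(1)) < pIn) spawnFounder(sim)

  n <- length(sim$id)
  if (n > 0L) {
    ## (2) migration: persistent walk + zonal drift, clamped to the sphere
    withStream(sim$streams$migration, {
      turn <- runif(n) < cfg$turnRate * dt
      if (any(turn)) {
        k <- sum(turn)
        v <- matrix(runif(3 * k, -1, 1), ncol = 3)
        nv <- sqrt(rowSums(v^2))
        nv[nv < 1e-6] <- 1
        v <- v / nv
        sim$dx[turn] <- v[, 1]; sim$dy[turn] <- v[, 2]; sim$dz[turn] <- v[, 3]
      }
    })
    targetZ <- ifelse(sim$state == "CC", 1, -1)   # CC -> LZ, CB/selCC -> DZ
    stepLen <- cfg$speed * dt
    drift <- cfg$zonalDrift
    sim$x <- sim$x + stepLen * (1 - drift) * sim$dx
    sim$y <- sim$y + stepLen * (1 - drift) * sim$dy
    sim$z <- sim$z + stepLen * ((1 - drift) * sim$dz + drift * targetZ)
    rad <- sqrt(sim$x^2 + sim$y^2 + sim$z^2)
    out <- rad > cfg$radius
    if (any(out)) {
      f <- cfg$radius / rad[out]
      sim$x[out] <- sim$x[out] * f
      sim$y[out] <- sim$y[out] * f
      sim$z[out] <- sim$z[out] * f
    }

    ## (3) centroblast cycling and division
    isCB <- sim$state == "CB"
    sim$cycleT[isCB] <- sim$cycleT[isCB] - dt
    ## divisions and SHM can remove cells, shifting indices: walk by cell id
    divIds <- sim$id[isCB & sim$cycleT <= 0 & sim$divLeft > 0L]
    for (cid in divIds) {
      i <- match(cid, sim$id)
      if (!is.na(i)) .divideCell(sim, i)
    }

    ## (4) CB -> CC differentiation once the division programme is spent
    toCC <- which(sim$state == "CB" & sim$divLeft == 0L)
    if (length(toCC)) {
      sim$state[toCC] <- "CC"
      sim$ccTimer[toCC] <- cfg$ccLifespan
      sim$intSig[toCC] <- 0
    }

    withStream(sim$streams$selection, {
      ## (5) CC-FDC contact: antigen capture, probability ~ affinity
      inLZ <- sim$z > 0
      cc <- sim$state == "CC" & inLZ
      contact <- cc & runif(length(cc)) < cfg$fdcContactRate * dt
      if (any(contact)) {
        capture <- contact &
          runif(length(contact)) < pmin(1, sim$aff * cfg$captureScale)
        sim$ag[capture] <- sim$ag[capture] + 1
        sim$sigBCR[capture] <- cfg$contactDuration
      }
      ## (6) CC-Tfh contact: CD40 window for antigen-presenting CCs
      tfh <- sim$state == "CC" & inLZ & sim$ag >= 1
      hit <- tfh & runif(length(tfh)) < cfg$tfhContactRate * dt
      sim$sigCD40[hit] <- cfg$contactDuration
    })

    ## selection decision on integrated CD40 signal
    sel <- sim$state == "CC" & sim$intSig >= cfg$selectionThreshold
    if (any(sel)) sim$state[sel] <- "selCC"

    ## (7) selected CCs that reach the DZ recycle to CB
    rec <- sim$state == "selCC" & sim$z <= 0
    if (any(rec)) {
      sim$state[rec] <- "CB"
      sim$recycled[rec] <- TRUE
      sim$divLeft[rec] <- cfg$divisionsPerRound
      sim$cycleT[rec] <- cfg$cycleTime
      sim$intSig[rec] <- 0
    }

    ## (8) unselected CC apoptosis on timeout
    isCC <- sim$state == "CC"
    sim$ccTimer[isCC] <- sim$ccTimer[isCC] - dt
    dying <- which(isCC & sim$ccTimer <= 0)
    if (length(dying)) .removeCells(sim, dying, "apoptosis")

    ## (9) GRN step for every live cell, with event-gated signals
    n <- length(sim$id)
    if (n > 0L) {
      par <- cfg$grn
      BCR <- ifelse(sim$sigBCR > 0, bcrSignal(sim$b, par$bcr0, par$k_b), 0)
      CD40 <- ifelse(sim$sigCD40 > 0,
                     cd40Signal(sim$b, sim$aff, par$cd0, par$k_b), 0)
      st <- integrateGRN(sim$p, sim$b, sim$r, par, BCR, CD40, dt = dt)
      sim$p <- st$p; sim$b <- st$b; sim$r <- st$r
      sim$intSig <- sim$intSig + CD40 * dt
      sim$sigBCR <- pmax(0, sim$sigBCR - dt)
      sim$sigCD40 <- pmax(0, sim$sigCD40 - dt)
    }
  }

  ## (10) advance time
  sim$t <- sim$t + dt
  invisible(sim)
}

## Division: the mother continues as one daughter (same id); one new cell is
## created. Both run SHM independently after the SHM start time. During
## post-selection (recycled) divisions the antigen-retaining daughter may be
## exported asymmetrically as an output cell (PC if BLIMP1 >= thetaPC, MBC
## otherwise).
.divideCell <- function(sim, i) {
  cfg <- sim$cfg
  clone <- sim$clone[i]
  sim$divLeft[i] <- sim$divLeft[i] - 1L
  sim$cycleT[i] <- cfg$cycleTime

  exportDaughter <- FALSE
  if (sim$recycled[i] && sim$ag[i] >= cfg$agExportThreshold) {
    exportDaughter <- withStream(sim$streams$selection,
                                 runif(1) < cfg$asymProb)
  }

  if (exportDaughter) {
    ## Ag-retaining daughter leaves the GC as an output cell
    type <- if (classifyPC(sim$p[i], cfg$grn$thetaPC)) "PC" else "MBC"
    id <- withStream(sim$streams$migration,
      .addCell(sim, parent = sim$id[i], clone = clone,
               x = sim$x[i], y = sim$y[i], z = sim$z[i],
               seqStr = sim$seq[i], aff = sim$aff[i],
               shapePos = sim$shapePos[i, ],
               p = sim$p[i], b = sim$b[i], r = sim$r[i],
               ag = sim$ag[i], cycleT = cfg$cycleTime, divLeft = 0L,
               recycled = TRUE))
    sim$ag[i] <- 0
    j <- length(sim$id)                 # the daughter sits in the last slot
    .exportCell(sim, j, type)
  } else {
    halfAg <- sim$ag[i] / 2
    sim$ag[i] <- halfAg
    withStream(sim$streams$migration,
      .addCell(sim, parent = sim$id[i], clone = clone,
               x = sim$x[i], y = sim$y[i], z = sim$z[i],
               seqStr = sim$seq[i], aff = sim$aff[i],
               shapePos = sim$shapePos[i, ],
               p = sim$p[i], b = sim$b[i], r = sim$r[i],
               ag = halfAg, cycleT = cfg$cycleTime,
               divLeft = sim$divLeft[i], recycled = sim$recycled[i]))
    ## SHM in both post-division cells, once switched on; mutate by id since
    ## a lethal outcome removes the cell and shifts later indices
    if (sim$t >= cfg$shmStart) {
      motherId <- sim$id[i]
      daughterId <- sim$id[length(sim$id)]
      for (cid in c(daughterId, motherId)) {
        k <- match(cid, sim$id)
        if (!is.na(k)) .mutateCell(sim, k)
      }
    }
  }
}

.mutateCell <- function(sim, k) {
  cfg <- sim$cfg
  clone <- sim$clone[k]
  res <- applySHM(sim$seq[k], sim$cloneRegions[[clone]],
                  sim$cloneFrame[clone], sim$shapePos[k, ], sim$aff[k],
                  cfg$fateTree, sim$registry, cfg$shape,
                  lambda = cfg$shmLambda, rng = sim$streams$shm)
  sim$seq[k] <- res$sequence
  sim$shapePos[k, ] <- res$position
  sim$aff[k] <- res$affinity
  sim$lin_aff[sim$id[k]] <- res$affinity
  if (res$apoptosis) .removeCells(sim, k, "apoptosis")
}

.exportCell <- function(sim, idx, type) {
  m <- length(sim$oc_id) + 1L
  sim$oc_id[m] <- sim$id[idx]
  sim$oc_clone[m] <- sim$clone[idx]
  sim$oc_type[m] <- type
  sim$oc_seq[m] <- sim$seq[idx]
  sim$oc_aff[m] <- sim$aff[idx]
  sim$oc_time[m] <- sim$t
  sim$exported <- sim$exported + 1L
  sim$lin_fate[sim$id[idx]] <- paste0("exported_", type)
  .dropRows(sim, idx)
}

.removeCells <- function(sim, idx, fate) {
  sim$apoptosed <- sim$apoptosed + length(idx)
  sim$lin_fate[sim$id[idx]] <- fate
  .dropRows(sim, idx)
}

.dropRows <- function(sim, idx) {
  keep <- setdiff(seq_along(sim$id), idx)
  for (f in c("id", "clone", "state", "x", "y", "z", "dx", "dy", "dz",
              "seq", "aff", "p", "b", "r", "ag", "cycleT", "divLeft",
              "ccTimer", "sigBCR", "sigCD40", "intSig", "recycled")) {
    sim[[f]] <- sim[[f]][keep]
  }
  sim$shapePos <- sim$shapePos[keep, , drop = FALSE]
}

.recordTimepoint <- function(sim) {
  n <- length(sim$id)
  live <- n > 0L
  sim$ts[[length(sim$ts) + 1L]] <- data.frame(
    t = sim$t,
    cells = n,
    cb = sum(sim$state == "CB"),
    cc = sum(sim$state %in% c("CC", "selCC")),
    dz = sum(sim$z <= 0),
    lz = sum(sim$z > 0),
    dzlz = if (live && any(sim$z > 0)) sum(sim$z <= 0) / sum(sim$z > 0)
           else NA_real_,
    mean_affinity = if (live) mean(sim$aff) else NA_real_,
    median_affinity = if (live) median(sim$aff) else NA_real_,
    clones = length(unique(sim$clone)),
    subclones = length(unique(sim$seq)),
    created = sim$created, apoptosed = sim$apoptosed,
    exported = sim$exported)
}

#' Run a germinal-center simulation
#'
#' Executes [gcStep()] for every time step of the configured horizon and
#' assembles a [GCSimResult-class]: population time series, the live cells
#' at the end, the exported output cells, the complete lineage forest, and
#' the sequence-affinity registry snapshot. Two runs with the same seed and
#' configuration are identical.
#'
#' @param cfg a [gcConfig()] (use [smokeConfig()] for a fast exerciser).
#' @param seed integer master seed.
#' @param checkConservation if `TRUE`, verify at every recorded timepoint
#'   that live + exported + apoptosed cells equal all cells ever created.
#' @return a [GCSimResult-class].
#' @examples
#' \donttest{
#' res <- runGC(smokeConfig(duration = 24), seed = 1)
#' res
#' }
#' @export
runGC <- function(cfg = gcConfig(), seed = 1L, checkConservation = TRUE) {
  sim <- .newSimState(cfg, seed)
  nStep <- round(cfg$duration / cfg$dt)
  recEvery <- max(1L, round(cfg$recordEvery / cfg$dt))
  .recordTimepoint(sim)
  for (s in seq_len(nStep)) {
    gcStep(sim)
    if (s %% recEvery == 0L || s == nStep) {
      .recordTimepoint(sim)
      if (checkConservation &&
          length(sim$id) + sim$exported + sim$apoptosed != sim$created)
        stop("cell conservation violated at t = ", sim$t)
    }
  }
  .simResult(sim)
}

.simResult <- function(sim) {
  ids <- seq_len(sim$nextId - 1L)
  lineage <- data.frame(
    id = ids,
    parent = if (length(ids)) sim$lin_parent[ids] else integer(0),
    clone_id = if (length(ids)) sim$lin_clone[ids] else integer(0),
    birth = if (length(ids)) sim$lin_birth[ids] else numeric(0),
    affinity = if (length(ids)) sim$lin_aff[ids] else numeric(0),
    fate = if (length(ids)) sim$lin_fate[ids] else character(0))
  cells <- data.frame(
    cell_id = sim$id, clone_id = sim$clone, state = sim$state,
    zone = ifelse(sim$z > 0, "LZ", "DZ"),
    sequence = sim$seq, affinity = sim$aff,
    p = sim$p, b = sim$b, r = sim$r, retained_ag = sim$ag,
    stringsAsFactors = FALSE)
  ocs <- data.frame(
    cell_id = sim$oc_id, clone_id = sim$oc_clone, type = sim$oc_type,
    sequence = sim$oc_seq, affinity = sim$oc_aff,
    export_time = sim$oc_time, stringsAsFactors = FALSE)
  new("GCSimResult",
      config = unclass(sim$cfg), seed = sim$seed,
      timeSeries = do.call(rbind, sim$ts),
      cells = cells, outputCells = ocs, lineage = lineage,
      registry = registrySnapshot(sim$registry),
      counters = c(created = sim$created, apoptosed = sim$apoptosed,
                   exported = sim$exported))
}

#' Export the lineage forest as Newick trees
#'
#' Writes one Newick file per founder clone (`clone_<k>.nwk`), with node
#' labels `c<id>` and branch lengths equal to birth-time differences, plus a
#' node-attribute TSV (`lineage_nodes.tsv`: id, parent, clone, birth time,
#' affinity, fate) covering every cell ever created. Trees with at least two
#' nodes re-parse with [ape::read.tree()] to the same parent/child
#' relations.
#'
#' @param result a [GCSimResult-class].
#' @param dir output directory (created if needed).
#' @return character vector of the Newick paths, invisibly.
#' @export
exportLineageForest <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lin <- result@lineage
  write.table(lin, file.path(dir, "lineage_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths <- character(0)
  endTime <- result@config$duration
  for (cl in sort(unique(lin$clone_id))) {
    sub <- lin[lin$clone_id == cl, , drop = FALSE]
    children <- split(sub$id, factor(sub$parent, levels = sub$id))
    root <- sub$id[sub$parent == 0L]
    stopifnot(length(root) == 1L)
    buildNode <- function(id, parentBirth) {
      kids <- children[[as.character(id)]]
      myBirth <- sub$birth[match(id, sub$id)]
      lab <- sprintf("c%d:%g", id, myBirth - parentBirth)
      if (is.null(kids) || length(kids) == 0L) return(lab)
      paste0("(", paste(vapply(kids, buildNode, character(1),
                               parentBirth = myBirth), collapse = ","),
             ")", lab)
    }
    nwk <- paste0(buildNode(root, sub$birth[match(root, sub$id)]), ";")
    path <- file.path(dir, sprintf("clone_%d.nwk", cl))
    writeLines(nwk, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
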