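## Continuous 4-D shape space: BcR and antigen positions, L1 metric,
## Gaussian affinity weight, and the SHM-driven random walk.

#' Shape-space configuration
#'
#' The shape space is a continuous box of side `extent` (arbitrary units)
#' per dimension. The antigen sits at a fixed position (default: the box
#' centre) and a BcR's affinity is a Gaussian weight of its L1 (Manhattan)
#' distance to the antigen, so affinity is 1 at the antigen and decays
#' towards 0 with distance. Somatic hypermutations that change affinity move
#' the BcR by one signed step in one randomly chosen dimension, with step
#' magnitude ~ Normal(`stepMean`, `stepSd`).
#'
#' The width `gamma` defaults to 2.8, jointly consistent with the founder
#' anchor: distance 6 maps to affinity ~0.01.
#'
#' @param dimensions number of dimensions (default 4).
#' @param extent per-dimension side length (default 10).
#' @param antigen antigen position (default the centre of the box).
#' @param gamma Gaussian width, > 0.
#' @param stepMean,stepSd step-magnitude distribution parameters.
#' @return a classed list of settings.
#' @export
shapeSpaceConfig <- function(dimensions = 4L, extent = 10,
                             antigen = rep(extent / 2, dimensions),
                             gamma = 2.8, stepMean = 1, stepSd = 0.1) {
  stopifnot(dimensions >= 1, extent > 0, gamma > 0, stepSd >= 0,
            length(antigen) == dimensions,
            all(antigen >= 0 & antigen <= extent))
  structure(list(dimensions = as.integer(dimensions), extent = extent,
                 antigen = as.numeric(antigen), gamma = gamma,
                 stepMean = stepMean, stepSd = stepSd),
            class = "shape_space_config")
}

#' L1 (Manhattan) distance between two shape-space positions
#'
#' @param pos,antigen numeric coordinate vectors of equal length.
#' @return sum of absolute coordinate differences.
#' @examples
#' l1Distance(c(1, 2, 0, 0), c(0, 0, 0, 0))  # 3
#' @export
l1Distance <- function(pos, antigen) {
  if (length(pos) != length(antigen))
    stop("dimension mismatch: ", length(pos), " vs ", length(antigen))
  sum(abs(pos - antigen))
}

#' Gaussian affinity weight of a shape-space distance
#'
#' Converts the L1 distance `d` between BcR and antigen to an affinity in
#' (0, 1]: `a(d) = exp(-(d / gamma)^2)`. Strictly decreasing in `d`, equal
#' to 1 at the antigen.
#'
#' @param d distance, >= 0.
#' @param gamma Gaussian width, > 0.
#' @return affinity in (0, 1].
#' @examples
#' affinityFromDistance(0, 2.8)        # 1
#' affinityFromDistance(6, 2.8)        # ~0.01, the founder anchor
#' @export
affinityFromDistance <- function(d, gamma = 2.8) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (any(d < 0)) stop("distance must be >= 0")
  exp(-(d / gamma)^2)
}

#' Move a BcR one SHM step through shape space
#'
#' Exactly one coordinate, chosen uniformly at random, changes by a signed
#' step: magnitude ~ Normal(`stepMean`, `stepSd`) (negative magnitude draws
#' re-sampled), sign equiprobable and independent of position, so a step may
#' increase or decrease the distance to the antigen. Coordinates clamp to
#' `[0, extent]` (the step truncates at the wall).
#'
#' @param pos current coordinate vector.
#' @param cfg a [shapeSpaceConfig()].
#' @param rng optional [newRngStream()] stream.
#' @return the new position.
#' @export
mutatePosition <- function(pos, cfg, rng = NULL) {
  stopifnot(length(pos) == cfg$dimensions, all(is.finite(pos)))
  draw <- function() {
    dim <- sample.int(cfg$dimensions, 1L)
    mag <- rnorm(1L, cfg$stepMean, cfg$stepSd)
    while (mag < 0) mag <- rnorm(1L, cfg$stepMean, cfg$stepSd)
    sgn <- if (runif(1L) < 0.5) -1 else 1
    c(dim, sgn * mag)
  }
  dm <- if (is.null(rng)) draw() else withStream(rng, draw())
  pos[dm[1L]] <- min(max(pos[dm[1L]] + dm[2L], 0), cfg$extent)
  pos
}

#' Place a position at a given L1 distance from the antigen
#'
#' Used to seed founder B cells at a configured distance (default 6, i.e.
#' affinity ~0.01 at the default width). The distance is split uniformly at
#' random over the dimensions (a uniform draw on the L1 simplex) with
#' equiprobable signs; draws leaving the box are rejected and re-sampled so
#' the requested distance is exact.
#'
#' @param d target L1 distance from the antigen.
#' @param cfg a [shapeSpaceConfig()].
#' @param rng optional [newRngStream()] stream.
#' @return a coordinate vector at L1 distance `d` from `cfg$antigen`.
#' @export
positionAtDistance <- function(d, cfg, rng = NULL) {
  stopifnot(d >= 0, d <= cfg$dimensions * cfg$extent / 2)
  draw <- function() {
    repeat {
      w <- -log(runif(cfg$dimensions))
      off <- d * w / sum(w) * sign(runif(cfg$dimensions) - 0.5)
      pos <- cfg$antigen + off
      if (all(pos >= 0 & pos <= cfg$extent)) return(pos)
    }
  }
  if (is.null(rng)) draw() else withStream(rng, draw())
}
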