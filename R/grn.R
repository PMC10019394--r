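## Per-cell BLIMP1 (p) / BCL6 (b) / IRF4 (r) regulatory network with BCR and
## CD40 inputs, integrated with a fixed-step classical Runge-Kutta scheme.
## Concentrations in M, time in hours. All functions are vectorised over
## cells so the whole population advances in one call.

#' GRN parameters
#'
#' Kinetic parameters of the bistable BLIMP1/BCL6/IRF4 core network:
#' basal transcription rates `mu_*` (M/h), induced maximal rates `sigma_*`
#' (M/h), shared dissociation constants `k_*` (M), first-order decay rates
#' `lambda_*` (1/h), the BCR/CD40 signal scales `bcr0` (1/h) and `cd0`
#' (M/h), and the plasma-cell threshold `thetaPC` on BLIMP1 (default
#' 8e-8 M). Defaults follow the published bistable parameterisation of this
#' network (dissociation constants 1e-8 M, unit decay rates), with signal
#' scales chosen inside its bistable regime; ship as data, override freely.
#'
#' @param ... named overrides of any default.
#' @return a classed list of parameters.
#' @examples
#' p <- grnParameters()
#' p$thetaPC
#' @export
grnParameters <- function(...) {
  par <- list(
    mu_p = 1e-14, mu_b = 2e-8, mu_r = 1e-9,
    sigma_p = 9e-8, sigma_b = 1e-6, sigma_r = 2.6e-8,
    k_p = 1e-8, k_b = 1e-8, k_r = 1e-8,
    lambda_p = 1, lambda_b = 1, lambda_r = 1,
    bcr0 = 15, cd0 = 5e-7,
    thetaPC = 8e-8,
    timeScale = 1)  # GRN-hours per ABM-hour
  ov <- list(...)
  bad <- setdiff(names(ov), names(par))
  if (length(bad)) stop("unknown GRN parameter(s): ", paste(bad, collapse = ", "))
  par[names(ov)] <- ov
  if (any(unlist(par) <= 0))
    stop("all GRN parameters must be strictly positive")
  structure(par, class = "grn_parameters")
}

#' BCR signalling strength
#'
#' Signal delivered while a centrocyte captures FDC-presented antigen:
#' `BCR = bcr0 * k_b^2 / (k_b^2 + b^2)`, i.e. maximal at low BCL6 and
#' half-saturated at `b = k_b`. Enters the BCL6 equation as extra decay.
#'
#' @param b BCL6 concentration(s), >= 0.
#' @param bcr0 signal scale.
#' @param k_b BCL6 dissociation constant.
#' @return signal value(s), >= 0.
#' @export
bcrSignal <- function(b, bcr0, k_b) {
  stopifnot(all(b >= 0))
  bcr0 * k_b^2 / (k_b^2 + b^2)
}

#' CD40 signalling strength
#'
#' Signal delivered during Tfh contact, scaled linearly by the BcR affinity
#' of the presented antigen: `CD40 = affinity * cd0 * k_b^2 / (k_b^2 + b^2)`.
#' Zero affinity gives zero signal. Enters the IRF4 equation additively.
#'
#' @param b BCL6 concentration(s).
#' @param affinity BcR affinity in `[0, 1]`.
#' @param cd0 signal scale.
#' @param k_b BCL6 dissociation constant.
#' @return signal value(s), >= 0.
#' @export
cd40Signal <- function(b, affinity, cd0, k_b) {
  if (any(affinity < 0 | affinity > 1))
    stop("affinity must lie in [0, 1]")
  affinity * cd0 * k_b^2 / (k_b^2 + b^2)
}

#' GRN time derivatives
#'
#' The three-equation core network. BLIMP1 is induced by BCL6 de-repression
#' and by IRF4; BCL6 is repressed by BLIMP1, itself, and IRF4 jointly and
#' degraded faster under BCR signalling; IRF4 activates itself and
#' integrates the CD40 signal:
#' \deqn{dp/dt = mu_p + sigma_p k_b^2/(k_b^2+b^2) + sigma_p r^2/(k_r^2+r^2)
#'   - lambda_p p}
#' \deqn{db/dt = mu_b + sigma_b k_p^2/(k_p^2+p^2) k_b^2/(k_b^2+b^2)
#'   k_r^2/(k_r^2+r^2) - (lambda_b + BCR) b}
#' \deqn{dr/dt = mu_r + sigma_r r^2/(k_r^2+r^2) + CD40 - lambda_r r}
#'
#' @param p,b,r concentrations (vectors of equal length).
#' @param par a [grnParameters()] list.
#' @param BCR,CD40 signal values, >= 0 (scalar or per-cell).
#' @return list of `dp`, `db`, `dr`.
#' @export
grnDerivative <- function(p, b, r, par, BCR = 0, CD40 = 0) {
  stopifnot(all(BCR >= 0), all(CD40 >= 0))
  hb <- par$k_b^2 / (par$k_b^2 + b^2)
  hp <- par$k_p^2 / (par$k_p^2 + p^2)
  hr <- par$k_r^2 / (par$k_r^2 + r^2)
  ar <- r^2 / (par$k_r^2 + r^2)
  list(
    dp = par$mu_p + par$sigma_p * hb + par$sigma_p * ar - par$lambda_p * p,
    db = par$mu_b + par$sigma_b * hp * hb * hr - (par$lambda_b + BCR) * b,
    dr = par$mu_r + par$sigma_r * ar + CD40 - par$lambda_r * r)
}

#' Advance the GRN with fixed-step classical Runge-Kutta
#'
#' Fourth-order fixed-step integration of [grnDerivative()] with signals
#' held constant over the step (they are event-gated by the agent-based
#' layer at its own resolution). State components are floored at zero after
#' each step.
#'
#' @param p,b,r current concentrations (vectors of equal length).
#' @param par a [grnParameters()] list.
#' @param BCR,CD40 signal values held constant over the horizon.
#' @param dt step size in hours, > 0.
#' @param horizon total time to advance (default one step).
#' @return list of advanced `p`, `b`, `r`.
#' @export
integrateGRN <- function(p, b, r, par, BCR = 0, CD40 = 0, dt,
                         horizon = dt) {
  stopifnot(dt > 0, horizon >= dt - 1e-12)
  nStep <- max(1L, round(horizon / dt))
  h <- (horizon / nStep) * par$timeScale
  for (i in seq_len(nStep)) {
    k1 <- grnDerivative(p, b, r, par, BCR, CD40)
    k2 <- grnDerivative(p + h / 2 * k1$dp, b + h / 2 * k1$db,
                        r + h / 2 * k1$dr, par, BCR, CD40)
    k3 <- grnDerivative(p + h / 2 * k2$dp, b + h / 2 * k2$db,
                        r + h / 2 * k2$dr, par, BCR, CD40)
    k4 <- grnDerivative(p + h * k3$dp, b + h * k3$db, r + h * k3$dr,
                        par, BCR, CD40)
    p <- pmax(0, p + h / 6 * (k1$dp + 2 * k2$dp + 2 * k3$dp + k4$dp))
    b <- pmax(0, b + h / 6 * (k1$db + 2 * k2$db + 2 * k3$db + k4$db))
    r <- pmax(0, r + h / 6 * (k1$dr + 2 * k2$dr + 2 * k3$dr + k4$dr))
  }
  if (any(!is.finite(c(p, b, r))))
    stop("non-finite GRN state after integration (cell index ",
         which(!is.finite(p + b + r))[1L], ")")
  list(p = p, b = b, r = r)
}

#' Plasma-cell classification by BLIMP1 threshold
#'
#' A cell differentiates to a plasma cell when its BLIMP1 concentration has
#' reached the threshold: `p >= thetaPC` (inclusive; default 8e-8 M).
#'
#' @param p BLIMP1 concentration(s).
#' @param thetaPC threshold, > 0.
#' @return logical vector.
#' @export
classifyPC <- function(p, thetaPC = 8e-8) {
  stopifnot(thetaPC > 0)
  p >= thetaPC
}

#' Locate GRN fixed points by multi-start root search
#'
#' Damped Newton iteration (numerical Jacobian) from a grid of starting
#' states, de-duplicated; each root is labelled stable when all Jacobian
#' eigenvalues have negative real part. With default parameters and zero
#' signals the network is bistable: one BCL6-high/BLIMP1-low state and one
#' BLIMP1-high/BCL6-low state.
#'
#' @param par a [grnParameters()] list.
#' @param BCR,CD40 constant signal values.
#' @param starts optional matrix of starting states (columns p, b, r).
#' @return `data.frame` with columns `p`, `b`, `r`, `stable`.
#' @export
grnFixedPoints <- function(par, BCR = 0, CD40 = 0, starts = NULL) {
  f <- function(x) {
    d <- grnDerivative(x[1], x[2], x[3], par, BCR, CD40)
    c(d$dp, d$db, d$dr)
  }
  if (is.null(starts)) {
    g <- as.matrix(expand.grid(p = c(0.1, 1, 5, 10) * 1e-8,
                               b = c(0.1, 1, 5, 10) * 1e-8,
                               r = c(0.1, 1, 3) * 1e-8))
    starts <- g
  }
  scale <- 1e-8
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    x <- starts[i, ] / scale
    fs <- function(y) f(y * scale) / scale
    ok <- TRUE
    for (it in seq_len(200L)) {
      fx <- fs(x)
      if (sqrt(sum(fx^2)) < 1e-12) break
      J <- .numJacobian(fs, x)
      dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(dx)) { ok <- FALSE; break }
      step <- 1
      while (step > 1e-4 &&
             sqrt(sum(fs(pmax(x + step * dx, 0))^2)) > sqrt(sum(fx^2))) {
        step <- step / 2
      }
      x <- pmax(x + step * dx, 0)
    }
    if (ok && sqrt(sum(fs(x)^2)) < 1e-10) roots[[length(roots) + 1L]] <- x
  }
  if (length(roots) == 0L)
    return(data.frame(p = numeric(), b = numeric(), r = numeric(),
                      stable = logical()))
  rootMat <- unique(round(do.call(rbind, roots), 6))
  out <- data.frame(p = rootMat[, 1] * scale, b = rootMat[, 2] * scale,
                    r = rootMat[, 3] * scale)
  out$stable <- vapply(seq_len(nrow(out)), function(i) {
    J <- .numJacobian(f, c(out$p[i], out$b[i], out$r[i]), h = 1e-14)
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }, logical(1))
  out
}

.numJacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dx <- numeric(n)
    dx[j] <- h * max(1, abs(x[j]))
    J[, j] <- (f(x + dx) - f(x - dx)) / (2 * dx[j])
  }
  J
}
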