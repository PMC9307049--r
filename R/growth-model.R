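#' Construct growth-model parameters
#'
#' @param k tip production flux at the root interface (tips cm^-2 s^-1)
#' @param v tip elongation speed (cm s^-1), must be positive
#' @param b_branch net branching rate b (s^-1)
#' @param d net length destruction rate (s^-1)
#' @return a validated [GrowthParams-class]
#' @examples
#' growthParams(k = 1e-4, v = 2e-5, b_branch = 5e-6)
#' @export
growthParams <- function(k = 0, v = 1e-5, b_branch = 0, d = 0) {
  if (length(v) != 1L || !is.finite(v) || v <= 0) {
    stop(errorCondition("'v' must be a positive finite scalar",
                        class = c("mycouptake_invalid_parameter", "mycouptake_error")))
  }
  new("GrowthParams", k = as.numeric(k), v = as.numeric(v),
      b_branch = as.numeric(b_branch), d = as.numeric(d))
}

#' Construct an observation set of hyphal length densities
#'
#' @param position_cm distances from the root-compartment interface (cm)
#' @param time_s times since transplanting (s)
#' @param replicate replicate identifiers
#' @param rho_cm2 observed hyphal length densities (cm hyphae cm^-3 soil)
#' @param sd_cm2 optional per-record standard deviations
#' @param truth optional planted-truth list (synthetic data)
#' @return an [ObservationSet-class]
#' @export
observationSet <- function(position_cm, time_s, replicate, rho_cm2,
                           sd_cm2 = NULL, truth = list()) {
  rec <- data.frame(position_cm = as.numeric(position_cm),
                    time_s = as.numeric(time_s),
                    replicate = replicate,
                    rho_cm2 = as.numeric(rho_cm2))
  if (!is.null(sd_cm2)) rec$sd_cm2 <- as.numeric(sd_cm2)
  new("ObservationSet", records = rec, truth = truth)
}

#' Read / write observation sets as CSV
#'
#' The CSV contract: header row with columns `position_cm`, `time_s`,
#' `replicate`, `rho_cm2` and optionally `sd_cm2`. Unit conversions
#' (mm to cm, weeks to s) belong to the caller, not to the model code.
#'
#' @param path file path
#' @return [ObservationSet-class] (reader) or invisibly `path` (writer)
#' @export
readObservationSet <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("position_cm", "time_s", "replicate", "rho_cm2")
  .assert(all(need %in% names(rec)),
          sprintf("CSV must contain columns %s", paste(need, collapse = ", ")),
          "mycouptake_invalid_format")
  new("ObservationSet", records = rec)
}

#' @rdname readObservationSet
#' @param obs an [ObservationSet-class]
#' @export
writeObservationSet <- function(obs, path) {
  stopifnot(is(obs, "ObservationSet"))
  write.csv(obs@records, path, row.names = FALSE)
  invisible(path)
}

.check_grids <- function(x_grid, t_grid) {
  .assert(.is_ascending(x_grid) && all(x_grid >= 0),
          "'x_grid' must be non-empty, strictly ascending and >= 0",
          "mycouptake_invalid_grid")
  .assert(.is_ascending(t_grid),
          "'t_grid' must be non-empty and strictly ascending",
          "mycouptake_invalid_grid")
}

# Characteristic solution at arbitrary (x, t) pairs (vectorised).
# Behind the front (x < v t):
#   n   = (k/v) exp(b x / v)                      [flux condition v n(0,t) = k]
#   rho = n v / d (1 - exp(-d (t - x/v)))  (d > 0)
#   rho = n v (t - x/v)                    (d = 0)
# Ahead of the front both vanish (zero initial condition).
.growth_closed_form <- function(params, x, t) {
  k <- params@k; v <- params@v; b <- params@b_branch; d <- params@d
  behind <- x < v * t
  n <- ifelse(behind, (k / v) * exp(b * x / v), 0)
  age <- pmax(t - x / v, 0)
  rho <- if (d > 0) {
    n * v / d * (1 - exp(-d * age))
  } else {
    n * v * age
  }
  rho[!behind] <- 0
  list(n = n, rho = rho)
}

#' Closed-form growth solution (method of characteristics)
#'
#' Solves the tip/length-density system exactly on the characteristics: the
#' tip wave travels at speed `v` from the root interface, amplified by the
#' branching factor `exp(b x / v)`, while length accumulates locally at
#' rate `n v` and decays at rate `d`.
#'
#' @param params a [GrowthParams-class]
#' @param x_grid ascending distances (cm), >= 0
#' @param t_grid ascending times (s)
#' @return a [GrowthSolution-class]
#' @examples
#' sol <- solveGrowthClosedForm(growthParams(k = 1, v = 1), 0:3, 0:3)
#' lengthDensity(sol)[1, ]   # linear accumulation k t at the interface
#' @export
solveGrowthClosedForm <- function(params, x_grid, t_grid) {
  stopifnot(is(params, "GrowthParams"))
  validObject(params)
  .check_grids(x_grid, t_grid)
  nx <- length(x_grid); nt <- length(t_grid)
  xx <- matrix(x_grid, nx, nt)
  tt <- matrix(t_grid, nx, nt, byrow = TRUE)
  cf <- .growth_closed_form(params, xx, tt)
  new("GrowthSolution", x_grid = as.numeric(x_grid), t_grid = as.numeric(t_grid),
      n = matrix(cf$n, nx, nt), rho = matrix(cf$rho, nx, nt), params = params)
}

#' First-order upwind numeric growth solution
#'
#' Finite-difference cross-check of [solveGrowthClosedForm()]: explicit
#' upwind advection of the tip density with source `b n` and inflow
#' `n(0) = k / v`, plus a length-density update that is implicit in the
#' decay term so `d > 0` never destabilises. The solver marches at the
#' fixed internal step `cfl_fraction * dx / v` — at the default unit CFL
#' the transport part of upwind is exact and the colonisation front stays
#' sharp — and interpolates the marched states linearly onto the
#' requested output times, re-imposing the causality constraint
#' `n = rho = 0` ahead of `x = v t`. Supplied `t_grid`s can never violate
#' stability; the internal step, not the output grid, controls it.
#'
#' @inheritParams solveGrowthClosedForm
#' @param cfl_fraction fraction of the CFL limit `dx / v` used as the
#'   internal marching step, in (0, 1]; 1 (default) advects exactly
#' @return a [GrowthSolution-class] on the supplied grids
#' @export
solveGrowthNumeric <- function(params, x_grid, t_grid, cfl_fraction = 1) {
  stopifnot(is(params, "GrowthParams"))
  validObject(params)
  .check_grids(x_grid, t_grid)
  .assert(cfl_fraction > 0 && cfl_fraction <= 1,
          "'cfl_fraction' must lie in (0, 1]", "mycouptake_invalid_parameter")
  k <- params@k; v <- params@v; b <- params@b_branch; d <- params@d
  nx <- length(x_grid); nt <- length(t_grid)
  dxs <- diff(x_grid)
  .assert(length(dxs) == 0L || diff(range(dxs)) <= 1e-9 * max(dxs),
          "'x_grid' must be uniform for the upwind solver",
          "mycouptake_invalid_grid")
  dx <- if (nx > 1L) dxs[1L] else x_grid[1L] + 1
  dt <- cfl_fraction * dx / v
  nu <- v * dt / dx                       # Courant number (= cfl_fraction)

  n_out <- matrix(0, nx, nt)
  rho_out <- matrix(0, nx, nt)
  # march from t = 0 (zero initial condition); negative t outputs stay 0
  n <- numeric(nx); rho <- numeric(nx)
  t_m <- 0
  out_idx <- which(t_grid > 0)
  pending <- if (length(out_idx)) out_idx[order(t_grid[out_idx])] else integer()
  t_end <- if (length(pending)) max(t_grid) else 0
  interp_out <- function(m, n_prev, rho_prev, n_cur, rho_cur, t_prev, t_cur) {
    wgt <- if (t_cur > t_prev) (t_grid[m] - t_prev) / (t_cur - t_prev) else 0
    ni <- (1 - wgt) * n_prev + wgt * n_cur
    ri <- (1 - wgt) * rho_prev + wgt * rho_cur
    ahead <- x_grid >= v * t_grid[m]
    ni[ahead] <- 0; ri[ahead] <- 0
    n_out[, m] <<- ni; rho_out[, m] <<- ri
  }
  while (t_m < t_end && length(pending)) {
    n_prev <- n; rho_prev <- rho; t_prev <- t_m
    n_new <- n
    n_new[1L] <- k / v                    # inflow boundary: v n(0, t) = k
    if (nx > 1L) {
      idx <- 2:nx
      n_new[idx] <- (n[idx] - nu * (n[idx] - n[idx - 1L])) * (1 + dt * b)
    }
    n_new <- pmax(n_new, 0)
    # trapezoidal source, implicit decay
    rho <- (rho * (1 - dt * d / 2) + dt / 2 * v * (n + n_new)) /
      (1 + dt * d / 2)
    n <- n_new
    t_m <- t_m + dt
    while (length(pending) && t_grid[pending[1L]] <= t_m + 1e-12 * dt) {
      interp_out(pending[1L], n_prev, rho_prev, n, rho, t_prev, t_m)
      pending <- pending[-1L]
    }
  }
  if (k == 0) { n_out[] <- 0; rho_out[] <- 0 }
  new("GrowthSolution", x_grid = as.numeric(x_grid), t_grid = as.numeric(t_grid),
      n = n_out, rho = pmax(rho_out, 0), params = params)
}

#' Predicted length densities at an observation design
#'
#' Evaluates the closed-form model at each `(position, time)` record of an
#' observation set. Records at `t = 0` return 0 (the zero initial
#' condition) with a warning.
#'
#' @param params a [GrowthParams-class]
#' @param obs an [ObservationSet-class]
#' @return numeric vector of predicted `rho` (cm^-2), one per record
#' @export
evaluateAt <- function(params, obs) {
  stopifnot(is(params, "GrowthParams"), is(obs, "ObservationSet"))
  validObject(obs)
  rec <- obs@records
  if (any(rec$time_s == 0)) {
    warning("records at t = 0 evaluate to 0 (zero initial condition)")
  }
  .growth_closed_form(params, rec$position_cm, rec$time_s)$rho
}

#' Write a growth solution as long-format CSV
#'
#' Columns `x_cm`, `t_s`, `n`, `rho`, one row per grid point.
#'
#' @param sol a [GrowthSolution-class]
#' @param path output file
#' @export
writeGrowthSolution <- function(sol, path) {
  stopifnot(is(sol, "GrowthSolution"))
  grid <- expand.grid(x_cm = sol@x_grid, t_s = sol@t_grid)
  grid$n <- as.vector(sol@n)
  grid$rho <- as.vector(sol@rho)
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
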