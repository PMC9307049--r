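# Run expr with a temporary, restored RNG state so fits are deterministic
# given `seed` without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Default parameter bounds: bracket all reported magnitudes by >= 10x.
.default_growth_bounds <- function() {
  list(lower = c(k = 1e-6, v = 1e-7, b_branch = 0, d = 0),
       upper = c(k = 1e-2, v = 1e-3, b_branch = 1e-4, d = 1e-4))
}

# Map between natural and optimiser space: log10 for strictly positive
# parameters, upper-bound-scaled linear for those with a zero lower bound.
.par_transform <- function(bounds, free) {
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  log_scale <- lo > 0
  list(
    free = free, log_scale = log_scale,
    lower_t = ifelse(log_scale, log10(lo), lo / hi),
    upper_t = ifelse(log_scale, log10(hi), 1),
    to_nat = function(u) {
      th <- ifelse(log_scale, 10^u, u * hi)
      names(th) <- free
      th
    },
    to_opt = function(th) {
      u <- ifelse(log_scale, log10(pmax(th, 1e-300)), th / hi)
      names(u) <- free
      u
    })
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with `SS_tot` taken about the observation mean.
#' Errors when the observations have zero variance (R^2 undefined).
#'
#' @param model_values model predictions
#' @param obs_values observations, same length (>= 2)
#' @return scalar R^2 (<= 1, can be negative for a bad model)
#' @examples
#' rSquared(c(1, 2, 4), c(1, 2, 3))   # 0.5
#' @export
rSquared <- function(model_values, obs_values) {
  .assert(length(model_values) == length(obs_values) && length(obs_values) >= 2,
          "need equal-length vectors of at least 2 values",
          "mycouptake_invalid_parameter")
  ss_tot <- sum((obs_values - mean(obs_values))^2)
  .assert(ss_tot > 0, "R^2 undefined: observations have zero variance",
          "mycouptake_degenerate_data")
  1 - sum((obs_values - model_values)^2) / ss_tot
}

#' Fit growth parameters to length-density observations
#'
#' Bounded least squares on \eqn{\sum (\rho_{model} - \rho_{obs})^2} using
#' Levenberg-Marquardt local fits launched from `n_starts` log-uniform
#' starting points inside the bounds (multi-modality is real on sparse
#' designs). Deterministic given `seed`. The Gauss-Newton approximation at
#' the best optimum is used to flag near-flat (poorly identified)
#' directions via its condition number.
#'
#' @param obs an [ObservationSet-class]
#' @param bounds list with named `lower` and `upper` vectors over
#'   `k, v, b_branch, d`; defaults bracket reported magnitudes by >= 10x
#' @param fix_d fix the destruction rate at 0 (default) instead of
#'   fitting it
#' @param n_starts number of multi-start initialisations
#' @param seed integer seed driving the starts
#' @return a [FitResult-class]; `diagnostics$starts` records every start's
#'   endpoint, `diagnostics$identifiability_warning` flags ill conditioning
#' @export
fitGrowth <- function(obs, bounds = .default_growth_bounds(), fix_d = TRUE,
                      n_starts = 16L, seed = 1L) {
  stopifnot(is(obs, "ObservationSet"))
  validObject(obs)
  rec <- obs@records
  .assert(any(rec$rho_cm2 > 0),
          "all observed densities are zero: growth parameters are not identifiable",
          "mycouptake_degenerate_data")
  free <- c("k", "v", "b_branch", if (!fix_d) "d")
  .assert(sum(rec$time_s > 0) >= length(free),
          "need at least as many informative records as free parameters",
          "mycouptake_degenerate_data")
  .assert(all(is.finite(bounds$lower[free])) && all(is.finite(bounds$upper[free])),
          "bounds must be finite for every free parameter",
          "mycouptake_invalid_parameter")
  tr <- .par_transform(bounds, free)

  resid_fun <- function(u) {
    th <- tr$to_nat(u)
    p <- growthParams(k = th[["k"]], v = th[["v"]], b_branch = th[["b_branch"]],
                      d = if (fix_d) 0 else th[["d"]])
    .growth_closed_form(p, rec$position_cm, rec$time_s)$rho - rec$rho_cm2
  }

  starts <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      u <- runif(length(free))
      tr$lower_t + u * (tr$upper_t - tr$lower_t)
    })
  })

  runs <- lapply(starts, function(u0) {
    tryCatch(
      minpack.lm::nls.lm(par = u0, lower = tr$lower_t, upper = tr$upper_t,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    stop(errorCondition(
      sprintf("all %d starts failed to converge; check bounds and data scale",
              n_starts),
      class = c("mycouptake_nonconvergence", "mycouptake_error")))
  }
  rss <- vapply(runs, function(r) if (is.null(r)) Inf else r$deviance, numeric(1))
  best <- runs[[which.min(rss)]]
  th <- tr$to_nat(best$par)
  if (fix_d) th <- c(th, d = 0)

  # identifiability: condition of J'J in the dimensionless optimiser space
  h <- best$hessian
  cond <- tryCatch({
    sv <- svd(h)$d
    sv <- sv[is.finite(sv)]
    if (length(sv) < ncol(h) || min(sv) <= 0) Inf else max(sv) / min(sv)
  }, error = function(e) Inf)
  model <- rec$rho_cm2 + resid_fun(best$par)
  r2 <- tryCatch(rSquared(model, rec$rho_cm2), error = function(e) NA_real_)

  start_tab <- data.frame(
    start = seq_len(n_starts), rss = rss,
    converged = vapply(runs, function(r) !is.null(r) && r$info %in% 1:4, logical(1)))
  new("FitResult",
      estimates = th[c(free, if (fix_d) "d")],
      objective = best$deviance, r2 = r2,
      n_starts = as.integer(n_starts),
      converged = best$info %in% 1:4,
      bounds = list(lower = bounds$lower[free], upper = bounds$upper[free]),
      seed = as.integer(seed),
      diagnostics = list(starts = start_tab, condition_number = cond,
                         identifiability_warning = is.finite(cond) && cond > 1e8 ||
                           !is.finite(cond),
                         fixed = if (fix_d) c(d = 0) else NULL))
}

#' Fit each replicate separately, then summarise
#'
#' Splits an observation set by its `replicate` column, fits each
#' replicate with [fitGrowth()] and returns the per-replicate fits. Use
#' [aggregateReplicates()] for the mean +/- SD summary; pooled fitting is
#' available by calling [fitGrowth()] on the full set.
#'
#' @inheritParams fitGrowth
#' @return list of [FitResult-class], named by replicate id
#' @export
fitGrowthReplicates <- function(obs, bounds = .default_growth_bounds(),
                                fix_d = TRUE, n_starts = 16L, seed = 1L) {
  rec <- records(obs)
  reps <- unique(rec$replicate)
  fits <- lapply(seq_along(reps), function(i) {
    sub <- new("ObservationSet", records = rec[rec$replicate == reps[i], ,
                                               drop = FALSE])
    fitGrowth(sub, bounds = bounds, fix_d = fix_d, n_starts = n_starts,
              seed = seed + i - 1L)
  })
  names(fits) <- as.character(reps)
  fits
}

#' Aggregate replicate fits into mean +/- SD
#'
#' @param fits list of [FitResult-class] (>= 1), typically from
#'   [fitGrowthReplicates()]
#' @return an [AggregateFit-class] with per-parameter mean and sample SD
#'   (n - 1 denominator; 0 for a single fit or identical estimates)
#' @export
aggregateReplicates <- function(fits) {
  .assert(length(fits) >= 1L && all(vapply(fits, is, logical(1), "FitResult")),
          "'fits' must be a non-empty list of FitResult objects",
          "mycouptake_invalid_parameter")
  pars <- names(estimates(fits[[1L]]))
  tab <- do.call(rbind, lapply(fits, function(f) estimates(f)[pars]))
  tab <- as.data.frame(tab)
  tab$r2 <- vapply(fits, function(f) f@r2, numeric(1))
  mu <- vapply(c(pars, "r2"), function(p) mean(tab[[p]]), numeric(1))
  s <- vapply(c(pars, "r2"), function(p) {
    if (nrow(tab) > 1L) sd(tab[[p]]) else 0
  }, numeric(1))
  new("AggregateFit", mean = mu, sd = s, replicates = tab)
}

#' Render "mean +/- SD" in scientific table style
#'
#' @param mean,sd scalars
#' @param digits significant digits for the mantissas
#' @return string such as `"4.66 x 10-4 +/- 1.76 x 10-4"`
#' @export
formatMeanSD <- function(mean, sd, digits = 3) {
  one <- function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v == 0) return("0")
    e <- floor(log10(abs(v)))
    m <- signif(v / 10^e, digits)
    sprintf("%g x 10%+d", m, e)
  }
  sprintf("%s +/- %s", one(mean), one(sd))
}

#' Fit the hyphal P-uptake rate to a depletion profile
#'
#' One-parameter bounded least squares for `lambda_h`: the forward model is
#' [solveUptake()] driven by the supplied hyphal length-density field, and
#' the objective is \eqn{\sum (c_{model}/c_\infty - c_{obs})^2} over the
#' profile positions at the final time. Because X-ray fluorescence maps are
#' in raw counts, profiles must be normalised to the far field
#' (`c / c_inf`). A coarse log-spaced scan (plus `lambda_h = 0`) brackets
#' the optimum, which is then refined by golden-section/parabolic search,
#' making the fit deterministic.
#'
#' Only the product `r_m * lambda_h` is identified; the returned result
#' records `r_m` in its diagnostics and doubling `r_m` halves the estimate.
#'
#' @param p_obs data.frame with columns `x_cm` and `c_rel` (relative total
#'   P at the final time)
#' @param rho_field scalar, `function(x, t)` or [GrowthSolution-class]
#' @param uparams an [UptakeParams-class]; `lambda_h` is ignored (free)
#' @param t_final final time (s) at which the profile was measured
#' @param lambda_upper upper bound for `lambda_h` (cm s^-1)
#' @param x_grid,nt solver grid controls (defaults match [genPProfile()])
#' @return a [FitResult-class] with estimate `lambda_h`
#' @export
fitUptake <- function(p_obs, rho_field, uparams, t_final,
                      lambda_upper = 1e-3,
                      x_grid = seq(0, 4.5, length.out = 361L), nt = 60L) {
  .assert(is.data.frame(p_obs) && all(c("x_cm", "c_rel") %in% names(p_obs)),
          "'p_obs' needs columns x_cm and c_rel", "mycouptake_invalid_parameter")
  .assert(t_final > 0, "'t_final' must be > 0", "mycouptake_invalid_parameter")
  t_grid <- seq(0, t_final, length.out = nt)
  rho_max <- max(.rho_at(rho_field, x_grid, t_final))
  .assert(rho_max > 0,
          "rho is identically zero: lambda_h is unidentifiable",
          "mycouptake_unidentifiable")
  if (all(p_obs$c_rel > 1 + 1e-6)) {
    warning("profile exceeds the far field everywhere: no depletion signal")
  }

  sse <- function(lambda) {
    up <- uptakeParams(D_eff = uparams@D_eff, r_m = uparams@r_m,
                       lambda_h = lambda, F_max = uparams@F_max,
                       c_inf = uparams@c_inf, theta = uparams@theta,
                       b_buffer = uparams@b_buffer)
    # the scan legitimately probes extreme lambda where the grid would be
    # under-resolved; the resolution warning stays for direct solver use
    sol <- suppressWarnings(solveUptake(up, rho_field, x_grid, t_grid))
    prof <- approx(sol@x_grid, sol@c_tot[, nt] / uparams@c_inf,
                   xout = p_obs$x_cm, rule = 2)$y
    sum((prof - p_obs$c_rel)^2)
  }

  grid <- c(0, 10^seq(-10, log10(lambda_upper), length.out = 25L))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  est <- if (i == 1L && vals[1L] <= vals[2L]) {
    list(minimum = 0, objective = vals[1L])
  } else {
    optimize(sse, lower = lo, upper = hi, tol = max(1e-12, 1e-6 * hi))
  }
  model_rss <- est$objective
  # model values at the optimum, for R^2
  up <- uptakeParams(D_eff = uparams@D_eff, r_m = uparams@r_m,
                     lambda_h = est$minimum, F_max = uparams@F_max,
                     c_inf = uparams@c_inf)
  sol <- solveUptake(up, rho_field, x_grid, t_grid)
  prof <- approx(sol@x_grid, sol@c_tot[, nt] / uparams@c_inf,
                 xout = p_obs$x_cm, rule = 2)$y
  r2 <- tryCatch(rSquared(prof, p_obs$c_rel), error = function(e) NA_real_)

  new("FitResult",
      estimates = c(lambda_h = max(est$minimum, 0)),
      objective = model_rss, r2 = r2, n_starts = length(grid),
      converged = TRUE,
      bounds = list(lower = c(lambda_h = 0), upper = c(lambda_h = lambda_upper)),
      seed = NA_integer_,
      diagnostics = list(r_m = uparams@r_m,
                         note = "only the product r_m * lambda_h is identified"))
}
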