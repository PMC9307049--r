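#' Construct a XANES spectrum
#'
#' @param energy_ev strictly increasing energies (eV), >= 20 points
#' @param intensity intensities, same length
#' @param edge `"P-K"` or `"S-K"`
#' @param distance_um optional distance annotation (um)
#' @return a [Spectrum-class]
#' @export
xanesSpectrum <- function(energy_ev, intensity, edge = "S-K",
                     distance_um = NA_real_) {
  new("Spectrum", energy_ev = as.numeric(energy_ev),
      intensity = as.numeric(intensity), edge = edge,
      distance_um = as.numeric(distance_um))
}

#' Read a two-column spectrum file
#'
#' Plain text/CSV with columns energy (eV) and intensity; comment lines
#' starting with `#` are ignored.
#'
#' @param path file path
#' @inheritParams xanesSpectrum
#' @return a [Spectrum-class]
#' @export
readSpectrum <- function(path, edge = "S-K", distance_um = NA_real_) {
  df <- read.csv(path, comment.char = "#",
                 col.names = c("energy_ev", "intensity"))
  xanesSpectrum(df$energy_ev, df$intensity, edge = edge, distance_um = distance_um)
}

#' Interpolate and edge-step normalise a spectrum
#'
#' Standard XANES pre-processing: linear interpolation onto a common
#' energy grid, least-squares linear pre-edge subtraction, then scaling so
#' the mean post-edge intensity (the edge step) is 1. A spectrum already
#' in this normal form passes through unchanged; overall intensity scale
#' cancels.
#'
#' @param spec a [Spectrum-class]
#' @param grid target energies (eV), inside the spectrum's span
#' @param pre_edge_ev range `c(lo, hi)` used to fit the pre-edge line;
#'   default the first 20% of the grid
#' @param post_edge_ev range used to measure the edge step; default the
#'   last 20% of the grid
#' @return a normalised [Spectrum-class] on `grid`
#' @export
preprocessSpectrum <- function(spec, grid, pre_edge_ev = NULL,
                               post_edge_ev = NULL) {
  stopifnot(is(spec, "Spectrum"))
  .assert(.is_ascending(grid), "'grid' must be strictly ascending",
          "mycouptake_invalid_grid")
  .assert(min(grid) >= min(spec@energy_ev) && max(grid) <= max(spec@energy_ev),
          "grid must lie within the spectrum's energy span",
          "mycouptake_invalid_grid")
  y <- approx(spec@energy_ev, spec@intensity, xout = grid)$y
  span <- diff(range(grid))
  if (is.null(pre_edge_ev)) pre_edge_ev <- c(min(grid), min(grid) + 0.2 * span)
  if (is.null(post_edge_ev)) post_edge_ev <- c(max(grid) - 0.2 * span, max(grid))
  pre <- grid >= pre_edge_ev[1L] & grid <= pre_edge_ev[2L]
  post <- grid >= post_edge_ev[1L] & grid <= post_edge_ev[2L]
  .assert(sum(pre) >= 2L && sum(post) >= 1L,
          "pre/post-edge windows must contain grid points",
          "mycouptake_invalid_grid")
  base <- lm.fit(cbind(1, grid[pre]), y[pre])$coefficients
  y0 <- y - (base[1L] + base[2L] * grid)
  step <- mean(y0[post])
  .assert(is.finite(step) && step > 0,
          "edge step is not positive; spectrum cannot be normalised",
          "mycouptake_degenerate_data")
  xanesSpectrum(grid, y0 / step, edge = spec@edge, distance_um = spec@distance_um)
}

#' Linear-combination fit against a standards library
#'
#' Fits a spectrum as a non-negative, sum-to-one mixture of standard
#' spectra by non-negative least squares with the sum-to-one constraint
#' imposed through an augmented row (weighted hard constraint inside the
#' solve, not post-hoc renormalisation, which would bias residuals). All
#' spectra must share the common energy grid and edge.
#'
#' @param spec a [Spectrum-class] (typically from [preprocessSpectrum()])
#' @param standards named list of [Spectrum-class] standards on the same
#'   grid and edge
#' @return an [LCFResult-class]; a rank-deficient standard set triggers a
#'   warning carrying the condition number
#' @examples
#' e <- seq(2460, 2500, by = 0.25)
#' a <- xanesSpectrum(e, exp(-(e - 2473)^2 / 2)); b <- xanesSpectrum(e, exp(-(e - 2482)^2 / 2))
#' mix <- xanesSpectrum(e, 0.7 * a@intensity + 0.3 * b@intensity)
#' lcfWeights(lcfFit(mix, list(A = a, B = b)))
#' @export
lcfFit <- function(spec, standards) {
  stopifnot(is(spec, "Spectrum"))
  .assert(length(standards) >= 2L && !is.null(names(standards)),
          "need a named list of at least 2 standards",
          "mycouptake_invalid_parameter")
  for (s in standards) {
    .assert(is(s, "Spectrum"), "standards must be Spectrum objects",
            "mycouptake_invalid_parameter")
    .assert(identical(s@edge, spec@edge),
            sprintf("edge mismatch: spectrum is %s, a standard is %s",
                    spec@edge, s@edge),
            "mycouptake_edge_mismatch")
    .assert(isTRUE(all.equal(s@energy_ev, spec@energy_ev, tolerance = 1e-9)),
            "all spectra must share the common energy grid",
            "mycouptake_invalid_grid")
  }
  A <- vapply(standards, function(s) s@intensity, numeric(length(spec@energy_ev)))
  cond <- kappa(A, exact = TRUE)
  if (!is.finite(cond) || cond > 1e8) {
    warning(sprintf("standard set is (near) rank-deficient: condition number %.3g",
                    cond))
  }
  scale <- sqrt(mean(A^2))
  w <- 1e4 * scale
  A_aug <- rbind(A, rep(w, ncol(A)))
  y_aug <- c(spec@intensity, w)
  if (!is.finite(cond) || cond > 1e8) {
    # small ridge keeps the active-set solve defined on degenerate
    # libraries; applied only when the set is already flagged ill-posed
    A_aug <- rbind(A_aug, diag(1e-3 * scale, ncol(A)))
    y_aug <- c(y_aug, rep(0, ncol(A)))
  }
  fit <- pracma::lsqnonneg(A_aug, y_aug)
  wts <- fit$x
  names(wts) <- names(standards)
  fitted <- as.numeric(A %*% wts)
  rss <- sum((spec@intensity - fitted)^2)
  new("LCFResult", weights = wts, rss = rss,
      r_factor = rss / sum(spec@intensity^2), fitted = fitted,
      diagnostics = list(condition_number = cond))
}

#' Speciation fractions versus distance
#'
#' Runs [lcfFit()] on each annotated spectrum, groups the standard weights
#' into species groups (default: the S K-edge grouping, reduced = amino
#' acid thiols, oxidized = sulfonate + sulfate), and aggregates the group
#' fractions in distance bins as mean +/- SD.
#'
#' @param spectra list of [Spectrum-class], each with a finite
#'   `distance_um` annotation
#' @param standards named list of standards on the common grid
#' @param bins ascending bin edges (um)
#' @param groups named list mapping group name to standard names; default
#'   `list(reduced = "thiol", oxidized = c("sulfonate", "sulfate"))`
#' @return data.frame: bin, bin centre, n spectra, and per group
#'   `mean_<group>` and `sd_<group>`; empty bins flagged with `n = 0`
#' @export
speciationVsDistance <- function(spectra, standards, bins,
                                 groups = list(reduced = "thiol",
                                               oxidized = c("sulfonate", "sulfate"))) {
  .assert(length(spectra) >= 1L, "no spectra supplied",
          "mycouptake_invalid_parameter")
  ann <- vapply(spectra, function(s) s@distance_um, numeric(1))
  .assert(all(is.finite(ann)), "every spectrum must carry a distance annotation",
          "mycouptake_invalid_parameter")
  .assert(.is_ascending(bins) && length(bins) >= 2L,
          "'bins' must be ascending edges", "mycouptake_invalid_grid")
  .assert(all(unlist(groups) %in% names(standards)),
          "group table names standards missing from the library",
          "mycouptake_invalid_parameter")
  fracs <- t(vapply(spectra, function(s) {
    wts <- lcfWeights(lcfFit(s, standards))
    vapply(groups, function(g) sum(wts[g]), numeric(1))
  }, numeric(length(groups))))
  colnames(fracs) <- names(groups)
  bin_id <- cut(ann, breaks = bins, include.lowest = TRUE)
  out <- data.frame(bin = levels(bin_id),
                    mid_um = (head(bins, -1L) + tail(bins, -1L)) / 2)
  out$n <- as.integer(table(bin_id)[out$bin])
  for (g in names(groups)) {
    out[[paste0("mean_", g)]] <- vapply(out$bin, function(b) {
      v <- fracs[bin_id == b, g]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    out[[paste0("sd_", g)]] <- vapply(out$bin, function(b) {
      v <- fracs[bin_id == b, g]
      if (length(v) > 1L) sd(v) else if (length(v) == 1L) 0 else NA_real_
    }, numeric(1))
  }
  if (any(out$n == 0L)) warning("some distance bins contain no spectra")
  rownames(out) <- NULL
  out
}
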