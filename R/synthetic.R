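GENERATOR_VERSION <- "1.0"

.truth <- function(seed, ...) {
  c(list(...), list(seed = seed, generator_version = GENERATOR_VERSION))
}

#' Synthetic hyphal length-density observations
#'
#' Emulates the compartment observation design (by default three positions
#' h1 = 13.5, h2 = 28.5, h3 = 43.5 mm from the root interface, sampled at
#' 2 and 4 weeks, three replicates) by evaluating the closed-form growth
#' model and adding replicate noise: multiplicative lognormal (default,
#' mean-one, coefficient of variation = `level`) or additive Gaussian with
#' absolute sd `level` (clamped at 0).
#'
#' @param true_params a [GrowthParams-class], the planted truth
#' @param positions_cm observation positions (cm)
#' @param times_s observation times (s)
#' @param replicates number of replicates
#' @param noise list with `type` (`"lognormal"` or `"gaussian"`) and
#'   `level` (>= 0)
#' @param seed integer seed; identical seeds reproduce the set exactly
#' @return an [ObservationSet-class] whose `truth` records the planted
#'   parameters
#' @export
genLengthDensityObs <- function(true_params,
                                positions_cm = c(1.35, 2.85, 4.35),
                                times_s = c(2, 4) * SECONDS_PER_WEEK,
                                replicates = 3L,
                                noise = list(type = "lognormal", level = 0.1),
                                seed = 1L) {
  stopifnot(is(true_params, "GrowthParams"))
  .assert(noise$level >= 0, "noise level must be >= 0",
          "mycouptake_invalid_parameter")
  design <- expand.grid(position_cm = positions_cm, time_s = times_s,
                        replicate = seq_len(replicates))
  mu <- .growth_closed_form(true_params, design$position_cm, design$time_s)$rho
  vals <- .with_seed(seed, {
    if (noise$level == 0) {
      mu
    } else if (identical(noise$type, "lognormal")) {
      s <- sqrt(log(1 + noise$level^2))   # CV of the multiplier = level
      mu * rlnorm(length(mu), meanlog = -s^2 / 2, sdlog = s)
    } else if (identical(noise$type, "gaussian")) {
      pmax(mu + rnorm(length(mu), sd = noise$level), 0)
    } else {
      stop(errorCondition("noise$type must be 'lognormal' or 'gaussian'",
                          class = c("mycouptake_invalid_parameter",
                                    "mycouptake_error")))
    }
  })
  observationSet(design$position_cm, design$time_s, design$replicate, vals,
                 truth = .truth(seed,
                                params = c(k = true_params@k, v = true_params@v,
                                           b_branch = true_params@b_branch,
                                           d = true_params@d),
                                noise = noise))
}

.rand_unit3 <- function() {
  repeat {
    u <- rnorm(3)
    n2 <- sum(u^2)
    if (n2 > 1e-12) return(u / sqrt(n2))
  }
}

#' Synthetic hyphal skeleton in a cylindrical domain
#'
#' Grows tips from the x = 0 face of a cylinder with direction
#' persistence, per-step branching and stopping, then voxelises the
#' resulting polylines. Presets mirror the observed morphological
#' contrast: `"inoculated"` (straighter, sparsely branched) and
#' `"control"` (more tortuous, heavily branched).
#'
#' @param domain list: `radius_um`, `length_um` of the cylinder
#' @param process list: `step_um`, `persistence` in `[0, 1]` (1 = perfectly
#'   straight), `branch_prob` and `stop_prob` per step
#' @param n_tips number of tips launched at the x = 0 face
#' @param voxel_size_um voxel size for the voxelisation (um)
#' @param preset `NULL`, `"inoculated"` or `"control"` (overrides
#'   `process`)
#' @param seed integer seed
#' @return list: `voxels` (n x 3 voxel indices), `dims`, `voxel_size_um`,
#'   `graph` (exact polyline truth as a [SkeletonGraph-class]), `truth`
#'   (planted polylines, launch directions, per-branch lengths)
#' @export
genSkeleton <- function(domain = list(radius_um = 60, length_um = 220),
                        process = list(step_um = 8, persistence = 0.9,
                                       branch_prob = 0.02, stop_prob = 0.01),
                        n_tips = 5L, voxel_size_um = 1.6, preset = NULL,
                        seed = 1L) {
  if (!is.null(preset)) {
    process <- switch(preset,
      inoculated = list(step_um = 8, persistence = 0.95, branch_prob = 0.01,
                        stop_prob = 0.01),
      control = list(step_um = 8, persistence = 0.80, branch_prob = 0.06,
                     stop_prob = 0.01),
      stop(errorCondition("unknown preset",
                          class = c("mycouptake_invalid_parameter",
                                    "mycouptake_error"))))
  }
  .assert(domain$radius_um > 0 && domain$length_um > domain$radius_um / 10,
          "degenerate domain", "mycouptake_invalid_parameter")
  R <- domain$radius_um; L <- domain$length_um
  step <- process$step_um; p <- process$persistence
  max_steps <- ceiling(4 * L / step)
  max_tips <- 400L

  out <- .with_seed(seed, {
    polylines <- list(); launch_dirs <- list()
    # active tips: list(pos, dir, path matrix)
    tips <- lapply(seq_len(n_tips), function(i) {
      repeat {
        yz <- runif(2, -R, R)
        if (sum(yz^2) <= R^2) break
      }
      d0 <- c(1, 0, 0)
      if (p < 1) d0 <- d0 + (1 - p) * .rand_unit3()
      d0 <- d0 / sqrt(sum(d0^2))
      if (d0[1L] <= 0) d0 <- c(abs(d0[1L]) + 0.1, d0[2L], d0[3L]) /
          sqrt(sum(c(abs(d0[1L]) + 0.1, d0[2L], d0[3L])^2))
      list(pos = c(0, yz), dir = d0, path = matrix(c(0, yz), 1L, 3L))
    })
    n_spawned <- n_tips
    step_count <- 0L
    while (length(tips) > 0L && step_count < max_steps) {
      step_count <- step_count + 1L
      nxt <- list()
      for (tip in tips) {
        dir <- tip$dir
        if (p < 1) {
          dir <- p * dir + (1 - p) * .rand_unit3()
          dir <- dir / sqrt(sum(dir^2))
        }
        pos <- tip$pos + step * dir
        path <- rbind(tip$path, pos)
        outside <- pos[1L] < 0 || pos[1L] > L || sum(pos[2:3]^2) > R^2
        stopped <- runif(1) < process$stop_prob
        if (outside || stopped) {
          polylines[[length(polylines) + 1L]] <- path
          launch_dirs[[length(launch_dirs) + 1L]] <- tip$dir
          next
        }
        if (runif(1) < process$branch_prob && n_spawned < max_tips) {
          n_spawned <- n_spawned + 1L
          bdir <- p * dir + (1 - p + 0.3) * .rand_unit3()
          bdir <- bdir / sqrt(sum(bdir^2))
          nxt[[length(nxt) + 1L]] <- list(pos = pos, dir = bdir,
                                          path = matrix(pos, 1L, 3L))
        }
        nxt[[length(nxt) + 1L]] <- list(pos = pos, dir = dir, path = path)
      }
      tips <- nxt
    }
    for (tip in tips) {   # exhausted step budget
      polylines[[length(polylines) + 1L]] <- tip$path
      launch_dirs[[length(launch_dirs) + 1L]] <- tip$dir
    }
    list(polylines = polylines, launch_dirs = launch_dirs)
  })
  polylines <- lapply(out$polylines, function(p) {
    # clip to the domain box for voxelisation
    p[, 1L] <- pmin(pmax(p[, 1L], 0), L)
    p
  })
  vox <- voxelizePolylines(polylines, voxel_size_um,
                           origin = c(0, -R, -R))
  blen <- vapply(polylines, function(pl) {
    sum(sqrt(rowSums((pl[-1L, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2)))
  }, numeric(1))
  keep <- blen > 0
  list(voxels = vox$coords, dims = vox$dims, voxel_size_um = voxel_size_um,
       graph = skeletonFromPolylines(polylines[keep], voxel_size_um),
       truth = .truth(seed, process = process, domain = domain,
                      polylines = polylines[keep],
                      launch_dirs = out$launch_dirs[keep],
                      branch_length_um = blen[keep]))
}

#' Voxelise 3D polylines
#'
#' Rasterises each polyline as a chain of thin 26-connected digital line
#' segments: between consecutive vertex voxels a DDA walk advances one
#' step along the dominant axis, so the raster stays 1 voxel wide and a
#' valid input for [voxelSkeletonToGraph()].
#'
#' @param polylines list of n x 3 matrices (um)
#' @param voxel_size_um voxel edge (um)
#' @param origin um coordinates of the corner of voxel (1,1,1)
#' @return list: `coords` (m x 3 integer voxel indices, 1-based), `dims`
#' @export
voxelizePolylines <- function(polylines, voxel_size_um, origin = c(0, 0, 0)) {
  .assert(length(polylines) > 0, "no segments to voxelise",
          "mycouptake_invalid_parameter")
  chains <- lapply(polylines, function(pl) {
    pl <- sweep(pl, 2L, origin)
    vtx <- floor(pl / voxel_size_um) + 1L
    segs <- list(matrix(vtx[1L, ], 1L, 3L))
    for (s in seq_len(nrow(vtx) - 1L)) {
      a <- vtx[s, ]; b <- vtx[s + 1L, ]
      nsteps <- max(abs(b - a))
      if (nsteps == 0L) next
      tt <- seq_len(nsteps) / nsteps
      segs[[length(segs) + 1L]] <-
        cbind(round(a[1L] + tt * (b[1L] - a[1L])),
              round(a[2L] + tt * (b[2L] - a[2L])),
              round(a[3L] + tt * (b[3L] - a[3L])))
    }
    do.call(rbind, segs)
  })
  idx <- unique(do.call(rbind, chains))
  idx <- idx[rowSums(idx < 1L) == 0L, , drop = FALSE]
  storage.mode(idx) <- "integer"
  list(coords = idx, dims = apply(idx, 2L, max) + 1L)
}

#' Synthetic multi-element XRF map with planted phase geometry
#'
#' Builds a three-phase plane (air pores, high-Si primary grains, mixed
#' clay-water background), couples the P and Al fields to the distance
#' from planted hyphae and adds multiplicative noise. The hyphae live in a
#' thin 3D slab so that the distance plane exercises the true 3D distance
#' transform and plane registration. Two coupling profiles are available:
#' `"exp"` (`field = base (1 + a e^{-d/ell})`) and `"step"` (`base (1 + a)`
#' strictly inside the close class, `base` outside), the latter planting
#' an exact mean contrast for power studies.
#'
#' @param shape_px map shape in pixels (rows, cols)
#' @param pixel_size_um pixel size (um); the slab voxel size equals it
#' @param hyphae list from [genSkeleton()] (its truth polylines are
#'   re-voxelised into the slab), or `NULL` to plant a default set of
#'   crossing filaments in the left half of the plane
#' @param geometry list: `n_grains`, `grain_radius_px`, `n_pores`,
#'   `pore_radius_px`
#' @param coupling list: `profile` ("exp" or "step"), `a_P`, `a_Al`,
#'   `ell_um`, `close_um` (step profile boundary)
#' @param base named vector of mixed-phase baseline levels (counts)
#' @param noise_cv multiplicative lognormal noise CV on every element
#' @param seed integer seed
#' @return an [XRFMap-class] with `truth` carrying phase labels, the
#'   distance plane (um) and all planted settings; elements P, S, Al, Si
#' @export
genXRFMaps <- function(shape_px = c(160L, 160L), pixel_size_um = 6,
                       hyphae = NULL,
                       geometry = list(n_grains = 10L, grain_radius_px = 7,
                                       n_pores = 10L, pore_radius_px = 5),
                       coupling = list(profile = "exp", a_P = 0.35,
                                       a_Al = -0.5, ell_um = 60,
                                       close_um = 50),
                       base = c(P = 8300, S = 600, Al = 8000, Si = 800),
                       noise_cv = 0.2, seed = 1L) {
  nr <- shape_px[1L]; nc <- shape_px[2L]
  slab_z <- 9L
  .with_seed(seed, {
    # hyphal polylines in the slab (um frame of the map plane, z = 0 centre)
    if (is.null(hyphae)) {
      ext_r <- nr * pixel_size_um; ext_c <- nc * pixel_size_um
      polylines <- lapply(seq_len(4L), function(i) {
        y0 <- runif(1, 0.05, 0.45) * ext_r
        y1 <- y0 + runif(1, -0.15, 0.15) * ext_r
        x0 <- runif(1, 0, 0.2) * ext_c
        x1 <- runif(1, 0.8, 1) * ext_c
        cbind(seq(y0, y1, length.out = 50L), seq(x0, x1, length.out = 50L),
              runif(1, -1, 1) * pixel_size_um)
      })
    } else {
      polylines <- lapply(hyphae$truth$polylines, function(p) {
        cbind(p[, 2L] - min(p[, 2L]), p[, 1L], p[, 3L] - mean(p[, 3L]))
      })
    }
    zoff <- (slab_z / 2) * pixel_size_um
    vox <- voxelizePolylines(polylines, pixel_size_um,
                             origin = c(0, 0, -zoff))
    coords <- vox$coords
    keep <- coords[, 1L] <= nr & coords[, 2L] <= nc & coords[, 3L] <= slab_z
    coords <- coords[keep, , drop = FALSE]
    mask <- array(FALSE, c(nr, nc, slab_z))
    mask[coords] <- TRUE
    dist3 <- distanceTransform3D(mask, pixel_size_um)
    map_affine <- cbind(diag(3), c(0, 0, (slab_z + 1L) %/% 2L))
    # phases
    phase <- matrix("mixed", nr, nc)
    rc <- as.matrix(expand.grid(r = seq_len(nr), c = seq_len(nc)))
    put_discs <- function(n, rad, label) {
      for (i in seq_len(n)) {
        ctr <- c(runif(1, 1, nr), runif(1, 1, nc))
        sel <- (rc[, 1L] - ctr[1L])^2 + (rc[, 2L] - ctr[2L])^2 <= rad^2
        phase[rc[sel, , drop = FALSE]] <<- label
      }
    }
    put_discs(geometry$n_grains, geometry$grain_radius_px, "primary")
    put_discs(geometry$n_pores, geometry$pore_radius_px, "air")
    # distance plane sampled from the slab (identity in-plane)
    dplane <- matrix(dist3[cbind(rc[, 1L], rc[, 2L],
                                 rep((slab_z + 1L) %/% 2L, nrow(rc)))],
                     nr, nc)
    # element fields
    s <- sqrt(log(1 + noise_cv^2))
    mnoise <- function() matrix(rlnorm(nr * nc, -s^2 / 2, s), nr, nc)
    shape_fac <- function(a) {
      if (identical(coupling$profile, "step")) {
        1 + a * (dplane <= coupling$close_um)
      } else {
        1 + a * exp(-dplane / coupling$ell_um)
      }
    }
    P <- base[["P"]] * shape_fac(coupling$a_P) * mnoise()
    Al <- base[["Al"]] * pmax(shape_fac(coupling$a_Al), 0.05) * mnoise()
    S <- base[["S"]] * mnoise()
    Si <- base[["Si"]] * mnoise()
    # overwrite non-mixed phases
    grain <- phase == "primary"; air <- phase == "air"
    Si[grain] <- 3e4 * (1 + 0.1 * rnorm(sum(grain)))
    P[grain] <- 0.2 * base[["P"]]; Al[grain] <- base[["Al"]]
    S[grain] <- 0.2 * base[["S"]]
    P[air] <- 20; S[air] <- 5; Al[air] <- 20; Si[air] <- 10
    xrfMap(list(P = P, S = S, Al = Al, Si = Si),
           pixel_size_um = pixel_size_um, units = "counts",
           affine = map_affine,
           truth = .truth(seed, phase = phase, distance_um = dplane,
                          coupling = coupling, base = as.list(base),
                          noise_cv = noise_cv, hyphal_mask = mask))
  })
}

#' Synthetic XANES standards and mixtures
#'
#' Builds Gaussian-peak-plus-arctan-edge standards (defaults: the S K-edge
#' trio with white lines at 2473 eV (thiol), 2480.5 eV (sulfonate) and
#' 2482 eV (sulfate)) and a mixture spectrum with white noise at the
#' stated signal-to-noise ratio (sd = edge step / snr).
#'
#' @param weights named non-negative mixture weights summing to 1; names
#'   must match `standard_models`
#' @param snr signal-to-noise ratio; `Inf` for noise-free
#' @param standard_models named list of `list(center_ev, width_ev,
#'   amplitude)` peak models
#' @param grid energy grid (eV)
#' @param distance_um optional annotation for the mixture
#' @param seed integer seed
#' @return list: `mixture` ([Spectrum-class]), `standards` (named list of
#'   [Spectrum-class]), `truth`
#' @export
genXANES <- function(weights = c(thiol = 0.6, sulfonate = 0.2, sulfate = 0.2),
                     snr = 50,
                     standard_models = list(
                       thiol = list(center_ev = 2473, width_ev = 1.0, amplitude = 2.2),
                       sulfonate = list(center_ev = 2480.5, width_ev = 1.0, amplitude = 1.8),
                       sulfate = list(center_ev = 2482, width_ev = 0.9, amplitude = 2.6)),
                     grid = seq(2460, 2500, by = 0.25),
                     distance_um = NA_real_, seed = 1L) {
  .assert(all(weights >= 0) && abs(sum(weights) - 1) < 1e-9,
          "weights must be >= 0 and sum to 1", "mycouptake_invalid_parameter")
  .assert(all(names(weights) %in% names(standard_models)),
          "weight names must match standard models", "mycouptake_invalid_parameter")
  std_curve <- function(m) {
    edge <- (atan((grid - m$center_ev) / 1.2) + pi / 2) / pi
    peak <- m$amplitude * exp(-(grid - m$center_ev)^2 / (2 * m$width_ev^2))
    edge + peak
  }
  standards <- lapply(standard_models, function(m) xanesSpectrum(grid, std_curve(m)))
  mix_clean <- Reduce(`+`, Map(function(w, nm) w * standards[[nm]]@intensity,
                               weights, names(weights)))
  mix <- .with_seed(seed, {
    if (is.finite(snr)) mix_clean + rnorm(length(grid), sd = 1 / snr)
    else mix_clean
  })
  list(mixture = xanesSpectrum(grid, mix, distance_um = distance_um),
       standards = standards,
       truth = .truth(seed, weights = as.list(weights), snr = snr))
}

#' Synthetic normalised P depletion profile
#'
#' Runs [solveUptake()] with a planted `lambda_h` and samples the relative
#' total P profile `c_TOT(x, t_final) / c_inf` at the stated positions,
#' with additive Gaussian noise.
#'
#' @param uparams an [UptakeParams-class] carrying the planted `lambda_h`
#' @param rho_field scalar, function or [GrowthSolution-class]
#' @param t_final final time (s)
#' @param positions_cm profile positions (cm)
#' @param noise_sd additive Gaussian sd on the relative profile
#' @param x_grid,nt solver controls (defaults match [fitUptake()])
#' @param seed integer seed
#' @return list: `profile` (data.frame `x_cm`, `c_rel`), `truth`
#' @export
genPProfile <- function(uparams, rho_field, t_final = 4 * SECONDS_PER_WEEK,
                        positions_cm = seq(0.1, 4.3, length.out = 25L),
                        noise_sd = 0.02,
                        x_grid = seq(0, 4.5, length.out = 361L), nt = 60L,
                        seed = 1L) {
  sol <- solveUptake(uparams, rho_field, x_grid,
                     seq(0, t_final, length.out = nt))
  c_rel <- approx(sol@x_grid, sol@c_tot[, nt] / uparams@c_inf,
                  xout = positions_cm, rule = 2)$y
  obs <- .with_seed(seed, {
    if (noise_sd > 0) c_rel + rnorm(length(c_rel), sd = noise_sd) else c_rel
  })
  list(profile = data.frame(x_cm = positions_cm, c_rel = obs),
       truth = .truth(seed, lambda_h = uparams@lambda_h, r_m = uparams@r_m,
                      D_eff = uparams@D_eff, t_final = t_final,
                      noise_sd = noise_sd, clean = c_rel))
}
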