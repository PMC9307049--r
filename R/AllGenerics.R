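#' Accessors for grid-based solution objects
#'
#' @param object a [GrowthSolution-class] or [ConcentrationSolution-class]
#' @return `xGrid`/`tGrid` return the spatial (cm) / temporal (s) grid;
#'   `tipDensity` and `lengthDensity` the `n` and `rho` matrices of a growth
#'   solution; `cTot` the total-P matrix of a concentration solution.
#' @name solution-accessors
NULL

#' @rdname solution-accessors
#' @export
setGeneric("xGrid", function(object) standardGeneric("xGrid"))
#' @rdname solution-accessors
#' @export
setGeneric("tGrid", function(object) standardGeneric("tGrid"))
#' @rdname solution-accessors
#' @export
setGeneric("tipDensity", function(object) standardGeneric("tipDensity"))
#' @rdname solution-accessors
#' @export
setGeneric("lengthDensity", function(object) standardGeneric("lengthDensity"))
#' @rdname solution-accessors
#' @export
setGeneric("cTot", function(object) standardGeneric("cTot"))

#' @rdname solution-accessors
#' @export
setMethod("xGrid", "GrowthSolution", function(object) object@x_grid)
#' @rdname solution-accessors
#' @export
setMethod("tGrid", "GrowthSolution", function(object) object@t_grid)
#' @rdname solution-accessors
#' @export
setMethod("xGrid", "ConcentrationSolution", function(object) object@x_grid)
#' @rdname solution-accessors
#' @export
setMethod("tGrid", "ConcentrationSolution", function(object) object@t_grid)
#' @rdname solution-accessors
#' @export
setMethod("tipDensity", "GrowthSolution", function(object) object@n)
#' @rdname solution-accessors
#' @export
setMethod("lengthDensity", "GrowthSolution", function(object) object@rho)
#' @rdname solution-accessors
#' @export
setMethod("cTot", "ConcentrationSolution", function(object) object@c_tot)

#' Dissolved and sorbed P accessors
#'
#' When `theta` (mixed-phase volume fraction) and `b_buffer` (buffer power)
#' are set, the total concentration decomposes as
#' \eqn{c_{TOT} = (b + \theta) c_l} with solution-phase concentration
#' \eqn{c_l} and sorbed concentration \eqn{c_s = b\,c_l}.
#'
#' @param object a [ConcentrationSolution-class]
#' @return matrix on the solution grid
#' @export
setGeneric("cLiquid", function(object) standardGeneric("cLiquid"))

#' @rdname cLiquid
#' @export
setGeneric("cSorbed", function(object) standardGeneric("cSorbed"))

#' @rdname cLiquid
#' @export
setMethod("cLiquid", "ConcentrationSolution", function(object) {
  p <- object@params
  .assert(!is.na(p@theta) && !is.na(p@b_buffer),
          "theta and b_buffer must be set to decompose c_TOT",
          "mycouptake_invalid_parameter")
  object@c_tot / (p@b_buffer + p@theta)
})

#' @rdname cLiquid
#' @export
setMethod("cSorbed", "ConcentrationSolution", function(object) {
  object@params@b_buffer * cLiquid(object)
})

#' Observation records of an ObservationSet
#'
#' @param object an [ObservationSet-class]
#' @return the underlying data.frame
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "ObservationSet", function(object) object@records)

#' Parameter estimates of a fit
#'
#' @param object a [FitResult-class]
#' @return named numeric vector
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname estimates
#' @export
setMethod("estimates", "FitResult", function(object) object@estimates)

#' Standard weights of a linear-combination fit
#'
#' @param object an [LCFResult-class]
#' @return named numeric vector of non-negative, sum-to-one weights
#' @export
setGeneric("lcfWeights", function(object) standardGeneric("lcfWeights"))

#' @rdname lcfWeights
#' @export
setMethod("lcfWeights", "LCFResult", function(object) object@weights)

#' Planted ground truth attached to a synthetic object
#'
#' @param object an object produced by one of the `gen*` generators
#' @return list of planted parameters/labels (empty for real data)
#' @export
setGeneric("syntheticTruth", function(object) standardGeneric("syntheticTruth"))

#' @rdname syntheticTruth
#' @export
setMethod("syntheticTruth", "ObservationSet", function(object) object@truth)
#' @rdname syntheticTruth
#' @export
setMethod("syntheticTruth", "XRFMap", function(object) object@truth)

setMethod("show", "GrowthParams", function(object) {
  cat("GrowthParams (cm, s units)\n")
  cat(sprintf("  k = %.4g cm^-2 s^-1   v = %.4g cm s^-1\n", object@k, object@v))
  cat(sprintf("  b = %.4g s^-1         d = %.4g s^-1\n", object@b_branch, object@d))
})

setMethod("show", "GrowthSolution", function(object) {
  cat(sprintf("GrowthSolution: %d x-points x %d t-points\n",
              length(object@x_grid), length(object@t_grid)))
  cat(sprintf("  x in [%.3g, %.3g] cm, t in [%.3g, %.3g] s\n",
              min(object@x_grid), max(object@x_grid),
              min(object@t_grid), max(object@t_grid)))
  cat(sprintf("  max rho = %.4g cm^-2\n", max(object@rho)))
})

setMethod("show", "ObservationSet", function(object) {
  cat(sprintf("ObservationSet: %d records, %d replicate(s)%s\n",
              nrow(object@records), length(unique(object@records$replicate)),
              if (length(object@truth)) " [synthetic]" else ""))
})

setMethod("show", "UptakeParams", function(object) {
  cat("UptakeParams (cm, s units)\n")
  cat(sprintf("  D_eff = %.4g cm^2 s^-1, r_m = %.4g cm\n", object@D_eff, object@r_m))
  cat(sprintf("  lambda_h = %.4g cm s^-1 (identified only as r_m * lambda_h)\n",
              object@lambda_h))
  cat(sprintf("  F_max = %.4g cm s^-1, c_inf = %.4g\n", object@F_max, object@c_inf))
})

setMethod("show", "ConcentrationSolution", function(object) {
  cat(sprintf("ConcentrationSolution: %d x-points x %d t-points\n",
              length(object@x_grid), length(object@t_grid)))
  cat(sprintf("  c_tot/c_inf range [%.4g, %.4g] at final time\n",
              min(object@c_tot[, ncol(object@c_tot)]) / object@params@c_inf,
              max(object@c_tot[, ncol(object@c_tot)]) / object@params@c_inf))
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult\n")
  for (p in names(object@estimates)) {
    cat(sprintf("  %-9s = %.6g\n", p, object@estimates[[p]]))
  }
  cat(sprintf("  RSS = %.6g, R^2 = %.4f, starts = %d, converged = %s\n",
              object@objective, object@r2, object@n_starts, object@converged))
  if (isTRUE(object@diagnostics$identifiability_warning)) {
    cat("  warning: near-flat objective directions detected\n")
  }
})

setMethod("show", "AggregateFit", function(object) {
  cat(sprintf("AggregateFit over %d replicate fits (mean +/- SD)\n",
              nrow(object@replicates)))
  for (p in names(object@mean)) {
    cat(sprintf("  %-9s = %s\n", p, formatMeanSD(object@mean[[p]], object@sd[[p]])))
  }
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d nodes, %d branches, %d cluster(s)\n",
              nrow(object@nodes), length(object@branches),
              length(unique(object@cluster))))
})

setMethod("show", "HyphalMetrics", function(object) {
  cat("HyphalMetrics\n")
  cat(sprintf("  total length  = %.4g um (density %.4g cm^-2)\n",
              object@total_length_um, object@length_density_cm2))
  cat(sprintf("  clusters = %d, mean branch length = %.4g um\n",
              object@n_clusters, object@mean_branch_length_um))
  if (length(object@tortuosity)) {
    cat(sprintf("  tortuosity median = %.4g, angle median = %.4g deg\n",
                median(object@tortuosity), median(object@angle_deg)))
  }
})

setMethod("show", "XRFMap", function(object) {
  shp <- dim(object@elements[[1L]])
  cat(sprintf("XRFMap: %s | %d x %d px @ %.3g um (%s)%s\n",
              paste(names(object@elements), collapse = ", "),
              shp[1L], shp[2L], object@pixel_size_um, object@units,
              if (length(object@truth)) " [synthetic]" else ""))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s edge): %d points, %.1f-%.1f eV%s\n",
              object@edge, length(object@energy_ev),
              min(object@energy_ev), max(object@energy_ev),
              if (is.finite(object@distance_um)) {
                sprintf(", at %.0f um", object@distance_um)
              } else ""))
})

setMethod("show", "LCFResult", function(object) {
  cat("LCFResult (weights sum to 1):\n")
  for (nm in names(object@weights)) {
    cat(sprintf("  %-16s %5.1f%%\n", nm, 100 * object@weights[[nm]]))
  }
  cat(sprintf("  R-factor = %.4g\n", object@r_factor))
})
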