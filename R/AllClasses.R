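#' Tip-kinetics parameters of the hyphal colonisation model
#'
#' Container for the four kinetic constants of the hyphal growth model
#' \deqn{\partial_t n + v \partial_x n = b n, \qquad
#'       \partial_t \rho = n v - d \rho,}
#' where `n` is the hyphal tip density (tips cm\eqn{^{-3}}) and `rho` the
#' hyphal length density (cm hyphae cm\eqn{^{-3}} soil, i.e. cm\eqn{^{-2}}).
#' Tips are produced at the root-compartment interface at constant flux
#' \eqn{v\,n(0, t) = k}. All internal units are cm and s.
#'
#' @slot k tip production flux at the root interface (tips cm^-2 s^-1), >= 0
#' @slot v tip elongation speed (cm s^-1), > 0
#' @slot b_branch net branching rate (s^-1)
#' @slot d net length destruction rate (s^-1), >= 0
#'
#' @seealso [growthParams()] for the user-facing constructor,
#'   [solveGrowthClosedForm()], [fitGrowth()]
#' @export
setClass("GrowthParams",
  representation(k = "numeric", v = "numeric",
                 b_branch = "numeric", d = "numeric"),
  prototype(k = 0, v = 1e-5, b_branch = 0, d = 0))

setValidity("GrowthParams", function(object) {
  msgs <- character()
  for (s in c("k", "v", "b_branch", "d")) {
    val <- slot(object, s)
    if (length(val) != 1L || !is.finite(val)) {
      msgs <- c(msgs, sprintf("'%s' must be a finite scalar", s))
    }
  }
  if (length(msgs) == 0L) {
    if (object@v <= 0) msgs <- c(msgs, "'v' must be > 0")
    if (object@k < 0) msgs <- c(msgs, "'k' must be >= 0")
    if (object@d < 0) msgs <- c(msgs, "'d' must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Hyphal tip- and length-density fields on a space-time grid
#'
#' Result of [solveGrowthClosedForm()] or [solveGrowthNumeric()]: the tip
#' density `n` and hyphal length density `rho` evaluated on the tensor grid
#' `x_grid` x `t_grid`. Both fields are zero ahead of the colonisation front
#' `x = v t`.
#'
#' @slot x_grid distances from the root-compartment interface (cm, ascending)
#' @slot t_grid times since transplanting (s, ascending)
#' @slot n matrix `length(x_grid)` x `length(t_grid)` of tip density
#' @slot rho matrix of hyphal length density (cm^-2), same shape as `n`
#' @slot params the [GrowthParams-class] used
#' @export
setClass("GrowthSolution",
  representation(x_grid = "numeric", t_grid = "numeric",
                 n = "matrix", rho = "matrix", params = "GrowthParams"))

setValidity("GrowthSolution", function(object) {
  msgs <- character()
  if (!.is_ascending(object@x_grid) || any(object@x_grid < 0)) {
    msgs <- c(msgs, "'x_grid' must be ascending and >= 0")
  }
  if (!.is_ascending(object@t_grid)) msgs <- c(msgs, "'t_grid' must be ascending")
  dims_ok <- identical(dim(object@n), c(length(object@x_grid), length(object@t_grid))) &&
    identical(dim(object@rho), dim(object@n))
  if (!dims_ok) msgs <- c(msgs, "'n' and 'rho' must be length(x_grid) x length(t_grid)")
  if (dims_ok && (any(object@n < 0) || any(object@rho < 0))) {
    msgs <- c(msgs, "'n' and 'rho' must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Hyphal length-density observations
#'
#' A table of length-density measurements: position along the hyphal
#' compartment midline, time since transplanting, replicate id and the
#' observed density, with an optional standard deviation. Units are cm, s
#' and cm^-2; readers perform any mm/week conversion.
#'
#' @slot records data.frame with columns `position_cm`, `time_s`,
#'   `replicate`, `rho_cm2` and optionally `sd_cm2`
#' @slot truth optional list describing planted ground truth for synthetic
#'   sets (empty for real data)
#' @seealso [observationSet()], [readObservationSet()], [genLengthDensityObs()]
#' @export
setClass("ObservationSet",
  representation(records = "data.frame", truth = "list"),
  prototype(truth = list()))

setValidity("ObservationSet", function(object) {
  rec <- object@records
  need <- c("position_cm", "time_s", "replicate", "rho_cm2")
  if (!all(need %in% names(rec))) {
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  }
  msgs <- character()
  if (nrow(rec) < 1L) msgs <- c(msgs, "at least one record required")
  if (any(rec$position_cm < 0)) msgs <- c(msgs, "positions must be >= 0")
  if (any(rec$time_s < 0)) msgs <- c(msgs, "times must be >= 0")
  if (any(rec$rho_cm2 < 0)) msgs <- c(msgs, "rho values must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Soil-phosphorus transport and uptake parameters
#'
#' Parameters of the total-P transport equation
#' \deqn{\partial_t c_{TOT} = D_{eff} \partial_{xx} c_{TOT}
#'       - 2 \pi r_m \lambda_h \rho \, c_{TOT},}
#' with Robin condition \eqn{D_{eff}\partial_x c_{TOT} = F_{max} c_{TOT}} at
#' the root interface and a fixed far field \eqn{c_{TOT} \to c_\infty}.
#' Only the product \eqn{r_m \lambda_h} is identified by depletion profiles,
#' so \eqn{r_m} must always be reported alongside \eqn{\lambda_h}.
#'
#' @slot D_eff effective P diffusivity (cm^2 s^-1); default 1.05e-8
#' @slot r_m hyphal radius (cm); default 5e-4 (10 um diameter)
#' @slot lambda_h hyphal P uptake rate coefficient (cm s^-1), >= 0
#' @slot F_max root-compartment sink coefficient (cm s^-1), >= 0; default 0
#' @slot c_inf far-field total P concentration (fixed arbitrary unit), > 0
#' @slot theta mixed-phase volume fraction (optional, NA when unused)
#' @slot b_buffer first-order P binding buffer power (optional, NA)
#' @seealso [uptakeParams()], [solveUptake()], [fitUptake()]
#' @export
setClass("UptakeParams",
  representation(D_eff = "numeric", r_m = "numeric", lambda_h = "numeric",
                 F_max = "numeric", c_inf = "numeric",
                 theta = "numeric", b_buffer = "numeric"),
  prototype(D_eff = 1.05e-8, r_m = 5e-4, lambda_h = 0, F_max = 0,
            c_inf = 1, theta = NA_real_, b_buffer = NA_real_))

setValidity("UptakeParams", function(object) {
  msgs <- character()
  if (object@D_eff <= 0) msgs <- c(msgs, "'D_eff' must be > 0")
  if (object@r_m <= 0) msgs <- c(msgs, "'r_m' must be > 0")
  if (object@lambda_h < 0) msgs <- c(msgs, "'lambda_h' must be >= 0")
  if (object@F_max < 0) msgs <- c(msgs, "'F_max' must be >= 0")
  if (object@c_inf <= 0) msgs <- c(msgs, "'c_inf' must be > 0")
  both <- !is.na(object@theta) && !is.na(object@b_buffer)
  if (both && (object@theta <= 0 || object@b_buffer <= 0)) {
    msgs <- c(msgs, "'theta' and 'b_buffer' must be > 0 when set")
  }
  if (length(msgs)) msgs else TRUE
})

#' Total soil-phosphorus field on a space-time grid
#'
#' Result of [solveUptake()]: the total P concentration
#' \eqn{c_{TOT}(x, t)} plus the cumulative boundary and hyphal-sink fluxes
#' accumulated consistently with the discrete scheme, which makes an exact
#' mass-balance audit possible via [massBalance()].
#'
#' @slot x_grid cm, ascending, starting at 0
#' @slot t_grid s, ascending, starting at 0
#' @slot c_tot matrix `length(x_grid)` x `length(t_grid)`
#' @slot params the [UptakeParams-class] used
#' @slot root_efflux cumulative P removed through the x = 0 Robin boundary
#'   per unit cross-section, at each `t_grid` point
#' @slot far_influx cumulative P supplied through the x = L boundary
#' @slot hyphal_uptake cumulative P removed by the hyphal sink term
#' @export
setClass("ConcentrationSolution",
  representation(x_grid = "numeric", t_grid = "numeric", c_tot = "matrix",
                 params = "UptakeParams", root_efflux = "numeric",
                 far_influx = "numeric", hyphal_uptake = "numeric"))

setValidity("ConcentrationSolution", function(object) {
  msgs <- character()
  if (!.is_ascending(object@x_grid)) msgs <- c(msgs, "'x_grid' must be ascending")
  if (!.is_ascending(object@t_grid)) msgs <- c(msgs, "'t_grid' must be ascending")
  if (!identical(dim(object@c_tot),
                 c(length(object@x_grid), length(object@t_grid)))) {
    msgs <- c(msgs, "'c_tot' must be length(x_grid) x length(t_grid)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a bounded least-squares fit
#'
#' @slot estimates named numeric vector of parameter estimates
#' @slot objective residual sum of squares at the optimum
#' @slot r2 coefficient of determination of model vs observations
#' @slot n_starts number of multi-start initialisations used
#' @slot converged logical, did the best start converge
#' @slot bounds list with `lower` and `upper` named vectors
#' @slot seed integer seed that drove the starts
#' @slot diagnostics list: per-start endpoints, identifiability flags,
#'   condition number of the Gauss-Newton approximation, warnings
#' @export
setClass("FitResult",
  representation(estimates = "numeric", objective = "numeric", r2 = "numeric",
                 n_starts = "integer", converged = "logical", bounds = "list",
                 seed = "integer", diagnostics = "list"),
  prototype(diagnostics = list(), seed = NA_integer_))

setValidity("FitResult", function(object) {
  msgs <- character()
  if (length(object@objective) != 1L || object@objective < 0) {
    msgs <- c(msgs, "'objective' must be a scalar >= 0")
  }
  if (length(object@r2) == 1L && is.finite(object@r2) && object@r2 > 1 + 1e-12) {
    msgs <- c(msgs, "'r2' cannot exceed 1")
  }
  lo <- object@bounds$lower; hi <- object@bounds$upper
  if (!is.null(lo) && !is.null(hi)) {
    p <- intersect(names(object@estimates), intersect(names(lo), names(hi)))
    ok <- all(object@estimates[p] >= lo[p] - 1e-12) &&
      all(object@estimates[p] <= hi[p] + 1e-12)
    if (!isTRUE(ok)) msgs <- c(msgs, "estimates must lie within bounds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Replicate-aggregated fit summary
#'
#' Per-parameter mean and sample standard deviation (n - 1 denominator)
#' across replicate fits, in the reporting style "mean +/- SD".
#'
#' @slot mean named numeric vector
#' @slot sd named numeric vector (0 when all replicate estimates agree)
#' @slot replicates data.frame of per-replicate estimates plus `r2`
#' @export
setClass("AggregateFit",
  representation(mean = "numeric", sd = "numeric", replicates = "data.frame"))

#' Filament network extracted from a voxel skeleton
#'
#' Branch-graph representation of a skeletonised hyphal network: nodes are
#' end-points and (merged) junctions, branches are ordered 3D polylines
#' between nodes, and clusters are connected components.
#'
#' @slot nodes data.frame: `id`, `x_um`, `y_um`, `z_um`, `degree`
#' @slot branches list of polylines (n x 3 matrices, um coordinates)
#' @slot branch_nodes integer matrix (n_branches x 2) of endpoint node ids
#' @slot branch_length numeric, arc length per branch (um)
#' @slot cluster integer cluster id per branch
#' @slot voxel_size voxel edge length (um)
#' @seealso [voxelSkeletonToGraph()], [skeletonFromPolylines()],
#'   [computeMetrics()]
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", branches = "list",
                 branch_nodes = "matrix", branch_length = "numeric",
                 cluster = "integer", voxel_size = "numeric"))

setValidity("SkeletonGraph", function(object) {
  nb <- length(object@branches)
  msgs <- character()
  if (length(object@branch_length) != nb || length(object@cluster) != nb) {
    msgs <- c(msgs, "branch attributes must match the number of branches")
  }
  if (nb > 0L) {
    chord <- vapply(object@branches, function(p) {
      sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
    }, numeric(1))
    if (any(object@branch_length < chord - 1e-6)) {
      msgs <- c(msgs, "arc length must be >= endpoint Euclidean distance")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Morphometric summary of a hyphal skeleton
#'
#' @slot total_length_um total hyphal length (um)
#' @slot length_density_cm2 cm hyphae per cm^3 analysed volume
#' @slot n_clusters number of discrete hyphal clusters
#' @slot branches_per_cluster integer vector, branches in each cluster
#' @slot mean_branch_length_um mean branch arc length (um)
#' @slot tortuosity arc-chord ratio per branch (>= 1); loops excluded
#' @slot angle_deg orientation of each branch end-to-end vector to the
#'   compartment midline, folded to `[0, 90]` degrees; loops excluded
#' @slot n_zero_chord number of zero-chord (loop) branches excluded
#' @export
setClass("HyphalMetrics",
  representation(total_length_um = "numeric", length_density_cm2 = "numeric",
                 n_clusters = "integer", branches_per_cluster = "integer",
                 mean_branch_length_um = "numeric", tortuosity = "numeric",
                 angle_deg = "numeric", n_zero_chord = "integer"))

setValidity("HyphalMetrics", function(object) {
  msgs <- character()
  if (any(object@tortuosity < 1 - 1e-9)) msgs <- c(msgs, "tortuosity must be >= 1")
  if (any(object@angle_deg < -1e-9 | object@angle_deg > 90 + 1e-9)) {
    msgs <- c(msgs, "angles must lie in [0, 90] degrees")
  }
  if (length(msgs)) msgs else TRUE
})

#' Registered multi-element XRF map
#'
#' Per-element 2D intensity/concentration images on a common pixel grid,
#' with the affine placement of the plane in the 3D tomography frame.
#'
#' @slot elements named list of numeric matrices (typically P, S, Al, Si),
#'   all the same shape
#' @slot pixel_size_um pixel edge length (um)
#' @slot units `"counts"` or `"ug_g"`
#' @slot affine 3 x 4 row-major affine mapping pixel (row, col, 0) + 1-based
#'   indices to 3D volume coordinates in um; default identity
#' @slot truth optional list of planted ground truth (synthetic maps)
#' @export
setClass("XRFMap",
  representation(elements = "list", pixel_size_um = "numeric",
                 units = "character", affine = "matrix", truth = "list"),
  prototype(units = "counts",
            affine = cbind(diag(3), c(0, 0, 0)), truth = list()))

setValidity("XRFMap", function(object) {
  msgs <- character()
  if (length(object@elements) < 1L || is.null(names(object@elements))) {
    return("'elements' must be a named non-empty list of matrices")
  }
  shp <- dim(object@elements[[1L]])
  same <- all(vapply(object@elements,
                     function(m) is.matrix(m) && identical(dim(m), shp),
                     logical(1)))
  if (!same) msgs <- c(msgs, "all element arrays must share one shape")
  if (object@pixel_size_um <= 0) msgs <- c(msgs, "'pixel_size_um' must be > 0")
  if (!identical(dim(object@affine), c(3L, 4L))) {
    msgs <- c(msgs, "'affine' must be a 3 x 4 matrix")
  }
  if (length(msgs)) msgs else TRUE
})

#' An energy-resolved XANES spectrum
#'
#' @slot energy_ev strictly increasing energies (eV), >= 20 points
#' @slot intensity fluorescence/absorption intensities
#' @slot edge `"P-K"` or `"S-K"`
#' @slot distance_um optional annotation: distance from hyphae or from the
#'   root-compartment interface (NA when unannotated)
#' @export
setClass("Spectrum",
  representation(energy_ev = "numeric", intensity = "numeric",
                 edge = "character", distance_um = "numeric"),
  prototype(edge = "S-K", distance_um = NA_real_))

setValidity("Spectrum", function(object) {
  msgs <- character()
  if (length(object@energy_ev) < 20L) msgs <- c(msgs, "at least 20 points required")
  if (!.is_ascending(object@energy_ev)) {
    msgs <- c(msgs, "'energy_ev' must be strictly increasing")
  }
  if (length(object@intensity) != length(object@energy_ev)) {
    msgs <- c(msgs, "'intensity' must match 'energy_ev' in length")
  }
  if (length(msgs)) msgs else TRUE
})

#' Linear-combination fit of a spectrum against a standards library
#'
#' Weights are non-negative and sum to one (enforced through an
#' augmented-row constraint inside the non-negative least-squares solve,
#' not by renormalisation).
#'
#' @slot weights named numeric vector, one weight per standard
#' @slot rss residual sum of squares
#' @slot r_factor sum((data - fit)^2) / sum(data^2)
#' @slot fitted fitted intensities on the common grid
#' @slot diagnostics list (condition number, warnings)
#' @export
setClass("LCFResult",
  representation(weights = "numeric", rss = "numeric", r_factor = "numeric",
                 fitted = "numeric", diagnostics = "list"),
  prototype(diagnostics = list()))

setValidity("LCFResult", function(object) {
  msgs <- character()
  if (any(object@weights < -1e-12)) msgs <- c(msgs, "weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-6) {
    msgs <- c(msgs, "weights must sum to 1 within 1e-6")
  }
  if (object@r_factor < 0) msgs <- c(msgs, "R-factor must be >= 0")
  if (length(msgs)) msgs else TRUE
})
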