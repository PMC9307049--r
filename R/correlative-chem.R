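#' Construct an XRF elemental map
#'
#' @param elements named list of same-shape numeric matrices (e.g. `P`,
#'   `S`, `Al`, `Si`)
#' @param pixel_size_um pixel edge length (um)
#' @param units `"counts"` (raw detector counts) or `"ug_g"` (calibrated);
#'   all class logic downstream is unit-agnostic
#' @param affine 3 x 4 matrix placing pixel (row, col) centres in the 3D
#'   volume frame (um): `xyz = A %*% c(row, col, 0, 1)`. Default identity.
#' @param truth optional planted-truth list (synthetic maps)
#' @return an [XRFMap-class]
#' @export
xrfMap <- function(elements, pixel_size_um, units = "counts",
                   affine = cbind(diag(3), c(0, 0, 0)), truth = list()) {
  new("XRFMap", elements = elements, pixel_size_um = pixel_size_um,
      units = units, affine = affine, truth = truth)
}

#' Exact 3D Euclidean distance transform of a hyphal mask
#'
#' Distance (um) from every voxel centre to the nearest foreground
#' (hyphal) voxel centre, computed exactly by the separable lower-envelope
#' algorithm.
#'
#' @param hyphal_mask 3D array, non-zero where hyphae are present
#' @param voxel_size voxel edge length (um, isotropic)
#' @return 3D numeric array of distances (um); zero exactly on hyphae
#' @export
distanceTransform3D <- function(hyphal_mask, voxel_size = 1) {
  .assert(is.array(hyphal_mask) && length(dim(hyphal_mask)) == 3L,
          "'hyphal_mask' must be a 3D array", "mycouptake_invalid_parameter")
  .assert(voxel_size > 0, "'voxel_size' must be > 0", "mycouptake_invalid_parameter")
  m <- hyphal_mask != 0
  .assert(any(m), "mask is empty: distances to hyphae are undefined",
          "mycouptake_empty_mask")
  d2 <- .edt3d_sq(as.logical(m), dim(m), voxel_size)
  array(sqrt(d2), dim(m))
}

#' Classify XRF pixels into soil phases
#'
#' Pixels are `air` when the summed signal over all elements falls below
#' `air_threshold_total`, otherwise `primary` (mineral grain) when the Si
#' signal exceeds `si_threshold`, otherwise `mixed` (clay-water-organic
#' phase). Excluding high-Si pixels from the mixed phase also guards
#' against Si signal overflowing into the neighbouring P and Al channels.
#'
#' @param map an [XRFMap-class] containing an `Si` element
#' @param air_threshold_total threshold on the summed elemental signal
#' @param si_threshold threshold on the Si signal
#' @return matrix of labels (`"air"`, `"primary"`, `"mixed"`), same shape
#'   as the element maps
#' @export
classifyPhases <- function(map, air_threshold_total, si_threshold) {
  stopifnot(is(map, "XRFMap"))
  .assert(air_threshold_total > 0 && si_threshold > 0,
          "thresholds must be > 0", "mycouptake_invalid_parameter")
  .assert("Si" %in% names(map@elements), "map must contain an 'Si' element",
          "mycouptake_invalid_parameter")
  total <- Reduce(`+`, map@elements)
  lab <- matrix("mixed", nrow(total), ncol(total))
  lab[map@elements$Si > si_threshold] <- "primary"
  lab[total < air_threshold_total] <- "air"
  lab
}

#' Distance classes relative to the nearest hyphal surface
#'
#' `close` when distance <= `close_um` (inclusive at the boundary), `far`
#' when distance > `far_um` (exclusive: strictly further), otherwise
#' `neither`.
#'
#' @param dist matrix of per-pixel distances to hyphae (um)
#' @param close_um,far_um class boundaries (um), `close_um < far_um`;
#'   defaults 50 and 200
#' @return matrix of labels `"close"`, `"far"`, `"neither"`
#' @export
distanceClasses <- function(dist, close_um = 50, far_um = 200) {
  .assert(close_um < far_um, "'close_um' must be below 'far_um'",
          "mycouptake_invalid_parameter")
  lab <- matrix("neither", nrow(dist), ncol(dist))
  lab[dist <= close_um] <- "close"
  lab[dist > far_um] <- "far"
  if (!any(lab == "close")) warning("close distance class is empty")
  if (!any(lab == "far")) warning("far distance class is empty")
  lab
}

#' Close-vs-far statistics of one element in the mixed phase
#'
#' Restricted to mixed-phase pixels, compares the element's values between
#' the close and far distance classes: class means and counts, normalised
#' histograms (bars sum to 1 per class), a two-sample t-test (equal
#' variance by default, the generic two-sample form) and a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param map an [XRFMap-class]
#' @param phases phase labels from [classifyPhases()]
#' @param classes distance-class labels from [distanceClasses()]
#' @param element element name present in the map
#' @param bin_width histogram bin width in the map's units (default 1000,
#'   the conventional raw-count bin)
#' @param var_equal use the pooled-variance t-test (default TRUE)
#' @return list: `means`, `counts`, `histograms` (per class: `mid`,
#'   `prob`), `t_test`, `ks_test`
#' @export
classStatistics <- function(map, phases, classes, element,
                            bin_width = 1000, var_equal = TRUE) {
  stopifnot(is(map, "XRFMap"))
  .assert(element %in% names(map@elements),
          sprintf("element '%s' not in map", element),
          "mycouptake_invalid_parameter")
  vals <- map@elements[[element]]
  keep <- phases == "mixed"
  close_v <- vals[keep & classes == "close"]
  far_v <- vals[keep & classes == "far"]
  for (nm in c("close", "far")) {
    nv <- if (nm == "close") length(close_v) else length(far_v)
    .assert(nv >= 2L,
            sprintf("distance class '%s' has %d mixed-phase pixel(s); need >= 2",
                    nm, nv),
            "mycouptake_empty_class")
  }
  rng <- range(c(close_v, far_v))
  breaks <- seq(floor(rng[1L] / bin_width) * bin_width,
                ceiling(rng[2L] / bin_width) * bin_width + bin_width,
                by = bin_width)
  histo <- function(v) {
    h <- hist(v, breaks = breaks, plot = FALSE)
    list(mid = h$mids, prob = h$counts / length(v))
  }
  identical_samples <- length(close_v) == length(far_v) &&
    all(sort(close_v) == sort(far_v))
  tt <- if (identical_samples) {
    list(statistic = c(t = 0), p.value = 1)
  } else {
    t.test(close_v, far_v, var.equal = var_equal)
  }
  ks <- if (identical_samples) {
    list(statistic = c(D = 0), p.value = 1)
  } else {
    suppressWarnings(ks.test(close_v, far_v))
  }
  list(element = element,
       means = c(close = mean(close_v), far = mean(far_v)),
       counts = c(close = length(close_v), far = length(far_v)),
       histograms = list(close = histo(close_v), far = histo(far_v)),
       t_test = list(statistic = unname(tt$statistic), p = tt$p.value),
       ks_test = list(statistic = unname(ks$statistic), p = ks$p.value))
}

#' High/low elemental classes and their distances to hyphae
#'
#' Labels each mixed-phase pixel high or low in each element relative to a
#' threshold, then summarises compound classes (conjunctions such as
#' high-P & low-Al) by pixel count, mean distance to hyphae, a distance
#' histogram and the fraction of pixels within 100 um of hyphae. With
#' `thresholds = "from-close-means"` each element's threshold is the mean
#' value of mixed-phase pixels within the close distance class, mirroring
#' the convention of defining "high P" against the near-hypha mean.
#'
#' @param map an [XRFMap-class]
#' @param phases labels from [classifyPhases()]
#' @param dist distance plane (um)
#' @param thresholds `"from-close-means"` or a named numeric vector of
#'   explicit per-element thresholds
#' @param pairs list of length-2 character vectors naming compound
#'   classes, each entry `"<element>+"` (high) or `"<element>-"` (low)
#' @param close_um close-class boundary used for `"from-close-means"`
#' @param bin_um distance histogram bin width (default 100 um)
#' @return list with `thresholds` and per-pair summaries (`n`,
#'   `mean_distance_um`, `fraction_within_100um`, `hist`); empty compound
#'   classes are reported with `n = 0`, never as silent NaN
#' @export
elementalClasses <- function(map, phases, dist, thresholds = "from-close-means",
                             pairs = list(c("P+", "Al-"), c("P+", "Al+"),
                                          c("S+", "Al-"), c("S+", "Al+")),
                             close_um = 50, bin_um = 100) {
  stopifnot(is(map, "XRFMap"))
  mixed <- phases == "mixed"
  .assert(any(mixed), "no mixed-phase pixels", "mycouptake_empty_class")
  elems <- unique(sub("[+-]$", "", unlist(pairs)))
  .assert(all(elems %in% names(map@elements)),
          "all pair elements must be present in the map",
          "mycouptake_invalid_parameter")
  if (identical(thresholds, "from-close-means")) {
    close_mask <- mixed & dist <= close_um
    .assert(any(close_mask),
            "close class empty: cannot derive thresholds from close means",
            "mycouptake_empty_class")
    thr <- vapply(elems, function(e) mean(map@elements[[e]][close_mask]),
                  numeric(1))
  } else {
    .assert(is.numeric(thresholds) && all(elems %in% names(thresholds)),
            "explicit thresholds must be a named numeric vector covering all pair elements",
            "mycouptake_invalid_parameter")
    thr <- thresholds[elems]
  }
  high <- lapply(elems, function(e) map@elements[[e]] > thr[[e]])
  names(high) <- elems

  summarise_pair <- function(pair) {
    sel <- mixed
    for (tag in pair) {
      e <- sub("[+-]$", "", tag)
      sel <- sel & (if (grepl("\\+$", tag)) high[[e]] else !high[[e]])
    }
    d <- dist[sel]
    if (length(d) == 0L) {
      return(list(pair = paste(pair, collapse = " & "), n = 0L,
                  mean_distance_um = NA_real_,
                  fraction_within_100um = NA_real_, hist = NULL))
    }
    breaks <- seq(0, ceiling(max(d) / bin_um) * bin_um + bin_um, by = bin_um)
    h <- hist(d, breaks = breaks, plot = FALSE)
    list(pair = paste(pair, collapse = " & "), n = length(d),
         mean_distance_um = mean(d),
         fraction_within_100um = mean(d <= 100),
         hist = list(mid = h$mids, prob = h$counts / length(d)))
  }
  out <- lapply(pairs, summarise_pair)
  names(out) <- vapply(out, `[[`, character(1), "pair")
  list(thresholds = thr, classes = out)
}

#' Sample a 3D distance field onto an XRF map plane
#'
#' Maps every pixel centre through the map's affine placement into the
#' 3D volume frame and samples the field at the nearest voxel. The affine
#' takes 1-based (row, col, 0, 1) pixel coordinates to continuous 1-based
#' voxel coordinates.
#'
#' @param map an [XRFMap-class] carrying the affine placement
#' @param field 3D numeric array (e.g. from [distanceTransform3D()])
#' @return matrix of sampled values, one per map pixel
#' @export
registerPlane <- function(map, field) {
  stopifnot(is(map, "XRFMap"))
  .assert(is.array(field) && length(dim(field)) == 3L,
          "'field' must be a 3D array", "mycouptake_invalid_parameter")
  A <- map@affine
  .assert(abs(det(A[, 1:3])) > 1e-12, "affine must be invertible",
          "mycouptake_invalid_parameter")
  shp <- dim(map@elements[[1L]])
  px <- as.matrix(expand.grid(row = seq_len(shp[1L]), col = seq_len(shp[2L])))
  xyz <- t(A %*% rbind(t(px), 0, 1))
  vox <- round(xyz)
  dims <- dim(field)
  inside <- vox[, 1L] >= 1 & vox[, 1L] <= dims[1L] &
    vox[, 2L] >= 1 & vox[, 2L] <= dims[2L] &
    vox[, 3L] >= 1 & vox[, 3L] <= dims[3L]
  if (!all(inside)) {
    bad <- xyz[!inside, , drop = FALSE]
    stop(errorCondition(
      sprintf("plane extends outside the volume: %d pixel(s), e.g. voxel (%.1f, %.1f, %.1f) vs dims (%d, %d, %d)",
              sum(!inside), bad[1, 1], bad[1, 2], bad[1, 3],
              dims[1L], dims[2L], dims[3L]),
      class = c("mycouptake_out_of_bounds", "mycouptake_error")))
  }
  vals <- field[cbind(vox[, 1L], vox[, 2L], vox[, 3L])]
  matrix(vals, shp[1L], shp[2L])
}
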