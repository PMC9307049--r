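common_grid <- seq(2460, 2500, by = 0.25)

test_that("preprocessing is idempotent, scale-invariant and interpolates exactly", {
  gx <- genXANES(snr = Inf, seed = 1)
  norm1 <- preprocessSpectrum(gx$standards$thiol, common_grid,
                              pre_edge_ev = c(2460, 2466),
                              post_edge_ev = c(2494, 2500))
  norm2 <- preprocessSpectrum(norm1, common_grid,
                              pre_edge_ev = c(2460, 2466),
                              post_edge_ev = c(2494, 2500))
  expect_equal(norm2@intensity, norm1@intensity, tolerance = 1e-12)

  scaled <- xanesSpectrum(gx$standards$thiol@energy_ev,
                          5 * gx$standards$thiol@intensity)
  norm5 <- preprocessSpectrum(scaled, common_grid,
                              pre_edge_ev = c(2460, 2466),
                              post_edge_ev = c(2494, 2500))
  expect_equal(norm5@intensity, norm1@intensity, tolerance = 1e-12)

  ramp <- xanesSpectrum(seq(0, 100, by = 1), 2 * seq(0, 100, by = 1) + 3)
  grid <- seq(0.5, 99.5, by = 0.5)
  interp <- approx(ramp@energy_ev, ramp@intensity, xout = grid)$y
  expect_equal(interp, 2 * grid + 3)

  expect_error(preprocessSpectrum(gx$standards$thiol, seq(2000, 2100, 1)),
               class = "mycouptake_invalid_grid")
})

test_that("LCF returns exact weights for pure standards and is idempotent", {
  gx <- genXANES(snr = Inf, seed = 1)
  f <- lcfFit(gx$standards$sulfonate, gx$standards)
  expect_equal(unname(lcfWeights(f)),
               c(0, 1, 0), tolerance = 1e-8)
  expect_lt(f@rss, 1e-12)

  mixfit <- lcfFit(gx$mixture, gx$standards)
  refit <- lcfFit(xanesSpectrum(gx$mixture@energy_ev, mixfit@fitted),
                  gx$standards)
  expect_equal(lcfWeights(refit), lcfWeights(mixfit), tolerance = 1e-10)
  expect_lt(abs(sum(lcfWeights(mixfit)) - 1), 1e-6)
})

test_that("planted two-component mixtures are recovered within 0.02 at SNR 50", {
  errs <- vapply(1:20, function(s) {
    gx <- genXANES(weights = c(thiol = 0.6, sulfonate = 0, sulfate = 0.4),
                   snr = 50, seed = s)
    w <- lcfWeights(lcfFit(gx$mixture, gx$standards))
    mean(abs(w - c(0.6, 0, 0.4)))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("recovery error decreases with SNR", {
  err_at <- function(snr) {
    mean(vapply(1:25, function(s) {
      gx <- genXANES(weights = c(thiol = 0.5, sulfonate = 0.2, sulfate = 0.3),
                     snr = snr, seed = 500 + s)
      mean(abs(lcfWeights(lcfFit(gx$mixture, gx$standards)) -
                 c(0.5, 0.2, 0.3)))
    }, numeric(1)))
  }
  errs <- vapply(c(15, 50, 200), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("mismatched edges and rank deficiency are reported", {
  gx <- genXANES(snr = Inf, seed = 1)
  pk <- xanesSpectrum(gx$mixture@energy_ev, gx$mixture@intensity, edge = "P-K")
  expect_error(lcfFit(pk, gx$standards), class = "mycouptake_edge_mismatch")

  dup <- list(a = gx$standards$thiol, b = gx$standards$thiol)
  expect_warning(lcfFit(gx$mixture, dup), "rank-deficient")
})

test_that("speciation fractions aggregate correctly versus distance", {
  # single bin: the bin mean is the plain mean of the fractions
  sets <- lapply(1:3, function(i) {
    genXANES(weights = c(thiol = 0.3 + 0.1 * i, sulfonate = 0.2,
                         sulfate = 0.5 - 0.1 * i),
             snr = Inf, distance_um = 10 * i, seed = i)
  })
  spectra <- lapply(sets, `[[`, "mixture")
  standards <- sets[[1]]$standards
  tr <- speciationVsDistance(spectra, standards, bins = c(0, 100))
  expect_equal(tr$n, 3L)
  expect_equal(tr$mean_reduced, mean(c(0.4, 0.5, 0.6)), tolerance = 1e-6)
  expect_equal(tr$mean_reduced + tr$mean_oxidized, 1, tolerance = 1e-6)

  # planted monotone oxidation gradient is recovered across bins
  grad <- lapply(1:8, function(i) {
    d <- 50 * i
    red <- 0.8 - 0.08 * i
    genXANES(weights = c(thiol = red, sulfonate = 0.4 * (1 - red),
                         sulfate = 0.6 * (1 - red)),
             snr = 200, distance_um = d, seed = 40 + i)
  })
  tr2 <- speciationVsDistance(lapply(grad, `[[`, "mixture"),
                              grad[[1]]$standards,
                              bins = c(0, 100, 200, 300, 450))
  expect_true(all(diff(tr2$mean_reduced) < 0))
  expect_true(all(diff(tr2$mean_oxidized) > 0))
  expect_equal(tr2$mean_reduced + tr2$mean_oxidized, rep(1, 4),
               tolerance = 1e-6)

  unann <- genXANES(snr = Inf, seed = 1)$mixture
  expect_error(speciationVsDistance(list(unann), standards, c(0, 100)),
               class = "mycouptake_invalid_parameter")
})
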