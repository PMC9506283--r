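test_that("Fresnel reflectivity has the water critical edge and asymptote", {
  qc <- critical_qz(0.334)
  # printed critical angle of pure water at 8 keV: (4 pi / 1.55) sin(0.154 deg)
  expect_equal(qc, 4 * pi / 1.55 * sin(0.154 * pi / 180), tolerance = 5e-3)
  expect_equal(qc, 0.0218, tolerance = 5e-3)

  expect_equal(fresnel(c(qc / 2, qc * 0.999)), c(1, 1))
  expect_equal(fresnel(10 * qc), (qc / (2 * 10 * qc))^4, tolerance = 0.05)
  expect_error(fresnel(0.1, subphase_rho_e = -1), "positive")
})

test_that("zero-contrast stacks collapse to the bare Fresnel curve", {
  qz <- seq(0.02, 0.6, 0.002)
  m <- slab_model(c(20, 10), c(0.334, 0.334), sigma = 0)
  out <- slab_reflectivity(m, qz)
  expect_equal(out$R, fresnel(qz), tolerance = 1e-14)
  expect_equal(out$RRF, rep(1, length(qz)), tolerance = 1e-14)
})

test_that("single-slab fringes follow the interference condition", {
  m <- slab_model(25, 0.42, sigma = 0)
  qz <- seq(0.05, 0.6, 2e-4)
  rrf <- slab_reflectivity(m, qz)$RRF
  mins <- which(diff(sign(diff(rrf))) > 0) + 1L
  spacing <- diff(qz[mins])
  expect_lt(max(abs(spacing - 2 * pi / 25) / (2 * pi / 25)), 0.02)
})

test_that("Parratt recursion agrees with a transfer-matrix oracle", {
  m <- slab_model(c(17.3, 9.0), c(0.30, 0.45),
    sigma = c(2.5, 3.2),
    subphase_sigma = 3.0
  )
  qz <- seq(0.01, 0.7, 0.004) # includes below-critical points
  R <- slab_reflectivity(m, qz)$R
  R_tm <- oracle_transfer_matrix(m, qz)
  expect_lt(max(abs(R - R_tm) / pmax(R_tm, 1e-300)), 1e-10)
})

test_that("forward model is invariant under splitting a slab", {
  qz <- seq(0.02, 0.6, 0.002)
  one <- slab_model(c(26.3), c(0.38), sigma = 0)
  two <- slab_model(c(10, 16.3), c(0.38, 0.38), sigma = 0)
  expect_equal(slab_reflectivity(two, qz)$R, slab_reflectivity(one, qz)$R,
    tolerance = 1e-12
  )
})

test_that("normalised reflectivity oscillates about unity at large qz", {
  # for a sharp finite stack R/R_F keeps fringing at large qz within a
  # band set by the interface contrasts, straddling 1 with a geometric
  # mean of order 1
  m <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 0)
  qz <- seq(3, 3 + 2 * pi / 26.3, length.out = 400) # one full fringe
  rrf <- slab_reflectivity(m, qz)$RRF
  expect_lt(min(rrf), 1)
  expect_gt(max(rrf), 1)
  expect_lt(abs(log(exp(mean(log(rrf))))), log(2))
})

test_that("first minimum sits where the two-slab film thickness puts it", {
  m <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 3)
  fm <- first_minimum(slab_reflectivity(m, seq(0.03, 0.45, 2e-4)))
  expect_equal(fm, (3 * pi / 2) / (17.3 + 9.0 / 2), tolerance = 0.01)

  # a bare interface has no minimum
  qz <- seq(0.03, 0.5, 0.001)
  bare <- slab_reflectivity(slab_model(), qz)
  expect_error(first_minimum(bare), "no local minimum")

  # single slab less dense than the subphase: same-sign interface
  # reflections interfere destructively first at qz ~ pi/d (checked
  # against the forward model itself)
  d <- 24
  ms <- slab_model(d, 0.30, sigma = 0)
  fms <- first_minimum(slab_reflectivity(ms, seq(0.03, 0.45, 2e-4)))
  expect_equal(fms, pi / d, tolerance = 0.05)
})

test_that("electron density profile is an erf-smeared conservative step stack", {
  m0 <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 0)
  z <- seq(-40, 70, 0.01)
  p0 <- density_profile(m0, z)
  expect_equal(p0$rho[z > 1 & z < 16], rep(0.30, sum(z > 1 & z < 16)))
  expect_equal(p0$rho[z > 18 & z < 26], rep(0.45, sum(z > 18 & z < 26)))
  expect_equal(p0$rho[z < -0.5][1], 0)
  expect_equal(p0$rho[length(z)], 0.334)

  m3 <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 3, subphase_sigma = 3)
  p3 <- density_profile(m3, z)
  # erf smearing conserves the integrated density: the smooth profile
  # integrates to the exact analytic step-stack integral
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2) * 0.01
  exact <- 0.30 * 17.3 + 0.45 * 9.0 + 0.334 * (70 - 26.3)
  expect_equal(trapz(p3$rho), exact, tolerance = 1e-6)
})

test_that("slab fit recovers itself and noisy synthetic thicknesses", {
  truth <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 3)
  qz <- seq(0.02, 0.6, length.out = 250)
  clean <- slab_reflectivity(truth, qz)
  self_fit <- fit_reflectivity(clean, init = truth)
  expect_lt(self_fit$residual_sd_logR, 1e-8)
  expect_equal(self_fit$model$slabs$thickness, c(17.3, 9.0), tolerance = 1e-6)
  expect_equal(self_fit$d_tot, 26.3, tolerance = 1e-6)

  noisy <- gen_reflectivity(truth, qz, noise_rel = 0.02, seed = 19)
  fit <- fit_reflectivity(noisy,
    init = slab_model(c(14, 11), c(0.33, 0.41), sigma = 2.5)
  )
  expect_equal(fit$model$slabs$thickness, c(17.3, 9.0), tolerance = 0.05)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true(all(is.finite(td$std.error[!td$fixed])))
})

test_that("slab fit validates inputs and honours fixed parameters", {
  truth <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 3)
  few <- slab_reflectivity(truth, seq(0.05, 0.3, length.out = 20))
  expect_error(fit_reflectivity(few, init = truth), "5 data points")

  qz <- seq(0.02, 0.6, length.out = 200)
  noisy <- gen_reflectivity(truth, qz, noise_rel = 0.02, seed = 3)
  fit <- fit_reflectivity(noisy, init = truth, fixed = c("rho1", "rho2"))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "rho1"], 0.30)
  expect_true(td$fixed[td$term == "rho2"])
  expect_error(fit_reflectivity(noisy, init = truth, fixed = "bogus"), "unknown")
})
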