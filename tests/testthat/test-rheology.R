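test_that("noiseless single-exponential transients are recovered near-exactly", {
  tr <- gen_relaxation(1.0, 0.5, 100, time = seq(0, 900, 0.5))
  fit <- fit_relaxation(tr)
  expect_equal(fit$n_modes, 1L)
  expect_equal(fit$delta_pi_inf, 1.0, tolerance = 1e-4)
  expect_equal(fit$modes$amplitude, 0.5, tolerance = 1e-4)
  expect_equal(fit$modes$tau, 100, tolerance = 1e-4)
})

test_that("flat transients collapse to a zero-mode fit", {
  fit <- fit_relaxation(tibble::tibble(time = seq(0, 100, 1), delta_pi = 2.0))
  expect_equal(fit$n_modes, 0L)
  expect_equal(fit$delta_pi_inf, 2.0)
})

test_that("model selection finds two well-separated modes under noise", {
  tr <- gen_relaxation(1.0, c(0.5, 0.5), c(10, 1000),
    time = seq(0, 4000, 1),
    noise_sd = 0.01 * 2.0, seed = 42
  ) # noise = 1% of dpi(0)
  fit <- fit_relaxation(tr, max_modes = 3)
  expect_equal(fit$n_modes, 2L)
  expect_equal(fit$modes$tau, c(10, 1000), tolerance = 0.1)
})

test_that("closed-form spectrum matches the numerical Fourier-transform oracle", {
  nu <- 10^seq(log10(1e-4), 0, length.out = 25)
  fit <- list(
    delta_pi_inf = 1.0,
    modes = tibble::tibble(amplitude = c(0.5, 0.3), tau = c(20, 300))
  )
  sp <- spectrum_from_fit(fit, rel_area_change = 0.05, nu = nu)
  orc <- oracle_spectrum(1.0, c(0.5, 0.3), c(20, 300), 0.05, nu)
  expect_lt(max(abs(sp$storage - orc[1, ]) / orc[1, ]), 0.01)
  expect_lt(max(abs(sp$loss - orc[2, ]) / max(orc[2, ])), 0.01)
})

test_that("spectrum limits and loss maximum follow the Maxwell element", {
  fit <- list(
    delta_pi_inf = 1.0,
    modes = tibble::tibble(amplitude = 0.5, tau = 100)
  )
  u <- 0.05
  lims <- spectrum_from_fit(fit, u, nu = c(1e-8, 1e4))
  expect_equal(lims$storage[1], 1.0 / u, tolerance = 1e-6)    # G'(0)
  expect_equal(lims$storage[2], 1.5 / u, tolerance = 1e-6)    # G'(inf) = dpi(0)/u
  expect_lt(lims$loss[1] / lims$storage[1], 1e-5)
  expect_lt(lims$loss[2] / lims$storage[2], 1e-5)

  nu <- 10^seq(-4, 0, length.out = 2001)
  sp <- spectrum_from_fit(fit, u, nu = nu)
  numax <- sp$frequency[which.max(sp$loss)]
  expect_equal(numax, 1 / (2 * pi * 100), tolerance = 0.01)
  expect_equal(max(sp$loss), 0.5 / (2 * u), tolerance = 1e-4) # A1/(2u)

  # Kramers-Kronig-consistent shape: G' non-decreasing, G'' >= 0
  expect_true(all(diff(sp$storage) >= -1e-12))
  expect_true(all(sp$loss >= 0))
  # zero-shear dilatational viscosity: eta_D -> sum(A_i tau_i)/u
  expect_equal(lims$eta_D[1], 0.5 * 100 / u, tolerance = 1e-6)
  # dpi_inf >= A1/2 keeps the process predominantly elastic at all nu
  expect_true(all(sp$tan_phi < 1))
})

test_that("zero-mode spectra are purely elastic", {
  fit <- list(delta_pi_inf = 1.5, modes = tibble::tibble(
    amplitude = numeric(0), tau = numeric(0)
  ))
  sp <- spectrum_from_fit(fit, rel_area_change = 0.05)
  expect_true(all(sp$loss == 0))
  expect_true(all(sp$storage == 1.5 / 0.05))
  expect_true(all(sp$tan_phi == 0))
  expect_error(cole_cole(sp), "degenerate")
})

test_that("Cole-Cole deviation separates one- and two-step relaxation", {
  u <- 0.05
  one <- spectrum_from_fit(
    list(delta_pi_inf = 1, modes = tibble::tibble(amplitude = 0.5, tau = 100)),
    u,
    nu = 10^seq(-5, 1, length.out = 200)
  )
  cc1 <- cole_cole(one)
  expect_lt(cc1$deviation, 0.01)
  # exact semicircle: centre (G'(0)+G'(inf))/2, radius A1/(2u)
  expect_equal(cc1$center, (20 + 30) / 2, tolerance = 1e-6)
  expect_equal(cc1$radius, 0.5 / (2 * u), tolerance = 1e-6)

  two <- spectrum_from_fit(
    list(delta_pi_inf = 1, modes = tibble::tibble(
      amplitude = c(0.5, 0.5), tau = c(10, 1000)
    )),
    u,
    nu = 10^seq(-5, 1, length.out = 200)
  )
  expect_gt(cole_cole(two)$deviation, 0.05)

  expect_error(cole_cole(one[1:4, ]), "5")
})

test_that("plateau extraction flags non-plateau bands", {
  fit <- list(delta_pi_inf = 1, modes = tibble::tibble(amplitude = 0.5, tau = 100))
  sp <- spectrum_from_fit(fit, 0.05, nu = 10^seq(-4, 0, length.out = 200))
  pl <- plateau_modulus(sp) # band above 100 mHz >> 1/(2 pi tau)
  expect_equal(pl$plateau, 30, tolerance = 1e-4)
  expect_true(pl$is_plateau)

  low <- plateau_modulus(sp, band = c(1e-4, 1 / (2 * pi * 100)))
  expect_false(low$is_plateau)
  expect_error(plateau_modulus(sp, band = c(10, 20)), "band")

  fit0 <- list(delta_pi_inf = 1.5, modes = tibble::tibble(
    amplitude = numeric(0), tau = numeric(0)
  ))
  sp0 <- spectrum_from_fit(fit0, 0.05)
  expect_equal(plateau_modulus(sp0, band = c(1e-4, 1))$plateau, 30)
})

test_that("generate-fit-transform round trip reproduces the true spectrum", {
  nu <- 10^seq(-4, 0, length.out = 50)
  true_sp <- spectrum_from_fit(
    list(delta_pi_inf = 1, modes = tibble::tibble(amplitude = 0.5, tau = 100)),
    0.05,
    nu = nu
  )
  tr <- gen_relaxation(1, 0.5, 100, rel_area_change = 0.05, time = seq(0, 900, 0.5))
  sp <- spectrum_from_fit(fit_relaxation(tr), nu = nu)
  expect_lt(max(abs(sp$storage - true_sp$storage) / true_sp$storage), 0.01)
  expect_lt(max(abs(sp$loss - true_sp$loss) / max(true_sp$loss)), 0.01)
})

test_that("relaxation fit input validation", {
  expect_error(fit_relaxation(tibble::tibble(time = 0:5, delta_pi = 1:6)), "10")
  expect_error(
    fit_relaxation(tibble::tibble(time = seq(1, 20), delta_pi = rnorm(20))),
    "ascend from 0"
  )
  tr <- gen_relaxation(1, 0.5, 100)
  expect_error(spectrum_from_fit(fit_relaxation(tr, rel_area_change = NULL),
    rel_area_change = 0
  ), "positive")
})
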