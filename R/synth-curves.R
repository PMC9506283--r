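#' Generate a synthetic pressure-area isotherm
#'
#' Samples a parametric equation of state on a descending molecular-area
#' grid, optionally adding Gaussian sensor noise. Three models are
#' available:
#'
#' * `"ideal_gas"`: \eqn{\pi = kT/A}, the two-dimensional ideal gas.
#'   No coefficients.
#' * `"vdw2d"`: \eqn{\pi = kT/(A - A_0) - a/A^2}, a two-dimensional
#'   van-der-Waals-like film with excluded area `A0` (Å²) and attraction
#'   `a` ((mN/m)·Å⁴). Pressures are floored at zero (the film has not
#'   lifted off).
#' * `"piecewise_linear"`: zero pressure above the lift-off area, then a
#'   sequence of linear segments with slopes `slopes` (mN m⁻¹ Å⁻²,
#'   magnitudes of d\eqn{\pi}/dA) switching at the pressures
#'   `break_pressures`. Mimics the gradient change seen in condensed
#'   mixed monolayers.
#'
#' @param model One of `"ideal_gas"`, `"vdw2d"`, `"piecewise_linear"`.
#' @param coefficients Named list of model coefficients (see above).
#' @param temperature Subphase temperature, K.
#' @param area Molecular-area grid, Å²/molecule, strictly descending
#'   (compression). Default 100 to 20 Å².
#' @param noise_sd Additive Gaussian noise on pressure, mN/m.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param composition,subphase Free-text labels carried as metadata.
#' @return A tibble of class `ml_isotherm` with columns `area` and
#'   `pressure`, and attributes `temperature`, `composition`, `subphase`.
#' @examples
#' iso <- gen_isotherm("ideal_gas", temperature = 293)
#' head(iso)
#' @export
gen_isotherm <- function(model = c("ideal_gas", "vdw2d", "piecewise_linear"),
                         coefficients = list(),
                         temperature = 293,
                         area = seq(100, 20, length.out = 200),
                         noise_sd = 0,
                         seed = 1L,
                         composition = "synthetic",
                         subphase = "water") {
  model <- match.arg(model)
  if (any(area <= 0)) abort("molecular areas must be positive")
  if (any(diff(area) >= 0)) abort("`area` must be strictly descending (compression)")
  kT <- kT_monolayer(temperature)

  pressure <- switch(model,
    ideal_gas = kT / area,
    vdw2d = {
      A0 <- coefficients$excluded_area %||% 15
      a <- coefficients$attraction %||% 0
      if (any(area <= A0)) abort("areas must exceed the excluded area `A0`")
      pmax(kT / (area - A0) - a / area^2, 0)
    },
    piecewise_linear = {
      lift <- coefficients$liftoff_area %||% abort("piecewise_linear needs `liftoff_area`")
      slopes <- coefficients$slopes %||% abort("piecewise_linear needs `slopes`")
      breaks <- coefficients$break_pressures %||% numeric(0)
      if (length(breaks) != length(slopes) - 1L)
        abort("need one fewer `break_pressures` than `slopes`")
      if (any(slopes <= 0)) abort("segment slopes must be positive")
      piecewise_pressure(area, lift, slopes, breaks)
    }
  )
  if (any(pressure < 0)) abort("internal: negative noiseless pressure")

  if (noise_sd > 0) {
    pressure <- pressure + with_seed(seed, rnorm(length(area), 0, noise_sd))
  }

  new_ml_curve(tibble(area = area, pressure = pressure),
    class = "ml_isotherm",
    temperature = temperature, composition = composition, subphase = subphase
  )
}

# pi(A) for the piecewise-linear equation of state: segment i has slope
# slopes[i] (in -dpi/dA) and runs from pressure c(0, breaks)[i] up to
# breaks[i] (last segment unbounded).
piecewise_pressure <- function(area, liftoff_area, slopes, break_pressures) {
  seg_start_p <- c(0, break_pressures)
  seg_start_a <- liftoff_area
  out <- numeric(length(area))
  for (i in seq_along(slopes)) {
    if (i < length(slopes)) {
      seg_end_a <- seg_start_a - (break_pressures[i] - seg_start_p[i]) / slopes[i]
    } else {
      seg_end_a <- -Inf
    }
    sel <- area <= seg_start_a & area > seg_end_a
    out[sel] <- seg_start_p[i] + slopes[i] * (seg_start_a - area[sel])
    seg_start_a <- seg_end_a
  }
  out
}

#' Generate a synthetic stress-relaxation transient
#'
#' Evaluates the multi-exponential relaxation
#' \deqn{\Delta\pi(t) = \Delta\pi_\infty + \sum_i A_i e^{-t/\tau_i}}
#' on a time grid and adds Gaussian noise. This is the response of a
#' monolayer to a fast small compression (relative area change
#' \eqn{|\Delta A/A_0| \le 5\%}) followed by relaxation at constant area.
#'
#' @param delta_pi_inf Equilibrium pressure offset \eqn{\Delta\pi_\infty},
#'   mN/m (non-negative).
#' @param amplitudes Mode amplitudes \eqn{A_i}, mN/m (non-negative).
#' @param taus Relaxation times \eqn{\tau_i}, s (positive).
#' @param rel_area_change Magnitude of the applied relative area
#'   perturbation \eqn{|\Delta A/A_0|}, in (0, 0.05].
#' @param time Time grid, s, ascending from 0.
#' @param noise_sd Additive Gaussian noise, mN/m.
#' @param seed Integer seed.
#' @param target_pressure Target pressure \eqn{\pi_0}, mN/m (metadata).
#' @return A tibble of class `ml_transient` with columns `time`,
#'   `delta_pi` and attributes `rel_area_change`, `target_pressure`.
#' @examples
#' tr <- gen_relaxation(1, 0.5, 100, time = seq(0, 600, 1))
#' tr$delta_pi[1] # 1.5 at t = 0
#' @export
gen_relaxation <- function(delta_pi_inf, amplitudes = numeric(0),
                           taus = numeric(0),
                           rel_area_change = 0.05,
                           time = seq(0, 600, by = 0.5),
                           noise_sd = 0, seed = 1L,
                           target_pressure = 30) {
  if (length(amplitudes) != length(taus)) abort("amplitudes and taus must pair up")
  if (any(taus <= 0)) abort("relaxation times must be positive")
  if (any(amplitudes < 0) || delta_pi_inf < 0) abort("amplitudes and plateau must be non-negative")
  if (rel_area_change <= 0 || rel_area_change > 0.05)
    abort("rel_area_change must lie in (0, 0.05]")
  if (time[1] != 0 || any(diff(time) <= 0)) abort("time grid must ascend from 0")

  dp <- multi_exp(time, delta_pi_inf, amplitudes, taus)
  if (noise_sd > 0) dp <- dp + with_seed(seed, rnorm(length(time), 0, noise_sd))

  new_ml_curve(tibble(time = time, delta_pi = dp),
    class = "ml_transient",
    rel_area_change = rel_area_change, target_pressure = target_pressure
  )
}

multi_exp <- function(t, dp_inf, amplitudes, taus) {
  out <- rep_len(dp_inf, length(t))
  for (i in seq_along(amplitudes)) out <- out + amplitudes[i] * exp(-t / taus[i])
  out
}

#' Generate a synthetic reflectivity curve
#'
#' Runs the slab-stack forward model ([slab_reflectivity()]) and applies
#' multiplicative log-normal noise, emulating counting statistics on a
#' signal spanning many decades. With `noise_rel = 0` the output equals
#' the forward model exactly.
#'
#' @param model A [slab_model()].
#' @param qz Positive ascending wave-vector transfer grid, Å⁻¹.
#' @param noise_rel Relative (log-normal sdlog) noise level.
#' @param seed Integer seed.
#' @return A tibble of class `ml_reflectivity` with columns `qz`, `R`,
#'   `RF` (Fresnel) and `RRF` (normalised).
#' @examples
#' m <- slab_model(thickness = c(17.3, 9), rho_e = c(0.30, 0.45), sigma = 3)
#' head(gen_reflectivity(m, noise_rel = 0.02))
#' @export
gen_reflectivity <- function(model, qz = seq(0.015, 0.7, length.out = 400),
                             noise_rel = 0, seed = 1L) {
  if (any(qz <= 0) || any(diff(qz) <= 0)) abort("qz grid must be positive ascending")
  curve <- slab_reflectivity(model, qz)
  if (noise_rel > 0) {
    fac <- with_seed(seed, exp(rnorm(length(qz), 0, noise_rel)))
    curve$R <- pmin(curve$R * fac, 1)
    curve$RRF <- curve$R / curve$RF
  }
  curve
}

#' Generate a synthetic in-plane diffraction pattern
#'
#' A single Bragg peak of chosen line shape on a linear background, with
#' optional additive Gaussian counting noise. The noiseless maximum sits
#' at `q0` and the noiseless full width at half maximum equals `fwhm`
#' within grid resolution.
#'
#' @param q0 Peak centre, Å⁻¹ (positive).
#' @param fwhm Full width at half maximum, Å⁻¹ (positive).
#' @param amplitude Peak height above background, counts.
#' @param background Length-2 numeric `c(intercept, slope)` of the linear
#'   background in counts (slope per Å⁻¹).
#' @param shape `"lorentzian"` (2D-powder default) or `"gaussian"`.
#' @param qxy Grid, Å⁻¹; defaults to `q0` ± 8 fwhm (at least ±0.05).
#' @param noise_sd Additive Gaussian noise, counts.
#' @param seed Integer seed.
#' @return A tibble of class `ml_gixd` with columns `qxy`, `intensity`.
#' @examples
#' pat <- gen_gixd_peak(1.5036, 0.0318, amplitude = 500)
#' pat$qxy[which.max(pat$intensity)]
#' @export
gen_gixd_peak <- function(q0, fwhm, amplitude = 100, background = c(10, 0),
                          shape = c("lorentzian", "gaussian"),
                          qxy = NULL, noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  if (q0 <= 0) abort("q0 must be positive")
  if (fwhm <= 0) abort("fwhm must be positive")
  if (is.null(qxy)) {
    half <- max(8 * fwhm, 0.05)
    qxy <- seq(q0 - half, q0 + half, length.out = 601)
  }
  if (fwhm >= diff(range(qxy))) abort("fwhm is wider than the q grid span")
  peak <- peak_shape(qxy, q0, fwhm, shape)
  intensity <- background[1] + background[2] * qxy + amplitude * peak
  if (noise_sd > 0) {
    intensity <- pmax(intensity + with_seed(seed, rnorm(length(qxy), 0, noise_sd)), 0)
  }
  new_ml_curve(tibble(qxy = qxy, intensity = intensity), class = "ml_gixd")
}

# Unit-height line shapes parameterised by fwhm.
peak_shape <- function(q, q0, fwhm, shape, eta = 0.5) {
  switch(shape,
    lorentzian = 1 / (1 + (2 * (q - q0) / fwhm)^2),
    gaussian = exp(-4 * log(2) * ((q - q0) / fwhm)^2),
    pseudo_voigt = eta / (1 + (2 * (q - q0) / fwhm)^2) +
      (1 - eta) * exp(-4 * log(2) * ((q - q0) / fwhm)^2)
  )
}

# Light tibble subclass carrying instrument metadata in attributes.
new_ml_curve <- function(df, class, ...) {
  meta <- list(...)
  out <- as_tibble(df)
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  class(out) <- c(class, class(out))
  out
}

#' Metadata attached to a curve object
#'
#' @param x A curve tibble produced by one of the generators or readers.
#' @param field Metadata field name, e.g. `"temperature"`.
#' @param default Value returned when the field is absent.
#' @return The attribute value or `default`.
#' @export
curve_meta <- function(x, field, default = NULL) {
  attr(x, field, exact = TRUE) %||% default
}
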