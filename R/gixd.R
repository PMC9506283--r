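#' Convert grazing-incidence scattering angles to wave vectors
#'
#' Exact evaluation of the grazing-incidence relations
#' \deqn{q_{xy} = \frac{4\pi}{\lambda}\sin(2\theta_h/2), \qquad
#'       q_z = \frac{2\pi}{\lambda}\sin(\alpha_f)}
#' where \eqn{2\theta_h} is the horizontal scattering angle and
#' \eqn{\alpha_f} the out-of-plane exit angle.
#'
#' @param two_theta_h Horizontal scattering angle \eqn{2\theta_h}, deg.
#' @param alpha_f Out-of-plane exit angle \eqn{\alpha_f}, deg.
#' @param wavelength X-ray wavelength, Å.
#' @return A tibble with columns `qxy`, `qz` (Å⁻¹).
#' @examples
#' angles_to_q(21.38, 0, wavelength = 1.55)
#' @export
angles_to_q <- function(two_theta_h, alpha_f = 0, wavelength = 1.55) {
  if (wavelength <= 0) abort("wavelength must be positive")
  tibble(
    qxy = 4 * pi / wavelength * sin(two_theta_h * pi / 360),
    qz = 2 * pi / wavelength * sin(alpha_f * pi / 180)
  )
}

#' Fit a Bragg peak in an in-plane diffraction pattern
#'
#' Least-squares fit of a single peak (Lorentzian by 2D-powder
#' convention; Gaussian or pseudo-Voigt selectable) plus a linear
#' background to an intensity profile \eqn{I(q_{xy})}. The lattice
#' spacing \eqn{d = 2\pi/q_0} and the Scherrer coherence length
#' \eqn{L_c = 0.9 \cdot 2\pi/\mathrm{fwhm}} are filled from the fitted
#' peak with propagated 1-sigma uncertainties. Instrument-resolution
#' broadening is not deconvolved.
#'
#' A peak is deemed significant only if its height exceeds three times
#' the background noise (residual SD in the window flanks); otherwise
#' an error is raised.
#'
#' @param data Data frame with columns `qxy` and `intensity`.
#' @param shape Peak line shape.
#' @param q_window Optional length-2 numeric restricting the fit range,
#'   Å⁻¹.
#' @return An object of class `bragg_peak` with fields `q0`, `fwhm`,
#'   `amplitude`, `background`, `d_spacing`, `Lc`, their uncertainties,
#'   and fit diagnostics. Has [tidy()] and [glance()] methods.
#' @examples
#' pat <- gen_gixd_peak(1.5036, 0.0318, amplitude = 400, noise_sd = 2)
#' pk <- fit_peak(pat)
#' pk$d_spacing
#' @export
fit_peak <- function(data, shape = c("lorentzian", "gaussian", "pseudo_voigt"),
                     q_window = NULL) {
  shape <- match.arg(shape)
  if (!all(c("qxy", "intensity") %in% names(data)))
    abort("pattern data needs `qxy` and `intensity` columns")
  df <- as_tibble(data)[, c("qxy", "intensity")]
  if (!is.null(q_window)) {
    df <- df[df$qxy >= q_window[1] & df$qxy <= q_window[2], , drop = FALSE]
  }
  if (nrow(df) < 10L) abort("too few points in the fit window")
  q <- df$qxy
  y <- df$intensity

  # flank-based background and noise estimate
  n <- length(q)
  flank <- c(seq_len(ceiling(0.15 * n)), seq(floor(0.85 * n), n))
  bg_fit <- lm(y[flank] ~ q[flank])
  bg <- coef(bg_fit)[1] + coef(bg_fit)[2] * q
  noise <- sd(stats::residuals(bg_fit))
  # two-part significance gate: the raw peak height must clear 3x the
  # background noise, and the lightly smoothed curve must rise well
  # clear of its own (noise-suppressed) flank fluctuations, so the
  # extreme order statistic of pure noise does not masquerade as a peak
  sm_w <- max(5L, 2L * (n %/% 100L) + 1L)
  ys <- as.numeric(stats::filter(y - bg, rep(1 / sm_w, sm_w), sides = 2))
  height_sm <- max(ys, na.rm = TRUE)
  height0 <- max(y - bg)
  if (height0 <= 3 * noise || height_sm <= 4 * noise / sqrt(sm_w) ||
    height0 <= 0) {
    abort("no significant peak (amplitude below 3x background noise)")
  }

  q0_0 <- q[which.max(y - bg)]
  above <- which(y - bg > height0 / 2)
  fwhm0 <- max(diff(range(q[above])), 4 * median(diff(q)))
  p0 <- c(q0 = q0_0, fwhm = fwhm0, amp = height0, b0 = unname(coef(bg_fit)[1]),
          b1 = unname(coef(bg_fit)[2]))
  lower <- c(min(q), median(diff(q)), 0, -Inf, -Inf)
  upper <- c(max(q), diff(range(q)), Inf, Inf, Inf)
  res <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper,
    fn = function(p) {
      y - (p[4] + p[5] * q + p[3] * peak_shape(q, p[1], p[2], shape))
    },
    control = minpack.lm::nls.lm.control(maxiter = 300)
  )
  if (res$info %in% c(0, 9)) abort("peak fit did not converge")
  p <- res$par
  rss <- sum(res$fvec^2)
  dof <- max(n - 5L, 1L)
  se <- tryCatch(
    sqrt(pmax(diag(solve(res$hessian)), 0) * 2 * rss / dof),
    error = function(e) rep(NA_real_, 5)
  )

  q0 <- unname(p[1]); fwhm <- unname(p[2])
  out <- list(
    q0 = q0, fwhm = fwhm, amplitude = unname(p[3]),
    background = unname(p[4:5]),
    d_spacing = 2 * pi / q0,
    Lc = coherence_length(fwhm),
    se = c(
      q0 = unname(se[1]), fwhm = unname(se[2]), amplitude = unname(se[3]),
      d_spacing = 2 * pi / q0^2 * unname(se[1]),
      Lc = 0.9 * 2 * pi / fwhm^2 * unname(se[2])
    ),
    shape = shape,
    residual_sd = sqrt(rss / dof),
    n_points = n
  )
  class(out) <- "bragg_peak"
  out
}

#' Scherrer coherence length
#'
#' Average crystalline domain extent along the diffraction vector from
#' the peak width: \eqn{L_c = 0.9 \cdot 2\pi/\mathrm{fwhm}}.
#'
#' @param fwhm Full width at half maximum of the Bragg peak, Å⁻¹, or a
#'   `bragg_peak` object.
#' @return Coherence length, Å.
#' @examples
#' coherence_length(0.0318)
#' @export
coherence_length <- function(fwhm) {
  if (inherits(fwhm, "bragg_peak")) fwhm <- fwhm$fwhm
  if (any(fwhm <= 0)) abort("fwhm must be positive")
  0.9 * 2 * pi / fwhm
}

#' @export
print.bragg_peak <- function(x, ...) {
  cat(sprintf(
    "Bragg peak (%s): q0 = %.5f A^-1, fwhm = %.5f A^-1\n  d = %.4f A, Lc = %.1f A\n",
    x$shape, x$q0, x$fwhm, x$d_spacing, x$Lc
  ))
  invisible(x)
}

#' @rdname fit_peak
#' @param x A `bragg_peak`.
#' @param ... Unused.
#' @method tidy bragg_peak
#' @export
tidy.bragg_peak <- function(x, ...) {
  tibble(
    term = c("q0", "fwhm", "amplitude", "d_spacing", "Lc"),
    estimate = c(x$q0, x$fwhm, x$amplitude, x$d_spacing, x$Lc),
    std.error = unname(x$se[c("q0", "fwhm", "amplitude", "d_spacing", "Lc")])
  )
}

#' @rdname fit_peak
#' @method glance bragg_peak
#' @export
glance.bragg_peak <- function(x, ...) {
  tibble(
    shape = x$shape, residual_sd = x$residual_sd, n_points = x$n_points
  )
}

#' Classify acyl-chain packing from in-plane diffraction
#'
#' A single in-plane Bragg peak whose intensity maximum sits at the
#' horizon (\eqn{q_z \approx 0}) indicates hexagonally packed, untilted
#' chains; two or more resolved peaks, or an off-horizon Bragg-rod
#' maximum, indicate tilted packing; no significant peak (a diffuse
#' halo) indicates disordered chains.
#'
#' @param peaks A `bragg_peak`, a list of them, or `NULL`/empty list.
#' @param qz_maxima Numeric vector of Bragg-rod maximum positions
#'   (Å⁻¹), one per peak; defaults to the horizon (0).
#' @param qz_tol Horizon tolerance, Å⁻¹.
#' @return One of `"hexagonal_untilted"`, `"tilted"`, `"disordered"`.
#' @examples
#' classify_packing(list())
#' @export
classify_packing <- function(peaks, qz_maxima = NULL, qz_tol = 0.1) {
  if (inherits(peaks, "bragg_peak")) peaks <- list(peaks)
  if (is.null(peaks) || length(peaks) == 0L) return("disordered")
  if (length(peaks) >= 2L) return("tilted")
  qz_max <- if (is.null(qz_maxima) || length(qz_maxima) == 0L) 0 else qz_maxima[1]
  if (abs(qz_max) > qz_tol) "tilted" else "hexagonal_untilted"
}
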