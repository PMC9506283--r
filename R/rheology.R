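#' Fit a multi-exponential model to a stress-relaxation transient
#'
#' Models the pressure relaxation after a fast small compression as
#' \deqn{\Delta\pi(t) = \Delta\pi_\infty + \sum_{i=1}^{m} A_i e^{-t/\tau_i}}
#' and selects the number of modes `m` in `0..max_modes` by the
#' small-sample-corrected Akaike criterion. Each candidate mode count is
#' fitted by bounded Levenberg-Marquardt least squares from several
#' starts with initial relaxation times log-spaced over the record, so
#' the fit does not depend on a lucky starting point.
#'
#' @param data Data frame with columns `time` (s, ascending from 0) and
#'   `delta_pi` (mN/m), e.g. from [gen_relaxation()] or [read_curve()].
#' @param max_modes Largest mode count to consider (1-3).
#' @param rel_area_change Relative area perturbation \eqn{|\Delta A/A_0|};
#'   taken from the data's metadata when absent.
#' @return An object of class `relaxation_fit`: `delta_pi_inf`, `modes`
#'   (tibble of `amplitude`, `tau`, sorted by `tau`), `n_modes`,
#'   `sigma` (residual SD), `rel_area_change`, `fitted`. Has [tidy()]
#'   and [glance()] methods.
#' @examples
#' tr <- gen_relaxation(1, 0.5, 100, time = seq(0, 600, 1))
#' fit <- fit_relaxation(tr)
#' tidy(fit)
#' @export
fit_relaxation <- function(data, max_modes = 3L, rel_area_change = NULL) {
  if (!all(c("time", "delta_pi") %in% names(data)))
    abort("transient data needs `time` and `delta_pi` columns")
  t <- data$time
  y <- data$delta_pi
  if (length(t) < 10L) abort("need at least 10 samples")
  if (t[1] != 0 || any(diff(t) <= 0)) abort("time grid must ascend from 0")
  if (any(!is.finite(y))) abort("delta_pi must be finite")
  if (!max_modes %in% 1:3) abort("`max_modes` must be 1, 2 or 3")
  u <- rel_area_change %||% curve_meta(data, "rel_area_change")

  n <- length(t)
  rss_floor <- n * (.Machine$double.eps * max(abs(y), 1))^2
  aicc <- function(rss, k) {
    p <- k + 1 # + residual variance
    n * log(max(rss, rss_floor) / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
  }

  # m = 0: flat transient
  best <- list(
    n_modes = 0L, delta_pi_inf = mean(y), modes = tibble(amplitude = numeric(0), tau = numeric(0)),
    rss = sum((y - mean(y))^2), aicc = aicc(sum((y - mean(y))^2), 1L)
  )

  span <- max(t)
  for (m in seq_len(max_modes)) {
    cand <- best_m_mode_fit(t, y, m, span)
    if (is.null(cand)) next
    a <- aicc(cand$rss, 2L * m + 1L)
    if (a < best$aicc - 1e-9) {
      best <- c(cand, list(aicc = a))
    }
  }

  fitted <- multi_exp(t, best$delta_pi_inf, best$modes$amplitude, best$modes$tau)
  dof <- max(n - (2L * best$n_modes + 1L), 1L)
  out <- list(
    delta_pi_inf = best$delta_pi_inf,
    modes = best$modes,
    n_modes = best$n_modes,
    sigma = sqrt(best$rss / dof),
    rel_area_change = u,
    target_pressure = curve_meta(data, "target_pressure"),
    fitted = fitted,
    data = tibble(time = t, delta_pi = y)
  )
  class(out) <- "relaxation_fit"
  out
}

# Multi-start bounded LM fit with m exponential modes; NULL if nothing
# converges.
best_m_mode_fit <- function(t, y, m, span) {
  starts <- mode_starts(m, span)
  best <- NULL
  for (tau0 in starts) {
    par0 <- c(min(y), rep((max(y) - min(y)) / max(m, 1), m), tau0)
    lower <- c(0, rep(0, m), rep(span * 1e-5, m))
    upper <- c(Inf, rep(Inf, m), rep(span * 1e3, m))
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = pmax(par0, lower + 1e-12),
        lower = lower, upper = upper,
        fn = function(p) y - multi_exp(t, p[1], p[2:(m + 1)], p[(m + 2):(2 * m + 1)]),
        control = minpack.lm::nls.lm.control(maxiter = 400)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = res$par, rss = rss)
  }
  if (is.null(best)) return(NULL)
  p <- best$par
  ord <- order(p[(m + 2):(2 * m + 1)])
  tibble_modes <- tibble(
    amplitude = p[2:(m + 1)][ord],
    tau = p[(m + 2):(2 * m + 1)][ord]
  )
  list(n_modes = m, delta_pi_inf = p[1], modes = tibble_modes, rss = best$rss)
}

# Initial relaxation-time sets, log-spaced over the record.
mode_starts <- function(m, span) {
  grid <- span * 10^seq(-2.5, 0, length.out = 6)
  if (m == 1L) {
    as.list(grid)
  } else if (m == 2L) {
    list(span * c(0.01, 0.5), span * c(0.003, 0.1), span * c(0.05, 1), span * c(0.001, 0.3))
  } else {
    list(span * c(0.003, 0.05, 0.8), span * c(0.001, 0.03, 0.5), span * c(0.01, 0.1, 1))
  }
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(
    "Relaxation fit: %d mode(s), delta_pi_inf = %.4g mN/m, residual SD %.3g\n",
    x$n_modes, x$delta_pi_inf, x$sigma
  ))
  if (x$n_modes > 0) print(x$modes)
  invisible(x)
}

#' @rdname fit_relaxation
#' @param x A `relaxation_fit`.
#' @param ... Unused.
#' @method tidy relaxation_fit
#' @export
tidy.relaxation_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "delta_pi_inf", estimate = x$delta_pi_inf),
    if (x$n_modes > 0) {
      tibble(
        term = c(
          paste0("A", seq_len(x$n_modes)),
          paste0("tau", seq_len(x$n_modes))
        ),
        estimate = c(x$modes$amplitude, x$modes$tau)
      )
    }
  )
}

#' @rdname fit_relaxation
#' @method glance relaxation_fit
#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble(
    n_modes = x$n_modes, sigma = x$sigma,
    delta_pi_0 = x$delta_pi_inf + sum(x$modes$amplitude),
    rel_area_change = x$rel_area_change %||% NA_real_
  )
}

#' Viscoelastic spectrum from a relaxation fit
#'
#' Converts a fitted multi-exponential relaxation into the complex
#' frequency-dependent dilatational modulus
#' \eqn{E^*(\nu) = G'(\nu) + iG''(\nu)} by Fourier-transforming the
#' fitted model analytically under the step-strain assumption
#' (\eqn{d\ln A/dt = -u\,\delta(t)} with \eqn{u} the relative area
#' perturbation):
#' \deqn{G'(\omega) = \frac{1}{u}\Big(\Delta\pi_\infty +
#'   \sum_i A_i \frac{\omega^2\tau_i^2}{1+\omega^2\tau_i^2}\Big), \quad
#'  G''(\omega) = \frac{1}{u}\sum_i A_i \frac{\omega\tau_i}{1+\omega^2\tau_i^2}}
#' with \eqn{\omega = 2\pi\nu}. The loss tangent
#' \eqn{\tan\varphi = G''/G'} and the dilatational viscosity
#' \eqn{\eta_D = G''/(2\pi\nu)} are filled from their definitions.
#'
#' @param fit A `relaxation_fit` from [fit_relaxation()], or any list
#'   with fields `delta_pi_inf` and `modes`.
#' @param rel_area_change Relative area perturbation `u`; defaults to
#'   the fit's stored value.
#' @param nu Frequency grid, Hz; default log-spaced 0.1 mHz to 1 Hz.
#' @param strain `"linear"` uses \eqn{u = |\Delta A/A_0|} directly;
#'   `"log"` uses the exact \eqn{|\ln(1 - \Delta A/A_0)|} (differs by
#'   < 2.6% for perturbations up to 5%).
#' @return A tibble of class `ml_spectrum` with columns `frequency`
#'   (Hz), `storage`, `loss` (mN/m), `tan_phi`, `eta_D` (mN·s/m).
#' @examples
#' fit <- fit_relaxation(gen_relaxation(1, 0.5, 100, time = seq(0, 900, 0.5)))
#' sp <- spectrum_from_fit(fit, rel_area_change = 0.05)
#' range(sp$storage) # 20 to 30 mN/m
#' @export
spectrum_from_fit <- function(fit, rel_area_change = NULL,
                              nu = 10^seq(-4, 0, length.out = 241),
                              strain = c("linear", "log")) {
  strain <- match.arg(strain)
  u <- rel_area_change %||% fit$rel_area_change
  if (is.null(u) || u <= 0) abort("a positive `rel_area_change` is required")
  if (strain == "log") u <- abs(log1p(-u))
  if (any(nu <= 0)) abort("frequencies must be positive")

  w <- 2 * pi * nu
  storage <- rep_len(fit$delta_pi_inf, length(nu))
  loss <- numeric(length(nu))
  for (i in seq_len(nrow(fit$modes))) {
    A <- fit$modes$amplitude[i]
    tau <- fit$modes$tau[i]
    wt <- w * tau
    storage <- storage + A * wt^2 / (1 + wt^2)
    loss <- loss + A * wt / (1 + wt^2)
  }
  storage <- storage / u
  loss <- loss / u
  new_ml_curve(
    tibble(
      frequency = nu,
      storage = storage,
      loss = loss,
      tan_phi = ifelse(storage > 0, loss / storage, NA_real_),
      eta_D = loss / w
    ),
    class = "ml_spectrum",
    rel_area_change = u
  )
}

#' Cole-Cole diagnostics of a viscoelastic spectrum
#'
#' Plots of loss against storage modulus trace a semicircle centred on
#' the \eqn{G'} axis for a single standard-linear-solid (Maxwell)
#' relaxation process. This function fits that semicircle (centre on
#' the \eqn{G'} axis) by algebraic least squares and reports the RMS
#' radial deviation normalised by the radius: values near zero indicate
#' a single relaxation process, large values a multi-step relaxation.
#'
#' @param spectrum An `ml_spectrum` tibble from [spectrum_from_fit()].
#' @return An object of class `cole_cole`: list with `curve` (tibble of
#'   `storage`, `loss`), `center`, `radius` and `deviation` (RMS radial
#'   deviation / radius).
#' @examples
#' fit <- fit_relaxation(gen_relaxation(1, 0.5, 100, time = seq(0, 900, 0.5)))
#' cc <- cole_cole(spectrum_from_fit(fit, rel_area_change = 0.05))
#' cc$deviation # ~0 for a single mode
#' @export
cole_cole <- function(spectrum) {
  if (nrow(spectrum) < 5L) abort("need at least 5 spectrum points")
  span <- diff(range(log10(spectrum$frequency)))
  if (span < 2) abort("spectrum must span at least 2 decades of frequency")
  gp <- spectrum$storage
  gpp <- spectrum$loss
  if (diff(range(gpp)) <= 1e-12 * max(abs(gp), 1))
    abort("degenerate spectrum: loss modulus is constant (purely elastic)")

  # Circle with centre (c, 0): G'^2 + G''^2 = 2 c G' + (r^2 - c^2),
  # linear in (c, d); solved by least squares.
  rhs <- gp^2 + gpp^2
  X <- cbind(2 * gp, 1)
  beta <- qr.coef(qr(X), rhs)
  centre <- beta[1]
  radius <- sqrt(max(beta[2] + centre^2, 0))
  if (radius <= 0) abort("degenerate Cole-Cole curve (zero radius)")
  dist <- sqrt((gp - centre)^2 + gpp^2)
  out <- list(
    curve = tibble(storage = gp, loss = gpp),
    center = unname(centre),
    radius = unname(radius),
    deviation = sqrt(mean((dist - radius)^2)) / radius
  )
  class(out) <- "cole_cole"
  out
}

#' @export
print.cole_cole <- function(x, ...) {
  cat(sprintf(
    "Cole-Cole semicircle: centre %.4g mN/m, radius %.4g mN/m, RMS deviation %.3g\n",
    x$center, x$radius, x$deviation
  ))
  invisible(x)
}

#' High-frequency plateau of the storage modulus
#'
#' Mean storage modulus over a frequency band (default above 100 mHz,
#' where condensed-monolayer spectra level off). The band is flagged as
#' not a true plateau when the relative spread of \eqn{G'} within it
#' exceeds 5%.
#'
#' @param spectrum An `ml_spectrum` tibble.
#' @param band Length-2 numeric frequency band, Hz.
#' @return One-row tibble: `plateau` (mN/m), `rel_spread`, `is_plateau`,
#'   `band_min`, `band_max`.
#' @examples
#' fit <- fit_relaxation(gen_relaxation(1, 0.5, 100, time = seq(0, 900, 0.5)))
#' plateau_modulus(spectrum_from_fit(fit, rel_area_change = 0.05))
#' @export
plateau_modulus <- function(spectrum, band = c(0.1, Inf)) {
  sel <- spectrum$frequency >= band[1] & spectrum$frequency <= band[2]
  if (!any(sel)) abort("no spectrum points inside the band")
  gp <- spectrum$storage[sel]
  spread <- if (mean(gp) > 0) (max(gp) - min(gp)) / mean(gp) else 0
  tibble(
    plateau = mean(gp),
    rel_spread = spread,
    is_plateau = spread <= 0.05,
    band_min = band[1],
    band_max = min(band[2], max(spectrum$frequency))
  )
}
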