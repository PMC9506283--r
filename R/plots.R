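#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_path geom_col
#'   geom_tile labs scale_x_log10 scale_y_log10 scale_fill_viridis_c
#'   facet_wrap theme_minimal
NULL

#' Plot methods for leafletlab result objects
#'
#' `autoplot()` methods returning ggplot objects: isotherms
#' (\eqn{\pi} vs A), compression-modulus curves (\eqn{\varepsilon} vs
#' \eqn{\pi}), relaxation transients, viscoelastic spectra (G', G''
#' against frequency on log axes), Cole-Cole plots, normalised
#' reflectivity, electron density profiles, diffraction patterns,
#' order-parameter profiles and contact heatmaps.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name leafletlab-autoplot
NULL

#' @rdname leafletlab-autoplot
#' @method autoplot ml_isotherm
#' @export
autoplot.ml_isotherm <- function(object, ...) {
  ggplot(object, aes(.data$area, .data$pressure)) +
    geom_line() +
    labs(
      x = expression(A ~ (ring(A)^2 / molecule)),
      y = expression(pi ~ (mN / m))
    ) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot ml_modulus
#' @export
autoplot.ml_modulus <- function(object, ...) {
  ggplot(object, aes(.data$pressure, .data$epsilon)) +
    geom_line() +
    labs(
      x = expression(pi ~ (mN / m)),
      y = expression(epsilon ~ (mN / m))
    ) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot ml_transient
#' @export
autoplot.ml_transient <- function(object, ...) {
  ggplot(object, aes(.data$time, .data$delta_pi)) +
    geom_point(size = 0.6, alpha = 0.6) +
    labs(x = "t (s)", y = expression(Delta * pi ~ (mN / m))) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot ml_spectrum
#' @export
autoplot.ml_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("frequency", "storage", "loss")],
    c("storage", "loss"),
    names_to = "modulus", values_to = "value"
  )
  ggplot(long, aes(.data$frequency, .data$value, colour = .data$modulus)) +
    geom_line() +
    scale_x_log10() +
    labs(x = expression(nu ~ (Hz)), y = "modulus (mN/m)", colour = NULL) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot cole_cole
#' @export
autoplot.cole_cole <- function(object, ...) {
  ggplot(object$curve, aes(.data$storage, .data$loss)) +
    geom_path() +
    labs(
      x = expression(G * minute ~ (mN / m)),
      y = expression(G * second ~ (mN / m))
    ) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot ml_reflectivity
#' @export
autoplot.ml_reflectivity <- function(object, ...) {
  ggplot(object, aes(.data$qz, .data$RRF)) +
    geom_line() +
    scale_y_log10() +
    labs(
      x = expression(q[z] ~ (ring(A)^-1)),
      y = expression(R / R[F])
    ) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot ml_edp
#' @export
autoplot.ml_edp <- function(object, ...) {
  ggplot(object, aes(.data$z, .data$rho)) +
    geom_line() +
    labs(
      x = expression(z ~ (ring(A))),
      y = expression(rho[e] ~ (e^-{} / ring(A)^3))
    ) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot ml_gixd
#' @export
autoplot.ml_gixd <- function(object, ...) {
  ggplot(object, aes(.data$qxy, .data$intensity)) +
    geom_line() +
    labs(
      x = expression(q[xy] ~ (ring(A)^-1)),
      y = "intensity (counts)"
    ) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot ml_scd
#' @export
autoplot.ml_scd <- function(object, ...) {
  ggplot(object, aes(.data$carbon_index, .data$s_cd, colour = .data$tail)) +
    geom_line() +
    geom_point() +
    facet_wrap(~species) +
    labs(x = "carbon position", y = expression(S[CD]), colour = NULL) +
    theme_minimal()
}

#' @rdname leafletlab-autoplot
#' @method autoplot contact_heatmap
#' @export
autoplot.contact_heatmap <- function(object, ...) {
  df <- as_tibble(as.table(object$matrix), .name_repair = "minimal")
  names(df) <- c("sterol_atom", "partner_atom", "frequency")
  ggplot(df, aes(.data$partner_atom, .data$sterol_atom, fill = .data$frequency)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(
      x = object$partner_species, y = object$sterol_species,
      fill = "contact\nfrequency"
    ) +
    theme_minimal()
}
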