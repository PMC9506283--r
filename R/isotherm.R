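#' Static compression modulus of an isotherm
#'
#' Computes the static (quasi-equilibrium) compression modulus
#' \deqn{\varepsilon(\pi) = -A \, d\pi/dA}
#' along the compression branch of a surface pressure-area isotherm.
#' The derivative is estimated by local polynomial (Savitzky-Golay
#' style) regression of pressure on area in a sliding window, which
#' tolerates noisy experimental records and non-uniform area grids.
#'
#' Only the compression branch is analysed: the longest strictly
#' decreasing-area run of the record. Points within half a window of the
#' branch ends are dropped (the derivative is not estimable there).
#'
#' @param data Data frame with columns `area` (Å²/molecule) and
#'   `pressure` (mN/m), e.g. from [gen_isotherm()] or [read_curve()].
#' @param window Odd window length in points (>= `polyorder + 2`).
#' @param polyorder Local polynomial degree.
#' @return A tibble with columns `area`, `pressure`, `epsilon` (mN/m)
#'   and attribute `smoothing` describing the estimator.
#' @examples
#' iso <- gen_isotherm("ideal_gas", area = seq(100, 30, length.out = 200))
#' cm <- compression_modulus(iso)
#' # ideal gas: epsilon(pi) == pi
#' max(abs(cm$epsilon - cm$pressure) / cm$pressure)
#' @export
compression_modulus <- function(data, window = 11L, polyorder = 2L) {
  check_isotherm(data)
  if (window %% 2L != 1L) abort("`window` must be odd")
  if (window < polyorder + 2L) abort("`window` must be at least polyorder + 2")
  branch <- compression_branch(data)
  n <- nrow(branch)
  if (n < window) abort("too few points on the compression branch for this window")
  if (var(branch$area) == 0) abort("zero-variance area")

  half <- (window - 1L) %/% 2L
  idx <- (half + 1L):(n - half)
  dpi_da <- vapply(idx, function(i) {
    sel <- (i - half):(i + half)
    local_poly_deriv(branch$area[sel], branch$pressure[sel],
      at = branch$area[i], degree = polyorder
    )
  }, numeric(1))

  out <- tibble(
    area = branch$area[idx],
    pressure = branch$pressure[idx],
    epsilon = -branch$area[idx] * dpi_da
  )
  attr(out, "smoothing") <- sprintf(
    "local polynomial, window %d pts, degree %d", window, polyorder
  )
  class(out) <- c("ml_modulus", class(out))
  out
}

# Derivative of a degree-`degree` polynomial least-squares fit, at `at`.
local_poly_deriv <- function(x, y, at, degree) {
  xc <- x - at
  X <- outer(xc, 0:degree, `^`)
  beta <- qr.coef(qr(X), y)
  beta[2]
}

check_isotherm <- function(data) {
  if (!all(c("area", "pressure") %in% names(data)))
    abort("isotherm data needs `area` and `pressure` columns")
  if (nrow(data) < 3L) abort("isotherm needs at least 3 points")
  if (any(data$pressure < -0.5))
    abort("pressures below -0.5 mN/m: not a valid isotherm record")
  invisible(data)
}

# Longest strictly decreasing-area run, returned largest area first. A
# record stored in the opposite sampling direction (area ascending) is
# the same physical curve and is flipped before branch extraction.
compression_branch <- function(data) {
  a <- data$area
  if (!any(diff(a) < 0) && any(diff(a) > 0)) {
    data <- data[rev(seq_len(nrow(data))), , drop = FALSE]
    a <- data$area
  }
  dec <- diff(a) < 0
  if (!any(dec)) abort("no compression (decreasing-area) branch found")
  r <- rle(dec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)[which.max(r$lengths[r$values])]
  data[starts[k]:(ends[k] + 1L), , drop = FALSE]
}

#' Lift-off area of an isotherm
#'
#' The lift-off is the molecular area at which the surface pressure
#' first rises above zero on compression. It is located as the largest
#' area at which the (optionally smoothed) pressure exceeds `threshold`,
#' refined by linear interpolation between the bracketing points.
#'
#' @inheritParams compression_modulus
#' @param threshold Pressure criterion, mN/m. Default 0.5 mN/m, small
#'   enough to sit just above sensor noise.
#' @param window Odd running-mean window for pre-smoothing; 1 disables.
#' @return Lift-off area, Å²/molecule.
#' @examples
#' iso <- gen_isotherm("piecewise_linear",
#'   coefficients = list(liftoff_area = 42, slopes = 6)
#' )
#' liftoff_area(iso)
#' @export
liftoff_area <- function(data, threshold = 0.5, window = 1L) {
  check_isotherm(data)
  branch <- compression_branch(data)
  p <- branch$pressure
  if (window > 1L) {
    if (window %% 2L != 1L) abort("`window` must be odd")
    p <- stats::filter(p, rep(1 / window, window), sides = 2)
    keep <- !is.na(p)
    branch <- branch[keep, , drop = FALSE]
    p <- as.numeric(p[keep])
  }
  if (max(p) <= threshold) abort("pressure never exceeds the lift-off threshold")
  if (min(p) > threshold)
    abort("isotherm does not extend below the lift-off threshold")
  i <- which(p > threshold)[1] # branch ordered largest area first
  if (i == 1L) return(branch$area[1])
  # interpolate the crossing between points i-1 (below) and i (above)
  a0 <- branch$area[i - 1L]; a1 <- branch$area[i]
  p0 <- p[i - 1L]; p1 <- p[i]
  a0 + (threshold - p0) * (a1 - a0) / (p1 - p0)
}

#' Piecewise-linear gradient segmentation of an isotherm
#'
#' Fits a continuous piecewise-linear model of \eqn{\pi(A)} with
#' `n_segments` segments to the post-lift-off compression branch, by
#' least squares over both the segment slopes and the free breakpoints.
#' Slopes are reported as magnitudes \eqn{|d\pi/dA|} (mN m⁻¹ Å⁻²) and
#' breakpoints as the fitted pressure at the slope change, the form in
#' which gradient changes of condensed monolayers are usually quoted.
#'
#' @inheritParams compression_modulus
#' @param n_segments Number of linear segments, 1-3.
#' @param threshold Lift-off pressure criterion passed to the branch
#'   selection, mN/m.
#' @param pressure_range Optional length-2 numeric restricting the fit
#'   to a pressure interval (mN/m).
#' @return An object of class `segment_fit`: list with `segments` (a
#'   tibble of `pressure_min`, `pressure_max`, `slope`),
#'   `break_pressures`, `break_areas`, `residual_sd`, `n_segments` and
#'   the fitted values. Has [tidy()] and [glance()] methods.
#' @examples
#' iso <- gen_isotherm("piecewise_linear",
#'   coefficients = list(liftoff_area = 60, slopes = c(3, 9), break_pressures = 22),
#'   area = seq(70, 20, length.out = 300)
#' )
#' tidy(segment_gradients(iso, 2))
#' @export
segment_gradients <- function(data, n_segments = 1L, threshold = 0.5,
                              pressure_range = NULL) {
  check_isotherm(data)
  if (!n_segments %in% 1:3) abort("`n_segments` must be 1, 2 or 3")
  branch <- compression_branch(data)
  sel <- branch$pressure > threshold
  if (!is.null(pressure_range)) {
    sel <- sel & branch$pressure >= pressure_range[1] &
      branch$pressure <= pressure_range[2]
  }
  branch <- branch[sel, , drop = FALSE]
  n_par <- 2L * n_segments # slopes + intercept + breakpoints
  if (nrow(branch) < n_par + 2L) abort("fewer points than model parameters")

  # Work in x = -A so that compression slopes are positive.
  x <- -branch$area
  y <- branch$pressure
  o <- order(x)
  x <- x[o]; y <- y[o]

  if (n_segments == 1L) {
    fit <- lm(y ~ x)
    slopes <- unname(coef(fit)[2])
    breaks_x <- numeric(0)
    fitted_y <- unname(predict(fit))
  } else {
    hinge_rss <- function(kx) {
      X <- cbind(1, x, outer(x, kx, function(x, k) pmax(x - k, 0)))
      f <- qr.fitted(qr(X), y)
      sum((y - f)^2)
    }
    # coarse grid over interior quantiles, then local refinement
    cand <- quantile(x, probs = seq(0.1, 0.9, by = 0.05), names = FALSE)
    if (n_segments == 2L) {
      rss <- vapply(cand, hinge_rss, numeric(1))
      k0 <- cand[which.min(rss)]
      opt <- optimise(hinge_rss, range(x))
      kx <- if (opt$objective < hinge_rss(k0)) opt$minimum else k0
    } else {
      grid <- expand.grid(k1 = cand, k2 = cand)
      grid <- grid[grid$k2 > grid$k1 + diff(range(x)) / 20, ]
      rss <- apply(grid, 1, hinge_rss)
      k0 <- as.numeric(grid[which.min(rss), ])
      opt <- optim(k0, function(k) {
        if (k[2] <= k[1]) return(Inf)
        hinge_rss(sort(k))
      })
      kx <- sort(opt$par)
    }
    kx <- sort(kx)
    X <- cbind(1, x, outer(x, kx, function(x, k) pmax(x - k, 0)))
    beta <- qr.coef(qr(X), y)
    slopes <- cumsum(beta[-1])
    breaks_x <- kx
    fitted_y <- as.numeric(X %*% beta)
  }

  seg_bounds_p <- c(min(y), approx_at(x, fitted_y, breaks_x), max(fitted_y))
  out <- list(
    segments = tibble(
      pressure_min = utils::head(seg_bounds_p, -1),
      pressure_max = utils::tail(seg_bounds_p, -1),
      slope = abs(unname(slopes))
    ),
    break_pressures = approx_at(x, fitted_y, breaks_x),
    break_areas = -breaks_x,
    residual_sd = sd(y - fitted_y),
    n_segments = n_segments,
    data = tibble(area = -x, pressure = y, fitted = fitted_y)
  )
  class(out) <- "segment_fit"
  out
}

approx_at <- function(x, y, at) {
  if (length(at) == 0) return(numeric(0))
  approx(x, y, xout = at, rule = 2)$y
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf(
    "Piecewise-linear isotherm fit: %d segment(s), residual SD %.3g mN/m\n",
    x$n_segments, x$residual_sd
  ))
  print(x$segments)
  if (length(x$break_pressures)) {
    cat("Breakpoints at pi =", paste(sprintf("%.2f", x$break_pressures),
      collapse = ", "
    ), "mN/m\n")
  }
  invisible(x)
}

#' @rdname segment_gradients
#' @param x A `segment_fit` object.
#' @param ... Unused.
#' @method tidy segment_fit
#' @export
tidy.segment_fit <- function(x, ...) {
  dplyr::mutate(x$segments, segment = dplyr::row_number(), .before = 1)
}

#' @rdname segment_gradients
#' @method glance segment_fit
#' @export
glance.segment_fit <- function(x, ...) {
  tibble(
    n_segments = x$n_segments,
    residual_sd = x$residual_sd,
    n_points = nrow(x$data)
  )
}
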