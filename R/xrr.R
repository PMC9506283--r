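#' Slab-stack model of a monolayer-covered interface
#'
#' Describes the interface as a stack of homogeneous slabs between air
#' (top) and a semi-infinite subphase, each slab with a thickness,
#' electron density and an upper-interface Gaussian roughness. The
#' conventional monolayer decomposition is two slabs: the acyl-chain
#' (tail) slab against air and the headgroup slab against water, so the
#' total film thickness is \eqn{d_{tot} = d_T + d_H}.
#'
#' @param thickness Slab thicknesses, Å, ordered air to subphase.
#' @param rho_e Slab electron densities, e⁻/Å³.
#' @param sigma Upper-interface roughnesses, Å (recycled to the number
#'   of slabs).
#' @param subphase_rho_e Subphase electron density, e⁻/Å³ (pure water
#'   0.334 by default).
#' @param subphase_sigma Roughness of the deepest interface, Å; defaults
#'   to the last slab roughness.
#' @param wavelength X-ray wavelength, Å (used in angle conversions).
#' @return An object of class `slab_model`.
#' @examples
#' slab_model(thickness = c(17.3, 9.0), rho_e = c(0.30, 0.45), sigma = 3)
#' @export
slab_model <- function(thickness = numeric(0), rho_e = numeric(0),
                       sigma = 0, subphase_rho_e = 0.334,
                       subphase_sigma = NULL, wavelength = 1.55) {
  if (length(thickness) != length(rho_e))
    abort("`thickness` and `rho_e` must have the same length")
  if (any(thickness <= 0)) abort("slab thicknesses must be positive")
  if (any(rho_e < 0) || subphase_rho_e <= 0)
    abort("electron densities must be non-negative (subphase positive)")
  sigma <- rep_len(sigma, length(thickness))
  if (any(sigma < 0)) abort("roughnesses must be non-negative")
  structure(
    list(
      slabs = tibble(thickness = thickness, rho_e = rho_e, sigma = sigma),
      subphase_rho_e = subphase_rho_e,
      subphase_sigma = subphase_sigma %||%
        (if (length(sigma)) sigma[length(sigma)] else 0),
      wavelength = wavelength
    ),
    class = "slab_model"
  )
}

#' @export
print.slab_model <- function(x, ...) {
  cat(sprintf(
    "Slab model: %d slab(s) on subphase rho_e = %.3f e-/A^3 (lambda = %.3g A)\n",
    nrow(x$slabs), x$subphase_rho_e, x$wavelength
  ))
  if (nrow(x$slabs)) print(x$slabs)
  invisible(x)
}

#' Fresnel reflectivity of a bare interface
#'
#' Reflectivity of an ideally sharp, flat air/subphase interface:
#' \deqn{R_F = \left| \frac{q_z - \sqrt{q_z^2 - q_c^2}}{q_z +
#'   \sqrt{q_z^2 - q_c^2}} \right|^2}
#' with critical wave vector \eqn{q_c = 4\sqrt{\pi r_e \rho_e}}
#' (\eqn{r_e} the Thomson scattering length). Below \eqn{q_c} the
#' interface is totally reflecting, \eqn{R_F = 1}. For pure water
#' \eqn{q_c = 0.0218} Å⁻¹, the critical angle 0.154° at 8 keV.
#'
#' @param qz Wave-vector transfer, Å⁻¹ (positive).
#' @param subphase_rho_e Subphase electron density, e⁻/Å³.
#' @return Numeric vector of reflectivities.
#' @examples
#' critical_qz(0.334)
#' fresnel(c(0.01, 0.05, 0.2))
#' @export
fresnel <- function(qz, subphase_rho_e = 0.334) {
  if (any(qz <= 0)) abort("qz must be positive")
  if (subphase_rho_e <= 0) abort("subphase electron density must be positive")
  qc2 <- 16 * pi * .r_e * subphase_rho_e
  qp <- sqrt(as.complex(qz^2 - qc2))
  Mod((qz - qp) / (qz + qp))^2
}

#' @rdname fresnel
#' @export
critical_qz <- function(subphase_rho_e = 0.334) {
  4 * sqrt(pi * .r_e * subphase_rho_e)
}

#' Specular reflectivity of a slab stack
#'
#' Dynamical (Parratt-recursion) reflectivity of the slab model, with
#' Gaussian interfacial roughness included through Nevot-Croce damping
#' of each interface's Fresnel coefficient. The dynamical treatment is
#' exact near the critical edge where the kinematic (Born) approximation
#' fails. Absorption is neglected (thin organic film at 8 keV).
#'
#' @param model A [slab_model()].
#' @param qz Wave-vector transfer grid, Å⁻¹ (positive).
#' @return A tibble of class `ml_reflectivity` with columns `qz`, `R`,
#'   `RF` (bare-subphase Fresnel) and `RRF = R/RF`.
#' @examples
#' m <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 3)
#' head(slab_reflectivity(m, seq(0.02, 0.6, 0.01)))
#' @export
slab_reflectivity <- function(model, qz = seq(0.015, 0.7, length.out = 400)) {
  stopifnot(inherits(model, "slab_model"))
  if (any(qz <= 0)) abort("qz must be positive")
  R <- parratt_reflectivity(
    qz,
    rho = c(0, model$slabs$rho_e, model$subphase_rho_e),
    d = c(Inf, model$slabs$thickness, Inf),
    sigma = c(model$slabs$sigma, model$subphase_sigma)
  )
  RF <- fresnel(qz, model$subphase_rho_e)
  new_ml_curve(
    tibble(qz = qz, R = R, RF = RF, RRF = R / RF),
    class = "ml_reflectivity",
    subphase_rho_e = model$subphase_rho_e,
    wavelength = model$wavelength
  )
}

# Parratt recursion over layers j = 0 (air) .. N+1 (subphase).
# rho: length N+2; d: length N+2 (outer entries ignored); sigma: length
# N+1, sigma[j] = roughness of the interface between layers j-1 and j.
parratt_reflectivity <- function(qz, rho, d, sigma) {
  n_lay <- length(rho)
  # vertical wave-vector transfer inside each layer (complex below its
  # critical edge; principal sqrt gives the decaying branch Im >= 0)
  qj <- lapply(seq_len(n_lay), function(j) {
    sqrt(as.complex(qz^2 - 16 * pi * .r_e * rho[j]))
  })
  X <- complex(length(qz)) # no reflection from below the subphase
  for (j in seq(n_lay - 1L, 1L)) {
    qa <- qj[[j]]
    qb <- qj[[j + 1L]]
    r <- (qa - qb) / (qa + qb) * exp(-qa * qb * sigma[j]^2 / 2)
    phase <- if (j + 1L < n_lay) exp(1i * qb * d[j + 1L]) else 0 + 0i
    Xb <- X * phase
    X <- (r + Xb) / (1 + r * Xb)
  }
  pmin(Mod(X)^2, 1)
}

#' First minimum of a normalised reflectivity curve
#'
#' Locates the first local minimum of \eqn{R/R_F} above the critical
#' edge and refines it by a parabola through the three bracketing
#' points. For a two-slab monolayer the position of this minimum is
#' tied to the film thickness, approximately
#' \eqn{q_z^{(1)} \simeq (3\pi/2)/(d_T + d_H/2)}.
#'
#' @param curve An `ml_reflectivity` tibble (needs the `RRF` column).
#' @param qz_min Ignore structure below this qz (stay clear of the
#'   total-reflection plateau), Å⁻¹.
#' @return The qz position of the first minimum, Å⁻¹.
#' @examples
#' m <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 3)
#' first_minimum(slab_reflectivity(m, seq(0.03, 0.45, 5e-4)))
#' @export
first_minimum <- function(curve, qz_min = NULL) {
  if (!all(c("qz", "RRF") %in% names(curve)))
    abort("curve must carry `qz` and the normalised branch `RRF`")
  qz_min <- qz_min %||%
    (1.5 * critical_qz(curve_meta(curve, "subphase_rho_e", .water_rho_e)))
  sel <- which(curve$qz > qz_min)
  if (length(sel) < 3L) abort("too few points above the critical edge")
  y <- curve$RRF[sel]
  q <- curve$qz[sel]
  interior <- which(diff(sign(diff(y))) > 0) + 1L
  if (!length(interior)) abort("no local minimum found in the normalised reflectivity")
  i <- interior[1]
  # parabolic refinement through (i-1, i, i+1)
  qs <- q[(i - 1):(i + 1)]
  ys <- y[(i - 1):(i + 1)]
  denom <- (qs[1] - qs[2]) * (qs[1] - qs[3]) * (qs[2] - qs[3])
  a <- (qs[3] * (ys[2] - ys[1]) + qs[2] * (ys[1] - ys[3]) + qs[1] * (ys[3] - ys[2])) / denom
  b <- (qs[3]^2 * (ys[1] - ys[2]) + qs[2]^2 * (ys[3] - ys[1]) + qs[1]^2 * (ys[2] - ys[3])) / denom
  if (a <= 0) return(q[i])
  -b / (2 * a)
}

#' Electron density profile of a slab model
#'
#' Laterally averaged electron density \eqn{\rho(z)} of the stack, with
#' each interface smeared by its Gaussian roughness (error-function
#' steps). The convention is z increasing from air into the subphase,
#' with the air/tail interface at z = 0.
#'
#' @param model A [slab_model()].
#' @param z Depth grid, Å.
#' @return A tibble of class `ml_edp` with columns `z`, `rho`.
#' @examples
#' m <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 3)
#' dp <- density_profile(m, seq(-20, 50, 0.25))
#' @export
density_profile <- function(model, z = seq(-20, sum(model$slabs$thickness) + 30, 0.2)) {
  stopifnot(inherits(model, "slab_model"))
  rho_layers <- c(0, model$slabs$rho_e, model$subphase_rho_e)
  z_if <- c(0, cumsum(model$slabs$thickness))
  sig <- c(model$slabs$sigma, model$subphase_sigma)
  rho <- numeric(length(z))
  for (i in seq_along(z_if)) {
    step <- if (sig[i] > 0) {
      stats::pnorm((z - z_if[i]) / sig[i])
    } else {
      as.numeric(z >= z_if[i])
    }
    rho <- rho + (rho_layers[i + 1] - rho_layers[i]) * step
  }
  new_ml_curve(tibble(z = z, rho = rho), class = "ml_edp")
}

#' Fit a slab model to a reflectivity curve
#'
#' Weighted least squares of the slab forward model against measured
#' reflectivity, performed on log R with uniform relative weights
#' (reflectivity spans many decades, so fitting in log space weights
#' all fringes evenly). Free parameters are slab thicknesses, electron
#' densities and roughnesses; any can be frozen via `fixed`.
#'
#' @param data Data frame with columns `qz` and `R`.
#' @param init A [slab_model()] giving starting values and stack
#'   geometry.
#' @param fixed Character vector of parameter names to hold at their
#'   initial values, from `d1, d2, ..., rho1, ..., sigma1, ...,
#'   sigma_sub`.
#' @param lower,upper Named numeric vectors overriding default bounds
#'   (d in \[1, 100\] Å, rho in \[0.01, 1\] e⁻/Å³, sigma in \[0, 12\] Å).
#' @return An object of class `slab_fit`: the fitted `model`, a
#'   parameter table with 1-sigma uncertainties, `d_tot`, and fit
#'   diagnostics. Has [tidy()] and [glance()] methods.
#' @examples
#' truth <- slab_model(c(17.3, 9.0), c(0.30, 0.45), sigma = 3)
#' curve <- gen_reflectivity(truth, noise_rel = 0.02, seed = 7)
#' fit <- fit_reflectivity(curve, init = slab_model(c(15, 10), c(0.32, 0.42), 3))
#' glance(fit)
#' @export
fit_reflectivity <- function(data, init, fixed = character(0),
                             lower = NULL, upper = NULL) {
  stopifnot(inherits(init, "slab_model"))
  if (!all(c("qz", "R") %in% names(data)))
    abort("reflectivity data needs `qz` and `R` columns")
  n_slab <- nrow(init$slabs)
  par_names <- c(
    paste0("d", seq_len(n_slab)),
    paste0("rho", seq_len(n_slab)),
    paste0("sigma", seq_len(n_slab)),
    "sigma_sub"
  )
  p0 <- setNames(
    c(init$slabs$thickness, init$slabs$rho_e, init$slabs$sigma, init$subphase_sigma),
    par_names
  )
  lo <- setNames(
    c(rep(1, n_slab), rep(0.01, n_slab), rep(0, n_slab), 0),
    par_names
  )
  hi <- setNames(
    c(rep(100, n_slab), rep(1, n_slab), rep(12, n_slab), 12),
    par_names
  )
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  bad_fixed <- setdiff(fixed, par_names)
  if (length(bad_fixed)) abort(paste("unknown fixed parameter:", bad_fixed[1]))
  free <- setdiff(par_names, fixed)
  n_free <- length(free)
  if (nrow(data) < 5L * n_free)
    abort("need at least 5 data points per free parameter")

  make_model <- function(p) {
    slab_model(
      thickness = unname(p[paste0("d", seq_len(n_slab))]),
      rho_e = unname(p[paste0("rho", seq_len(n_slab))]),
      sigma = unname(p[paste0("sigma", seq_len(n_slab))]),
      subphase_rho_e = init$subphase_rho_e,
      subphase_sigma = unname(p[["sigma_sub"]]),
      wavelength = init$wavelength
    )
  }
  keep <- data$R > 0
  qz <- data$qz[keep]
  logR <- log(data$R[keep])
  resid_fn <- function(pf) {
    p <- p0
    p[free] <- pf
    Rm <- slab_reflectivity(make_model(p), qz)$R
    log(pmax(Rm, 1e-300)) - logR
  }

  res <- minpack.lm::nls.lm(
    par = p0[free], lower = lo[free], upper = hi[free], fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 300)
  )
  if (res$info %in% c(0, 9)) abort("slab fit did not converge")
  p_hat <- p0
  p_hat[free] <- res$par
  rss <- sum(res$fvec^2)
  dof <- max(length(logR) - n_free, 1L)
  sigma2 <- rss / dof
  se <- setNames(rep(NA_real_, length(par_names)), par_names)
  se[free] <- tryCatch(
    sqrt(pmax(diag(solve(res$hessian)), 0) * 2 * sigma2),
    error = function(e) rep(NA_real_, n_free)
  )
  at_bound <- p_hat <= lo + 1e-8 * pmax(abs(lo), 1) |
    p_hat >= hi - 1e-8 * pmax(abs(hi), 1)
  at_bound[fixed] <- FALSE
  if (any(at_bound[free]))
    warn(paste(
      "parameters at bounds:",
      paste(names(which(at_bound[free])), collapse = ", ")
    ))

  model <- make_model(p_hat)
  out <- list(
    model = model,
    parameters = tibble(
      term = par_names,
      estimate = unname(p_hat),
      std.error = unname(se),
      fixed = par_names %in% fixed,
      at_bound = unname(at_bound)
    ),
    d_tot = sum(model$slabs$thickness),
    residual_sd_logR = sqrt(sigma2),
    n_points = length(logR),
    converged = TRUE
  )
  class(out) <- "slab_fit"
  out
}

#' @export
print.slab_fit <- function(x, ...) {
  cat(sprintf(
    "Slab fit: d_tot = %.2f A, residual SD (log R) = %.3g\n",
    x$d_tot, x$residual_sd_logR
  ))
  print(x$parameters)
  invisible(x)
}

#' @rdname fit_reflectivity
#' @param x A `slab_fit`.
#' @param ... Unused.
#' @method tidy slab_fit
#' @export
tidy.slab_fit <- function(x, ...) x$parameters

#' @rdname fit_reflectivity
#' @method glance slab_fit
#' @export
glance.slab_fit <- function(x, ...) {
  tibble(
    d_tot = x$d_tot,
    residual_sd_logR = x$residual_sd_logR,
    n_points = x$n_points,
    converged = x$converged
  )
}
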