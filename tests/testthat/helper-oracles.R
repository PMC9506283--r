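# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# Viscoelastic spectrum by direct numerical Fourier transform of the
# densely sampled transient derivative (trapezoid + analytic tail),
# E*(w) = F[dDpi/dt] / F[dlnA/dt] with F[dlnA/dt] = -u for a step.
oracle_spectrum <- function(delta_pi_inf, amplitudes, taus, u, nu,
                            t_span_factor = 60, n_t = 2e5) {
  tmax <- t_span_factor * max(taus)
  t <- seq(0, tmax, length.out = n_t)
  dydt <- rep(0, n_t)
  for (i in seq_along(amplitudes)) {
    dydt <- dydt - amplitudes[i] / taus[i] * exp(-t / taus[i])
  }
  dp0 <- delta_pi_inf + sum(amplitudes)
  vapply(nu, function(f) {
    w <- 2 * pi * f
    integrand <- dydt * exp(-1i * w * t)
    I <- sum((integrand[-1] + integrand[-n_t]) / 2) * (t[2] - t[1])
    tail_int <- 0 + 0i
    for (i in seq_along(amplitudes)) {
      a <- 1 / taus[i] + 1i * w
      tail_int <- tail_int - amplitudes[i] / taus[i] * exp(-a * tmax) / a
    }
    E <- (dp0 + I + tail_int) / u
    c(Re(E), Im(E))
  }, numeric(2))
}

# Transfer-matrix reflectivity of the same slab stack: 2x2
# characteristic matrices instead of the Parratt recursion.
oracle_transfer_matrix <- function(model, qz) {
  r_e <- 2.818e-5
  rho <- c(0, model$slabs$rho_e, model$subphase_rho_e)
  d <- c(0, model$slabs$thickness, 0)
  sig <- c(model$slabs$sigma, model$subphase_sigma)
  n_lay <- length(rho)
  vapply(qz, function(q) {
    k <- sqrt(as.complex(q^2 - 16 * pi * r_e * rho)) / 2
    M <- diag(2) + 0i
    for (j in seq_len(n_lay - 1L)) {
      rj <- (k[j] - k[j + 1]) / (k[j] + k[j + 1]) *
        exp(-2 * k[j] * k[j + 1] * sig[j]^2)
      tj <- 1 + rj
      I <- matrix(c(1, rj, rj, 1), 2, 2) / tj
      if (j < n_lay - 1L) {
        P <- diag(c(exp(-1i * k[j + 1] * d[j + 1]), exp(1i * k[j + 1] * d[j + 1])))
        M <- M %*% I %*% P
      } else {
        M <- M %*% I
      }
    }
    min(Mod(M[2, 1] / M[1, 1])^2, 1)
  }, numeric(1))
}

# Brute-force O(N^2) atomic contact tally between two species.
oracle_contacts <- function(traj, box, sp_a, sp_b, cutoff,
                            periodic = c("x", "y")) {
  dims <- match(periodic, c("x", "y", "z"))
  events <- list()
  for (fr in unique(traj$frame)) {
    f <- traj[traj$frame == fr, ]
    a <- f[f$species == sp_a, ]
    b <- f[f$species == sp_b, ]
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        if (a$mol_id[i] == b$mol_id[j]) next
        del <- c(a$x[i] - b$x[j], a$y[i] - b$y[j], a$z[i] - b$z[j])
        for (dd in dims) del[dd] <- del[dd] - box[dd] * round(del[dd] / box[dd])
        if (sum(del^2) <= cutoff^2) {
          events[[length(events) + 1L]] <- c(a$atom[i], b$atom[j])
        }
      }
    }
  }
  events
}

# Brute-force triple enumeration of geometric hydrogen bonds.
oracle_hbonds <- function(traj, box, donors, acceptors, d_max, angle_min,
                          periodic = c("x", "y")) {
  dims <- match(periodic, c("x", "y", "z"))
  mi <- function(del) {
    for (dd in dims) del[dd] <- del[dd] - box[dd] * round(del[dd] / box[dd])
    del
  }
  out <- list()
  for (fr in unique(traj$frame)) {
    f <- traj[traj$frame == fr, ]
    for (di in seq_len(nrow(donors))) {
      drows <- f[f$species == donors$species[di] & f$atom == donors$donor[di], ]
      for (r in seq_len(nrow(drows))) {
        hrow <- f[f$mol_id == drows$mol_id[r] & f$atom == donors$hydrogen[di], ]
        for (ai in seq_len(nrow(acceptors))) {
          arows <- f[f$species == acceptors$species[ai] &
            f$atom == acceptors$acceptor[ai] &
            f$mol_id != drows$mol_id[r], ]
          for (s in seq_len(nrow(arows))) {
            da <- mi(c(
              drows$x[r] - arows$x[s], drows$y[r] - arows$y[s],
              drows$z[r] - arows$z[s]
            ))
            if (sum(da^2) > d_max^2) next
            hd <- mi(c(
              drows$x[r] - hrow$x, drows$y[r] - hrow$y, drows$z[r] - hrow$z
            ))
            ha <- mi(c(
              arows$x[s] - hrow$x, arows$y[s] - hrow$y, arows$z[s] - hrow$z
            ))
            ang <- acos(sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))) * 180 / pi
            if (ang > angle_min) {
              out[[length(out) + 1L]] <- tibble::tibble(
                frame = fr,
                donor_species = donors$species[di], donor_atom = donors$donor[di],
                acceptor_species = acceptors$species[ai],
                acceptor_atom = acceptors$acceptor[ai]
              )
            }
          }
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  dplyr::count(
    dplyr::bind_rows(out),
    frame, donor_species, donor_atom, acceptor_species, acceptor_atom,
    name = "n"
  )
}

# Voronoi cell areas by dense-grid nearest-seed quadrature under
# periodic minimum image (independent of the clipping construction).
oracle_voronoi_grid <- function(xy, box_xy, n_grid = 1200L) {
  gx <- (seq_len(n_grid) - 0.5) / n_grid * box_xy[1]
  gy <- (seq_len(n_grid) - 0.5) / n_grid * box_xy[2]
  grid <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  best_d <- rep(Inf, nrow(grid))
  best_i <- rep(0L, nrow(grid))
  for (i in seq_len(nrow(xy))) {
    dx <- abs(grid[, 1] - xy[i, 1])
    dx <- pmin(dx, box_xy[1] - dx)
    dy <- abs(grid[, 2] - xy[i, 2])
    dy <- pmin(dy, box_xy[2] - dy)
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d
    best_d[upd] <- d2[upd]
    best_i[upd] <- i
  }
  cell_px <- tabulate(best_i, nbins = nrow(xy))
  cell_px / nrow(grid) * box_xy[1] * box_xy[2]
}

# Minimal hand-built trajectory for constructed-geometry tests.
make_traj <- function(df, box) {
  out <- tibble::as_tibble(df)
  defaults <- list(
    frame = 1L, leaflet = NA_character_, element = "C", species = "X",
    atom = "A"
  )
  for (nm in names(defaults)) {
    if (is.null(out[[nm]])) out[[nm]] <- defaults[[nm]]
  }
  if (!"mol_id" %in% names(out)) out$mol_id <- seq_len(nrow(out))
  attr(out, "box") <- box
  class(out) <- c("ml_traj", class(out))
  out
}
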