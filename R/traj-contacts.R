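# Pairwise squared distances between two coordinate sets with the
# minimum-image convention applied on the selected box dimensions.
pair_dist2 <- function(a, b, box, periodic = c("x", "y")) {
  dims <- match(periodic, c("x", "y", "z"))
  d2 <- matrix(0, nrow(a), nrow(b))
  for (d in 1:3) {
    del <- outer(a[, d], b[, d], `-`)
    if (d %in% dims) del <- del - box[d] * round(del / box[d])
    d2 <- d2 + del^2
  }
  d2
}

coords_matrix <- function(df) cbind(df$x, df$y, df$z)

#' Sterol-lipid atomic contact heatmap
#'
#' Counts, over all frames and molecule pairs, how often each
#' (sterol atom, partner atom) pair comes within `cutoff` of one
#' another under the minimum-image convention, and normalises the
#' count matrix to sum to 1. The matrix reveals which parts of the
#' sterol touch which parts of each neighbouring lipid species.
#' Normalisation is by total atom-pair contact events.
#'
#' @inheritParams area_per_lipid
#' @param sterol_species,partner_species Species names.
#' @param cutoff Contact distance, Å.
#' @param periodic Box dimensions treated as periodic.
#' @return An object of class `contact_heatmap`: `matrix` (normalised
#'   frequencies, sterol atoms in rows), `counts`, `n_events`, and the
#'   species/cutoff metadata.
#' @examples
#' traj <- gen_toy_monolayer(16, c(DPPX = 0.75, CHOL = 0.25), apl = 40)
#' ch <- contact_heatmap(traj, "CHOL", "DPPX")
#' sum(ch$matrix) # 1
#' @export
contact_heatmap <- function(traj, sterol_species, partner_species,
                            cutoff = 4.0, periodic = c("x", "y"),
                            topology = NULL) {
  box <- traj_box(traj)
  a_all <- traj[traj$species == sterol_species, , drop = FALSE]
  b_all <- traj[traj$species == partner_species, , drop = FALSE]
  if (!nrow(a_all) || !nrow(b_all)) abort("both species must be present")
  a_names <- sort(unique(a_all$atom))
  b_names <- sort(unique(b_all$atom))
  counts <- matrix(0L, length(a_names), length(b_names),
    dimnames = list(a_names, b_names)
  )
  for (fr in unique(traj$frame)) {
    a <- a_all[a_all$frame == fr, , drop = FALSE]
    b <- b_all[b_all$frame == fr, , drop = FALSE]
    d2 <- pair_dist2(coords_matrix(a), coords_matrix(b), box, periodic)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      same_mol <- a$mol_id[hit[, 1]] == b$mol_id[hit[, 2]]
      hit <- hit[!same_mol, , drop = FALSE]
    }
    if (nrow(hit)) {
      tab <- table(
        factor(a$atom[hit[, 1]], levels = a_names),
        factor(b$atom[hit[, 2]], levels = b_names)
      )
      counts <- counts + unclass(tab)
    }
  }
  n_events <- sum(counts)
  if (n_events == 0L) abort("no contacts within the cutoff in any frame")
  out <- list(
    matrix = counts / n_events, counts = counts, n_events = n_events,
    sterol_species = sterol_species, partner_species = partner_species,
    cutoff = cutoff
  )
  class(out) <- "contact_heatmap"
  out
}

#' @export
print.contact_heatmap <- function(x, ...) {
  cat(sprintf(
    "Contact heatmap %s-%s: %d events within %.1f A over %dx%d atom pairs\n",
    x$sterol_species, x$partner_species, x$n_events, x$cutoff,
    nrow(x$matrix), ncol(x$matrix)
  ))
  invisible(x)
}

#' Geometric hydrogen-bond detection
#'
#' A hydrogen bond is counted when a donor and an acceptor heavy atom
#' of different molecules are within `d_max` of one another and the
#' donor-hydrogen-acceptor angle exceeds `angle_min`. Donor/hydrogen
#' pairs and acceptor atoms come from the topology; distances use the
#' minimum-image convention.
#'
#' @inheritParams contact_heatmap
#' @param d_max Donor-acceptor distance criterion, Å.
#' @param angle_min Donor-hydrogen-acceptor angle criterion, degrees.
#' @return A tibble with one row per (frame, donor species:atom,
#'   acceptor species:atom) combination and the bond count `n`.
#' @examples
#' traj <- gen_toy_monolayer(16, c(CHOL = 1))
#' hb <- hydrogen_bonds(traj)
#' @export
hydrogen_bonds <- function(traj, topology = NULL, d_max = 3.5,
                           angle_min = 150, periodic = c("x", "y")) {
  topology <- topology %||% curve_meta(traj, "topology") %||%
    abort("no topology supplied or attached to the trajectory")
  box <- traj_box(traj)

  donor_defs <- dplyr::bind_rows(lapply(names(topology), function(sp) {
    ds <- topology[[sp]]$donors
    if (!length(ds)) return(NULL)
    tibble(
      species = sp,
      donor = vapply(ds, `[[`, character(1), "donor"),
      hydrogen = vapply(ds, `[[`, character(1), "hydrogen")
    )
  }))
  acc_defs <- dplyr::bind_rows(lapply(names(topology), function(sp) {
    as <- topology[[sp]]$acceptors
    if (!length(as)) return(NULL)
    tibble(species = sp, acceptor = as)
  }))
  if (!nrow(donor_defs) || !nrow(acc_defs))
    abort("topology defines no donors or no acceptors")

  results <- list()
  for (fr in unique(traj$frame)) {
    f <- traj[traj$frame == fr, , drop = FALSE]
    dd <- dplyr::inner_join(f, donor_defs,
      by = c("species", atom = "donor"), relationship = "many-to-many"
    )
    hh <- f[, c("frame", "mol_id", "atom", "x", "y", "z")]
    names(hh)[3:6] <- c("hydrogen", "hx", "hy", "hz")
    dd <- dplyr::inner_join(dd, hh, by = c("frame", "mol_id", "hydrogen"))
    if (anyNA(dd$hx)) abort("donor without its hydrogen in the trajectory")
    aa <- dplyr::inner_join(f, acc_defs, by = c("species", atom = "acceptor"))
    if (!nrow(dd) || !nrow(aa)) next

    d2 <- pair_dist2(coords_matrix(dd), coords_matrix(aa), box, periodic)
    hit <- which(d2 <= d_max^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    same <- dd$mol_id[hit[, 1]] == aa$mol_id[hit[, 2]]
    hit <- hit[!same, , drop = FALSE]
    if (!nrow(hit)) next

    hd <- min_image_vec(
      cbind(dd$x, dd$y, dd$z)[hit[, 1], , drop = FALSE],
      cbind(dd$hx, dd$hy, dd$hz)[hit[, 1], , drop = FALSE], box, periodic
    )
    ha <- min_image_vec(
      coords_matrix(aa)[hit[, 2], , drop = FALSE],
      cbind(dd$hx, dd$hy, dd$hz)[hit[, 1], , drop = FALSE], box, periodic
    )
    cosang <- rowSums(hd * ha) /
      (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- acos(pmax(pmin(cosang, 1), -1)) * 180 / pi
    ok <- ang > angle_min
    if (!any(ok)) next
    results[[length(results) + 1L]] <- tibble(
      frame = fr,
      donor_species = dd$species[hit[ok, 1]],
      donor_atom = dd$atom[hit[ok, 1]],
      acceptor_species = aa$species[hit[ok, 2]],
      acceptor_atom = aa$atom[hit[ok, 2]]
    )
  }
  if (!length(results)) {
    return(tibble(
      frame = integer(0), donor_species = character(0),
      donor_atom = character(0), acceptor_species = character(0),
      acceptor_atom = character(0), n = integer(0)
    ))
  }
  dplyr::count(
    dplyr::bind_rows(results),
    .data$frame, .data$donor_species, .data$donor_atom,
    .data$acceptor_species, .data$acceptor_atom,
    name = "n"
  )
}

# target - origin under minimum image, rowwise for paired matrices
min_image_vec <- function(target, origin, box, periodic = c("x", "y")) {
  dims <- match(periodic, c("x", "y", "z"))
  del <- target - origin
  for (d in dims) del[, d] <- del[, d] - box[d] * round(del[, d] / box[d])
  del
}

#' Radial distribution function
#'
#' Shell-histogram estimator of
#' \eqn{g_{\alpha\beta}(r) = \rho_{r,\alpha\beta}/\rho_\beta}: the
#' density of \eqn{\beta} atoms at distance r from \eqn{\alpha} atoms,
#' normalised by the mean \eqn{\beta} density, with minimum-image
#' distances. For a homogeneous system g(r) tends to 1 at large r.
#'
#' @inheritParams contact_heatmap
#' @param sel_alpha,sel_beta Selections: lists with optional `species`
#'   and `atom` character vectors.
#' @param r_max Largest distance, Å; at most half the smallest
#'   periodic box edge.
#' @param bins Number of distance bins.
#' @return A tibble of class `ml_rdf`: `r` (bin centres), `g`.
#' @examples
#' traj <- gen_toy_monolayer(16, c(CHOL = 1))
#' rdf(traj, list(species = "W", atom = "OW"), list(species = "W", atom = "OW"),
#'   r_max = 8
#' )
#' @export
rdf <- function(traj, sel_alpha, sel_beta, r_max, bins = 100L,
                periodic = c("x", "y", "z")) {
  box <- traj_box(traj)
  dims <- match(periodic, c("x", "y", "z"))
  if (r_max > min(box[dims]) / 2 + 1e-9)
    abort("r_max exceeds half the smallest periodic box edge")
  pick <- function(f, sel) {
    keep <- rep(TRUE, nrow(f))
    if (!is.null(sel$species)) keep <- keep & f$species %in% sel$species
    if (!is.null(sel$atom)) keep <- keep & f$atom %in% sel$atom
    f[keep, , drop = FALSE]
  }
  breaks <- seq(0, r_max, length.out = bins + 1L)
  counts <- numeric(bins)
  n_a_total <- 0
  n_b_total <- 0
  frames <- unique(traj$frame)
  for (fr in frames) {
    f <- traj[traj$frame == fr, , drop = FALSE]
    a <- pick(f, sel_alpha)
    b <- pick(f, sel_beta)
    if (!nrow(a) || !nrow(b)) abort("empty selection")
    key_a <- paste(a$mol_id, a$atom)
    key_b <- paste(b$mol_id, b$atom)
    # chunk over alpha rows to bound the pair-distance matrix size
    chunk <- max(1L, floor(2e6 / nrow(b)))
    for (i0 in seq(1L, nrow(a), by = chunk)) {
      i1 <- min(i0 + chunk - 1L, nrow(a))
      d2 <- pair_dist2(coords_matrix(a[i0:i1, , drop = FALSE]),
                       coords_matrix(b), box, periodic)
      self <- outer(key_a[i0:i1], key_b, `==`)
      d <- sqrt(d2[!self])
      d <- d[d <= r_max]
      counts <- counts + tabulate(findInterval(d, breaks,
        rightmost.closed = TRUE, all.inside = TRUE
      ), nbins = bins)
    }
    n_a_total <- n_a_total + nrow(a)
    n_b_total <- n_b_total + nrow(b)
  }
  vol <- prod(box)
  rho_b <- (n_b_total / length(frames)) / vol
  shell <- 4 / 3 * pi * (tail(breaks, -1)^3 - head(breaks, -1)^3)
  g <- counts / (length(frames) * (n_a_total / length(frames)) * shell * rho_b)
  new_ml_curve(
    tibble(r = (head(breaks, -1) + tail(breaks, -1)) / 2, g = g),
    class = "ml_rdf"
  )
}

#' Water histogram against the monolayer surface
#'
#' Minimum distance of each water molecule (its oxygen) to the
#' monolayer surface - by default the headgroup heavy atoms of all
#' lipid species - binned and normalised by the bulk water number
#' density, so the histogram tends to 1 in bulk-like regions. This is
#' a measure of total membrane hydration.
#'
#' @inheritParams contact_heatmap
#' @param bin_width Bin width, Å.
#' @param r_max Largest distance, Å.
#' @param surface_sel Optional selection list (as in [rdf()]) defining
#'   the surface atom set; defaults to headgroup heavy atoms of all
#'   lipid species.
#' @param sides Number of monolayer surfaces facing the water (2 for a
#'   water slab between two leaflets, 1 for a single interface).
#' @param bulk_density Bulk water number density, molecules/Å³.
#' @return A tibble of class `ml_hydration_hist`: `distance` (bin
#'   centres), `g` (normalised density).
#' @examples
#' traj <- gen_toy_monolayer(16, c(DPPX = 1), water_thickness = 40)
#' hydration_histogram(traj, r_max = 18)
#' @export
hydration_histogram <- function(traj, topology = NULL, bin_width = 0.5,
                                r_max = 15, surface_sel = NULL, sides = 2,
                                bulk_density = 0.0334,
                                periodic = c("x", "y")) {
  topology <- topology %||% curve_meta(traj, "topology")
  box <- traj_box(traj)
  wat <- traj[traj$species == "W" & traj$atom == "OW", , drop = FALSE]
  if (!nrow(wat)) abort("no water in the trajectory")
  surface <- if (is.null(surface_sel)) {
    if (is.null(topology)) abort("need a topology (or `surface_sel`) to define the surface")
    keep <- rep(FALSE, nrow(traj))
    for (sp in setdiff(names(topology), "W")) {
      heavy <- topology[[sp]]$head_atoms
      keep <- keep | (traj$species == sp & traj$atom %in% heavy &
        traj$element != "H")
    }
    traj[keep, , drop = FALSE]
  } else {
    f <- traj
    keep <- rep(TRUE, nrow(f))
    if (!is.null(surface_sel$species)) keep <- keep & f$species %in% surface_sel$species
    if (!is.null(surface_sel$atom)) keep <- keep & f$atom %in% surface_sel$atom
    f[keep, , drop = FALSE]
  }
  if (!nrow(surface)) abort("empty surface atom set")

  breaks <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(breaks) - 1L)
  frames <- unique(traj$frame)
  for (fr in frames) {
    w <- wat[wat$frame == fr, , drop = FALSE]
    s <- surface[surface$frame == fr, , drop = FALSE]
    d2 <- pair_dist2(coords_matrix(w), coords_matrix(s), box, periodic)
    dmin <- sqrt(apply(d2, 1, min))
    dmin <- dmin[dmin <= r_max]
    counts <- counts + tabulate(findInterval(dmin, breaks,
      rightmost.closed = TRUE, all.inside = TRUE
    ), nbins = length(counts))
  }
  vol_per_bin <- box[1] * box[2] * bin_width * sides
  g <- counts / (length(frames) * vol_per_bin * bulk_density)
  new_ml_curve(
    tibble(distance = (head(breaks, -1) + tail(breaks, -1)) / 2, g = g),
    class = "ml_hydration_hist"
  )
}

#' Per-atom hydration map of a species
#'
#' An atom is hydrated in a frame when a water oxygen lies within
#' `cutoff` of it. Hydration events are counted per heavy atom over
#' all molecules of the species and all frames, then normalised by the
#' molecule's total so the probabilities sum to 1 - a map of where on
#' the molecule the water sits.
#'
#' @inheritParams contact_heatmap
#' @param species Species to map.
#' @return A tibble of class `ml_hydration_map`: `atom`, `events`,
#'   `probability` (summing to 1).
#' @examples
#' traj <- gen_toy_monolayer(16, c(CHOL = 1))
#' hm <- hydration_map(traj, "CHOL")
#' sum(hm$probability)
#' @export
hydration_map <- function(traj, species, cutoff = 4.0,
                          periodic = c("x", "y"), topology = NULL) {
  box <- traj_box(traj)
  mol <- traj[traj$species == species & traj$element != "H", , drop = FALSE]
  wat <- traj[traj$species == "W" & traj$atom == "OW", , drop = FALSE]
  if (!nrow(mol)) abort("species not present")
  if (!nrow(wat)) abort("no water in the trajectory")
  events <- setNames(numeric(length(unique(mol$atom))), sort(unique(mol$atom)))
  for (fr in unique(traj$frame)) {
    m <- mol[mol$frame == fr, , drop = FALSE]
    w <- wat[wat$frame == fr, , drop = FALSE]
    d2 <- pair_dist2(coords_matrix(m), coords_matrix(w), box, periodic)
    hydrated <- apply(d2, 1, function(r) any(r <= cutoff^2))
    tallied <- tapply(hydrated, m$atom, sum)
    events[names(tallied)] <- events[names(tallied)] + tallied
  }
  total <- sum(events)
  if (total == 0) abort("species is never hydrated within the cutoff")
  new_ml_curve(
    tibble(
      atom = names(events), events = as.numeric(events),
      probability = as.numeric(events) / total
    ),
    class = "ml_hydration_map", species = species, cutoff = cutoff
  )
}
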