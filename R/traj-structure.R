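#' Area per lipid by periodic Voronoi tessellation
#'
#' Projects the headgroup reference atoms of every lipid in a leaflet
#' onto the xy plane and computes the area of each point's Voronoi cell
#' under periodic boundary conditions. A lipid's area is the sum of its
#' reference-point cell areas (three points for phospholipids, one for
#' sterols, which captures their very different headgroup sizes).
#'
#' Cells are obtained exactly by half-plane clipping against the eight
#' periodic images, so the per-leaflet areas sum to the box area to
#' machine precision.
#'
#' @param traj An `ml_traj` tibble (see [gen_toy_monolayer()]).
#' @param topology A [toy_topology()]-style list; defaults to the
#'   trajectory's own.
#' @return A tibble with one row per lipid and frame: `frame`,
#'   `leaflet`, `mol_id`, `species`, `apl` (Å²).
#' @examples
#' traj <- gen_toy_monolayer(16, c(CHOL = 1), lattice = "hexagonal")
#' apl <- area_per_lipid(traj)
#' sum(apl$apl) / 2 # equals the box xy area per leaflet
#' @export
area_per_lipid <- function(traj, topology = NULL) {
  topology <- topology %||% curve_meta(traj, "topology") %||%
    abort("no topology supplied or attached to the trajectory")
  box <- traj_box(traj)
  lipids <- traj[!is.na(traj$leaflet), , drop = FALSE]
  ref <- dplyr::bind_rows(lapply(names(topology), function(sp) {
    refs <- topology[[sp]]$ref_atoms
    if (!length(refs)) return(NULL)
    lipids[lipids$species == sp & lipids$atom %in% refs, , drop = FALSE]
  }))

  groups <- dplyr::group_split(dplyr::group_by(ref, .data$frame, .data$leaflet))
  out <- lapply(groups, function(g) {
    xy <- cbind(g$x %% box[1], g$y %% box[2])
    dup <- duplicated(round(xy, 9))
    if (any(dup)) {
      warn("coincident reference points; jittering by 1e-6 A")
      xy[dup, ] <- xy[dup, , drop = FALSE] + 1e-6
    }
    areas <- voronoi_areas_periodic(xy, box[1:2])
    dplyr::summarise(
      dplyr::group_by(
        tibble(
          frame = g$frame, leaflet = g$leaflet, mol_id = g$mol_id,
          species = g$species, cell = areas
        ),
        .data$frame, .data$leaflet, .data$mol_id, .data$species
      ),
      apl = sum(.data$cell), .groups = "drop"
    )
  })
  dplyr::bind_rows(out)
}

# Exact periodic 2-D Voronoi cell areas by iterative half-plane
# clipping. Each cell starts as the half-box rectangle around its seed
# (which always contains the periodic cell) and is cut by the
# perpendicular bisectors of ever more distant neighbours (all nine
# images) until no bisector can reach the polygon.
voronoi_areas_periodic <- function(xy, box_xy) {
  n <- nrow(xy)
  shifts <- as.matrix(expand.grid(dx = c(-1, 0, 1) * box_xy[1],
                                  dy = c(-1, 0, 1) * box_xy[2]))
  imgs <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
    cbind(xy[, 1] + shifts[s, 1], xy[, 2] + shifts[s, 2], seq_len(n), s)
  }))
  central <- which(shifts[, 1] == 0 & shifts[, 2] == 0)

  vapply(seq_len(n), function(i) {
    p <- xy[i, ]
    keep <- !(imgs[, 3] == i & imgs[, 4] == central)
    q <- imgs[keep, 1:2, drop = FALSE]
    d2 <- (q[, 1] - p[1])^2 + (q[, 2] - p[2])^2
    ord <- order(d2)
    poly <- rbind(
      p + c(-box_xy[1] / 2, -box_xy[2] / 2),
      p + c(box_xy[1] / 2, -box_xy[2] / 2),
      p + c(box_xy[1] / 2, box_xy[2] / 2),
      p + c(-box_xy[1] / 2, box_xy[2] / 2)
    )
    for (k in ord) {
      rmax2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
      if (d2[k] / 4 > rmax2) break
      poly <- clip_halfplane(poly, p, q[k, ])
      if (nrow(poly) < 3L) break
    }
    shoelace(poly)
  }, numeric(1))
}

# Clip polygon to the half-plane of points closer to p than to q
# (Sutherland-Hodgman against the perpendicular bisector).
clip_halfplane <- function(poly, p, q) {
  nrm <- q - p
  cval <- sum(nrm * (p + q) / 2)
  s <- as.numeric(poly %*% nrm) - cval # <= 0 inside
  k <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (a in seq_len(k)) {
    b <- if (a == k) 1L else a + 1L
    ina <- s[a] <= 0
    inb <- s[b] <= 0
    if (ina) out <- rbind(out, poly[a, ])
    if (xor(ina, inb)) {
      t <- s[a] / (s[a] - s[b])
      out <- rbind(out, poly[a, ] + t * (poly[b, ] - poly[a, ]))
    }
  }
  out
}

shoelace <- function(poly) {
  if (nrow(poly) < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Deuterium order parameters along the acyl tails
#'
#' Computes \eqn{S_{CD} = -\tfrac12\langle 3\cos^2\beta - 1\rangle}
#' per tail carbon, where \eqn{\beta} is the angle between each C-H
#' bond and the monolayer normal (the z axis), averaged over bonds,
#' lipids and frames. Values range from -0.5 (bonds along z, i.e.
#' chain in the plane) to 1.0; all-trans chains standing along z give
#' exactly 0.5. A mean outside that physical range (possible only for
#' inconsistent geometry, e.g. both methylene hydrogens parallel to z)
#' triggers a warning.
#'
#' @inheritParams area_per_lipid
#' @param species Species to analyse; defaults to all with tails.
#' @param n_blocks Number of blocks for the block-averaged SEM over
#'   frames.
#' @return A tibble of class `ml_scd`: `species`, `tail`,
#'   `carbon_index`, `carbon`, `s_cd`, `sem`.
#' @examples
#' traj <- gen_toy_monolayer(9, c(DPPX = 1), lattice = "square")
#' op <- order_parameter(traj)
#' range(op$s_cd) # exactly 0.5 for vertical all-trans chains
#' @export
order_parameter <- function(traj, topology = NULL, species = NULL,
                            n_blocks = 10L) {
  topology <- topology %||% curve_meta(traj, "topology") %||%
    abort("no topology supplied or attached to the trajectory")
  species <- species %||%
    names(Filter(function(s) length(s$tails) > 0, topology))

  out <- list()
  for (sp in species) {
    sp_top <- topology[[sp]]
    sub <- traj[traj$species == sp, , drop = FALSE]
    for (tail_name in names(sp_top$tails)) {
      tail <- sp_top$tails[[tail_name]]
      for (j in seq_along(tail$carbons)) {
        cn <- tail$carbons[j]
        hs <- tail$hydrogens[[cn]]
        cs <- sub[sub$atom == cn, c("frame", "mol_id", "z")]
        hrows <- sub[sub$atom %in% hs, c("frame", "mol_id", "atom", "x", "y", "z")]
        if (nrow(hrows) == 0L)
          abort(paste0("missing hydrogens for carbon ", cn, " of ", sp))
        crows <- sub[sub$atom == cn, c("frame", "mol_id", "x", "y", "z")]
        m <- dplyr::inner_join(hrows, crows,
          by = c("frame", "mol_id"), suffix = c("", "_c")
        )
        dx <- m$x - m$x_c; dy <- m$y - m$y_c; dz <- m$z - m$z_c
        cos2 <- dz^2 / (dx^2 + dy^2 + dz^2)
        m$s <- -(3 * cos2 - 1) / 2
        per_frame <- dplyr::summarise(
          dplyr::group_by(m, .data$frame),
          s = mean(.data$s), .groups = "drop"
        )
        out[[length(out) + 1L]] <- tibble(
          species = sp, tail = tail_name,
          carbon_index = j + 1L, carbon = cn,
          s_cd = mean(per_frame$s),
          sem = block_sem(per_frame$s, n_blocks)
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) && (any(res$s_cd < -0.5 - 1e-9) || any(res$s_cd > 1 + 1e-9)))
    warn("S_CD outside [-0.5, 1]: geometrically inconsistent C-H orientations")
  class(res) <- c("ml_scd", class(res))
  res
}

block_sem <- function(x, n_blocks) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  nb <- min(n_blocks, n)
  blocks <- split(x, cut(seq_len(n), nb, labels = FALSE))
  means <- vapply(blocks, mean, numeric(1))
  sd(means) / sqrt(length(means))
}

#' Tail, headgroup and total thickness per species
#'
#' Tail thickness is the mean |z| distance from the terminal tail
#' carbon to the carbonyl carbon; headgroup thickness the mean |z|
#' distance from the carbonyl carbon to the phosphorus; total their
#' sum. Averages run over lipids and frames. Species without a
#' phosphorus (sterols) are excluded with a message.
#'
#' @inheritParams area_per_lipid
#' @return A tibble: `species`, `tail`, `head`, `total` (Å).
#' @examples
#' traj <- gen_toy_monolayer(9, c(DPPX = 1), lattice = "square")
#' thicknesses(traj)
#' @export
thicknesses <- function(traj, topology = NULL) {
  topology <- topology %||% curve_meta(traj, "topology") %||%
    abort("no topology supplied or attached to the trajectory")
  out <- list()
  for (sp in setdiff(names(topology), "W")) {
    sp_top <- topology[[sp]]
    if (is.null(sp_top$phosphorus)) {
      message("excluding ", sp, ": no phosphorus atom (sterol)")
      next
    }
    sub <- traj[traj$species == sp, c("frame", "mol_id", "atom", "z")]
    zt <- sub[sub$atom == sp_top$terminal, c("frame", "mol_id", "z")]
    zc <- sub[sub$atom == sp_top$carbonyl, c("frame", "mol_id", "z")]
    zp <- sub[sub$atom == sp_top$phosphorus, c("frame", "mol_id", "z")]
    m <- dplyr::inner_join(zt, zc, by = c("frame", "mol_id"), suffix = c("_t", "_c"))
    m <- dplyr::inner_join(m, zp, by = c("frame", "mol_id"))
    tail_th <- mean(abs(m$z_t - m$z_c))
    head_th <- mean(abs(m$z_c - m$z))
    out[[sp]] <- tibble(
      species = sp, tail = tail_th, head = head_th, total = tail_th + head_th
    )
  }
  dplyr::bind_rows(out)
}

#' Electron density profile along the monolayer normal
#'
#' Histogram of per-atom electron counts over z bins, divided by the
#' bin volume, averaged over frames. With `fold = TRUE` the two
#' leaflets are aligned by reflection about the water midplane and
#' averaged, the usual presentation for paired-monolayer systems.
#'
#' @inheritParams area_per_lipid
#' @param bins Number of z bins.
#' @param fold Reflect-and-average the two halves about the water
#'   midplane?
#' @param electrons Named vector mapping element to electron count;
#'   defaults to H/C/N/O/P.
#' @return A tibble of class `ml_edp_traj`: `z` (bin centre; distance
#'   from the midplane when folded), `rho` (e⁻/Å³).
#' @examples
#' traj <- gen_toy_monolayer(9, c(DPPX = 1), lattice = "square")
#' edp <- electron_density_profile(traj, bins = 50)
#' @export
electron_density_profile <- function(traj, bins = 100L, fold = FALSE,
                                     electrons = NULL) {
  electrons <- electrons %||% c(H = 1, C = 6, N = 7, O = 8, P = 15)
  box <- traj_box(traj)
  if (bins < 1L) abort("need at least one bin")
  w <- electrons[traj$element]
  if (any(is.na(w))) abort("unknown element; extend the `electrons` table")
  n_frames <- length(unique(traj$frame))

  if (fold) {
    water_z <- curve_meta(traj, "water_z")
    mid <- if (!is.null(water_z)) mean(water_z) else mean(traj$z[traj$species == "W"])
    if (!is.finite(mid)) abort("cannot locate the water midplane")
    coord <- abs(traj$z - mid)
    breaks <- seq(0, max(coord) + 1e-9, length.out = bins + 1L)
    vol_factor <- 2
  } else {
    coord <- traj$z
    breaks <- seq(0, box[3], length.out = bins + 1L)
    vol_factor <- 1
  }
  dz <- diff(breaks)[1]
  if (dz <= 0) abort("zero bin width")
  idx <- findInterval(coord, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  sums <- vapply(seq_len(bins), function(b) sum(w[idx == b]), numeric(1))
  rho <- sums / (vol_factor * box[1] * box[2] * dz * n_frames)
  new_ml_curve(
    tibble(z = (head(breaks, -1) + tail(breaks, -1)) / 2, rho = rho),
    class = "ml_edp_traj", folded = fold, bin_width = dz
  )
}

#' Orientation of a molecular axis relative to the normal
#'
#' Angle between an atom-pair vector (by default the species' topology
#' axis, e.g. sterol C3 to C17, or a P-to-N headgroup vector) and the
#' monolayer normal, per molecule and frame. Angles are folded to
#' \[0°, 90°\] (orientation, not direction), so an isotropic
#' distribution has density proportional to sin(angle) and mean
#' 1 rad = 57.3°.
#'
#' @inheritParams area_per_lipid
#' @param species Species to analyse.
#' @param atom_pair Length-2 character vector `c(from, to)`; defaults
#'   to the species' topology `axis`.
#' @param breaks Histogram breaks in degrees.
#' @return An object of class `orientation_dist`: `angles` (tibble of
#'   `frame`, `mol_id`, `angle`), `histogram` (tibble of `mid`,
#'   `density`), `mean_angle` (deg).
#' @examples
#' traj <- gen_toy_monolayer(16, c(CHOL = 1))
#' vector_orientation(traj, species = "CHOL")$mean_angle # 0 when untilted
#' @export
vector_orientation <- function(traj, topology = NULL, species,
                               atom_pair = NULL, breaks = seq(0, 90, 3)) {
  topology <- topology %||% curve_meta(traj, "topology") %||%
    abort("no topology supplied or attached to the trajectory")
  atom_pair <- atom_pair %||% topology[[species]]$axis
  if (is.null(atom_pair) || length(atom_pair) != 2L)
    abort("an `atom_pair` of two atom names is required")
  sub <- traj[traj$species == species, , drop = FALSE]
  a <- sub[sub$atom == atom_pair[1], c("frame", "mol_id", "x", "y", "z")]
  b <- sub[sub$atom == atom_pair[2], c("frame", "mol_id", "x", "y", "z")]
  if (!nrow(a) || !nrow(b)) abort("atom pair not found in the trajectory")
  m <- dplyr::inner_join(a, b, by = c("frame", "mol_id"), suffix = c("_a", "_b"))
  dx <- m$x_b - m$x_a; dy <- m$y_b - m$y_a; dz <- m$z_b - m$z_a
  len <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(len == 0)) abort("zero-length orientation vector")
  angle <- acos(pmin(abs(dz) / len, 1)) * 180 / pi
  h <- graphics::hist(angle, breaks = breaks, plot = FALSE)
  out <- list(
    angles = tibble(frame = m$frame, mol_id = m$mol_id, angle = angle),
    histogram = tibble(mid = h$mids, density = h$density),
    mean_angle = mean(angle),
    species = species, atom_pair = atom_pair
  )
  class(out) <- "orientation_dist"
  out
}

#' @export
print.orientation_dist <- function(x, ...) {
  cat(sprintf(
    "Orientation of %s (%s -> %s): mean angle %.1f deg from the normal (n = %d)\n",
    x$species, x$atom_pair[1], x$atom_pair[2], x$mean_angle, nrow(x$angles)
  ))
  invisible(x)
}
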