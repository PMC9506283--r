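#' Toy lipid topology
#'
#' Atom-role definitions for the simplified molecule archetypes emitted
#' by [gen_toy_monolayer()]: a generic saturated two-tailed
#' phospholipid (headgroup N/P/glycerol-C2 with two phosphate oxygens,
#' two all-carbon tails with explicit methylene hydrogens), a sterol (a
#' hydroxyl-bearing rigid rod along its C3 to C17 axis), and three-site
#' water. Each species entry records the reference atoms used for the
#' Voronoi tessellation (three for phospholipids, one for sterols),
#' ordered tail carbons with their hydrogens, the carbonyl, terminal
#' and phosphorus atoms used for thickness measures, hydrogen-bond
#' donors/acceptors, and the sterol orientation axis.
#'
#' @param species Character vector of species names to define.
#' @param sterol_species Which of `species` are sterols; defaults to
#'   names matching "CHOL"/"STEROL".
#' @param n_chain_carbons Tail length of the phospholipid archetype
#'   (palmitoyl = 16).
#' @return Named list of per-species definitions (class
#'   `lipid_topology`), always including the water species `"W"`.
#' @examples
#' top <- toy_topology(c("DPPX", "CHOL"))
#' top$CHOL$ref_atoms
#' @export
toy_topology <- function(species, sterol_species = grep("CHOL|STEROL", species, value = TRUE),
                         n_chain_carbons = 16L) {
  if (n_chain_carbons < 3L) abort("tails need at least 3 carbons")
  out <- list()
  for (sp in species) {
    out[[sp]] <- if (sp %in% sterol_species) {
      sterol_def()
    } else {
      phospholipid_def(n_chain_carbons)
    }
  }
  out$W <- water_def()
  structure(out, class = "lipid_topology")
}

phospholipid_def <- function(nc) {
  tail_atoms <- function(suffix) {
    carbons <- paste0("C", 2:nc, suffix)
    hydrogens <- lapply(2:nc, function(k) {
      paste0("H", k, suffix, 1:2)
    })
    names(hydrogens) <- carbons
    list(carbons = carbons, hydrogens = hydrogens)
  }
  list(
    type = "phospholipid",
    ref_atoms = c("P", "C2", "N"),
    head_atoms = c("N", "P", "O11", "O12", "C2"),
    tails = list(sn1 = tail_atoms("A"), sn2 = tail_atoms("B")),
    carbonyl = "C1A",
    terminal = paste0("C", nc, "A"),
    phosphorus = "P",
    donors = list(), # PC/PE-like toy head: no donatable hydrogens
    acceptors = c("O11", "O12"),
    axis = c("P", "N")
  )
}

sterol_def <- function() {
  list(
    type = "sterol",
    ref_atoms = "O3",
    head_atoms = c("O3", "HO3"),
    tails = list(),
    carbonyl = NULL, terminal = NULL, phosphorus = NULL,
    donors = list(c(donor = "O3", hydrogen = "HO3")),
    acceptors = "O3",
    axis = c("C3", "C17")
  )
}

water_def <- function() {
  list(
    type = "water",
    ref_atoms = character(0),
    head_atoms = character(0),
    tails = list(),
    donors = list(
      c(donor = "OW", hydrogen = "HW1"),
      c(donor = "OW", hydrogen = "HW2")
    ),
    acceptors = "OW",
    axis = NULL
  )
}

# Local template coordinates (all_trans), z measured headgroup -> tail
# tip, built so that every methylene C-H bond is perpendicular to the
# chain axis (S_CD closed forms are then exact).
phospholipid_template <- function(nc) {
  rows <- list(
    c("N", "N", 1.0, 0.0, -1.0),
    c("P", "P", 0.0, 0.0, 0.0),
    c("O11", "O", 0.7, 0.7, -0.3),
    c("O12", "O", -0.7, -0.7, -0.3),
    c("C2", "C", 0.0, 0.5, 3.8),
    c("C1A", "C", -1.2, 0.0, 7.6),
    c("C1B", "C", 1.2, 0.0, 7.6)
  )
  for (suffix in c("A", "B")) {
    x0 <- if (suffix == "A") -1.2 else 1.2
    for (k in 2:nc) {
      z <- 7.6 + 1.27 * (k - 1)
      x <- x0 + 0.445 * (-1)^k
      rows <- c(rows, list(
        c(paste0("C", k, suffix), "C", x, 0.0, z),
        c(paste0("H", k, suffix, 1), "H", x, 1.09, z),
        c(paste0("H", k, suffix, 2), "H", x, -1.09, z)
      ))
    }
  }
  template_tibble(rows)
}

sterol_template <- function() {
  template_tibble(list(
    c("O3", "O", 0.0, 0.0, -0.5),
    c("HO3", "H", 0.0, 0.8, -1.0),
    c("C3", "C", 0.0, 0.0, 0.5),
    c("C5", "C", 0.8, 0.0, 3.5),
    c("C7", "C", -0.8, 0.0, 6.5),
    c("C10", "C", 0.8, 0.0, 9.5),
    c("C13", "C", -0.8, 0.0, 12.5),
    c("C17", "C", 0.0, 0.0, 15.5)
  ))
}

template_tibble <- function(rows) {
  m <- do.call(rbind, rows)
  tibble(
    atom = m[, 1], element = m[, 2],
    x = as.numeric(m[, 3]), y = as.numeric(m[, 4]), z = as.numeric(m[, 5])
  )
}

#' Generate a toy monolayer trajectory
#'
#' Builds a deterministic, fully synthetic two-leaflet monolayer system
#' as used in monolayer simulations: two leaflets of `n_lipids_per_leaflet`
#' molecules each, separated by a slab of randomly placed three-site
#' water at bulk number density 0.0334 molecules/Å³, with tails
#' pointing away from the water on both sides. Lipids sit on a
#' hexagonal, square or random lattice in the xy plane; chains are
#' either ideal all-trans (C-H bonds exactly perpendicular to the chain
#' axis) or seeded random walks. This is geometry only: no force field
#' or dynamics, but every structural operator of the package can run on
#' the output with known ground truth.
#'
#' @param n_lipids_per_leaflet Molecules per leaflet.
#' @param species_fractions Named mole fractions summing to 1, e.g.
#'   `c(DPPX = 0.8, CHOL = 0.2)`.
#' @param lattice `"hexagonal"`, `"square"` or `"random"`.
#' @param chain_conformation `"all_trans"` or `"random_walk"`.
#' @param tilt_deg Rigid tilt of each lipid from the leaflet normal,
#'   degrees.
#' @param apl Lattice area per molecule, Å² (sets the box).
#' @param water_thickness Water slab thickness, Å.
#' @param n_frames Number of frames.
#' @param jitter_sd Per-frame Gaussian positional noise, Å (0 = static).
#' @param topology A [toy_topology()]; defaults to one built from
#'   `species_fractions`.
#' @param seed Integer seed; output is a pure function of arguments.
#' @return A tibble of class `ml_traj` with columns `frame`, `mol_id`,
#'   `species`, `leaflet` (`"upper"`, `"lower"` or `NA` for water),
#'   `atom`, `element`, `x`, `y`, `z` (Å), plus attributes `box`
#'   (c(Lx, Ly, Lz)), `water_z` (slab z range) and `topology`.
#' @examples
#' traj <- gen_toy_monolayer(16, c(DPPX = 0.75, CHOL = 0.25), seed = 1)
#' dplyr::count(traj[traj$frame == 1, ], species)
#' @export
gen_toy_monolayer <- function(n_lipids_per_leaflet = 100L,
                              species_fractions = c(DPPX = 1),
                              lattice = c("hexagonal", "square", "random"),
                              chain_conformation = c("all_trans", "random_walk"),
                              tilt_deg = 0,
                              apl = 45,
                              water_thickness = 30,
                              n_frames = 1L,
                              jitter_sd = 0,
                              topology = NULL,
                              seed = 1L) {
  lattice <- match.arg(lattice)
  chain_conformation <- match.arg(chain_conformation)
  if (abs(sum(species_fractions) - 1) > 1e-9)
    abort("species fractions must sum to 1")
  if (is.null(names(species_fractions)) || any(names(species_fractions) == ""))
    abort("species fractions must be named")
  n <- as.integer(n_lipids_per_leaflet)
  topology <- topology %||% toy_topology(names(species_fractions))

  sites <- with_seed(seed, lattice_sites(n, apl, lattice))
  box_xy <- attr(sites, "box_xy")

  counts <- species_counts(species_fractions, n)
  templates <- lapply(names(species_fractions), function(sp) {
    if (topology[[sp]]$type == "sterol") {
      sterol_template()
    } else {
      nc <- sum(grepl("^C\\d+A$", names(topology[[sp]]$tails$sn1$hydrogens))) + 1L
      phospholipid_template(max(nc, 3L))
    }
  })
  names(templates) <- names(species_fractions)

  frames <- with_seed(seed + 1L, {
    species_by_site <- sample(rep(names(counts), counts))
    lapply(seq_len(n_frames), function(fr) {
      build_frame(fr, sites, species_by_site, templates, topology,
        chain_conformation, tilt_deg, water_thickness, box_xy, jitter_sd
      )
    })
  })
  atoms <- dplyr::bind_rows(frames)

  # shift so everything sits inside [0, Lz]; wrap x,y into the box
  margin <- 2
  zmin <- min(atoms$z)
  atoms$z <- atoms$z - zmin + margin
  Lz <- max(atoms$z) + margin
  atoms$x <- atoms$x %% box_xy[1]
  atoms$y <- atoms$y %% box_xy[2]
  water_z <- range(atoms$z[atoms$species == "W"])

  new_ml_curve(atoms,
    class = "ml_traj",
    box = c(box_xy, Lz), water_z = water_z, topology = topology
  )
}

species_counts <- function(fractions, n) {
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

lattice_sites <- function(n, apl, lattice) {
  if (lattice == "random") {
    L <- sqrt(n * apl)
    xy <- cbind(runif(n, 0, L), runif(n, 0, L))
    return(structure(xy, box_xy = c(L, L)))
  }
  fac <- divisor_pair(n, even_rows = lattice == "hexagonal")
  if (is.null(fac)) abort("infeasible packing: cannot factor lipid count into a periodic lattice")
  nx <- fac[1]; ny <- fac[2]
  if (lattice == "square") {
    a <- sqrt(apl)
    ax <- a; ay <- a
    offset <- 0
  } else {
    ax <- sqrt(2 * apl / sqrt(3))
    ay <- ax * sqrt(3) / 2
    offset <- ax / 2
  }
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  x <- ix * ax + (iy %% 2L) * offset
  y <- iy * ay
  structure(cbind(x, y), box_xy = c(nx * ax, ny * ay))
}

# divisor pair (nx, ny) with ny (rows) even when required, closest to
# square aspect
divisor_pair <- function(n, even_rows = FALSE) {
  divs <- which(n %% seq_len(n) == 0)
  best <- NULL
  for (nx in divs) {
    ny <- n %/% nx
    if (even_rows && ny %% 2L != 0L) next
    score <- abs(log(nx / ny))
    if (is.null(best) || score < best$score) best <- list(pair = c(nx, ny), score = score)
  }
  best$pair
}

build_frame <- function(fr, sites, species_by_site, templates, topology,
                        conformation, tilt_deg, water_thickness, box_xy, jitter_sd) {
  n <- nrow(sites)
  mols <- vector("list", 2L * n + 1L)
  mol_id <- 0L
  for (leaflet in c("upper", "lower")) {
    sgn <- if (leaflet == "upper") 1 else -1
    z_anchor <- if (leaflet == "upper") water_thickness + 1 else -1
    for (i in seq_len(n)) {
      mol_id <- mol_id + 1L
      sp <- species_by_site[i]
      tpl <- templates[[sp]]
      loc <- tpl[, c("x", "y", "z")]
      if (conformation == "random_walk" && length(topology[[sp]]$tails)) {
        loc <- randomize_tails(loc, tpl$atom, topology[[sp]])
      }
      if (tilt_deg != 0) {
        th <- tilt_deg * pi / 180
        xz <- cbind(loc$x * cos(th) + loc$z * sin(th), -loc$x * sin(th) + loc$z * cos(th))
        loc$x <- xz[, 1]; loc$z <- xz[, 2]
      }
      if (jitter_sd > 0 && fr > 1L) {
        loc <- loc + matrix(rnorm(3L * nrow(loc), 0, jitter_sd), ncol = 3)
      }
      mols[[mol_id]] <- tibble(
        frame = fr, mol_id = mol_id, species = sp, leaflet = leaflet,
        atom = tpl$atom, element = tpl$element,
        x = sites[i, 1] + loc$x,
        y = sites[i, 2] + loc$y,
        z = z_anchor + sgn * loc$z
      )
    }
  }
  # water slab in z = [0, water_thickness]
  n_w <- round(.water_number_density * box_xy[1] * box_xy[2] * water_thickness)
  ow <- cbind(
    runif(n_w, 0, box_xy[1]), runif(n_w, 0, box_xy[2]),
    runif(n_w, 0, water_thickness)
  )
  u1 <- random_units(n_w)
  u2 <- random_units(n_w)
  mols[[2L * n + 1L]] <- tibble(
    frame = fr,
    mol_id = rep(2L * n + seq_len(n_w), each = 3L),
    species = "W", leaflet = NA_character_,
    atom = rep(c("OW", "HW1", "HW2"), n_w),
    element = rep(c("O", "H", "H"), n_w),
    x = as.vector(rbind(ow[, 1], ow[, 1] + 0.96 * u1[, 1], ow[, 1] + 0.96 * u2[, 1])),
    y = as.vector(rbind(ow[, 2], ow[, 2] + 0.96 * u1[, 2], ow[, 2] + 0.96 * u2[, 2])),
    z = as.vector(rbind(ow[, 3], ow[, 3] + 0.96 * u1[, 3], ow[, 3] + 0.96 * u2[, 3]))
  )
  dplyr::bind_rows(mols)
}

random_units <- function(n) {
  v <- matrix(rnorm(3L * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Replace the all-trans tail carbons by seeded random-walk chains
# (steps of 1.54 A biased along the leaflet normal), keeping the two
# methylene hydrogens perpendicular to each local step.
randomize_tails <- function(loc, atom_names, sp_top) {
  for (tail in sp_top$tails) {
    carbons <- tail$carbons
    idx <- match(carbons, atom_names)
    start <- as.numeric(loc[match(sp_top$carbonyl, atom_names), ])
    pos <- start
    for (j in seq_along(idx)) {
      step <- c(rnorm(2, 0, 0.35), 1)
      step <- 1.54 * step / sqrt(sum(step^2))
      pos <- pos + step
      loc[idx[j], ] <- as.list(pos)
      hn <- tail$hydrogens[[carbons[j]]]
      hidx <- match(hn, atom_names)
      perp <- perpendicular_pair(step)
      phi <- runif(1, 0, 2 * pi)
      u <- cos(phi) * perp[[1]] + sin(phi) * perp[[2]]
      loc[hidx[1], ] <- as.list(pos + 1.09 * u)
      loc[hidx[2], ] <- as.list(pos - 1.09 * u)
    }
  }
  loc
}

perpendicular_pair <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- a - sum(a * v) * v
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(
    v[2] * u1[3] - v[3] * u1[2],
    v[3] * u1[1] - v[1] * u1[3],
    v[1] * u1[2] - v[2] * u1[1]
  )
  list(u1, u2)
}

#' Box dimensions of a trajectory
#'
#' @param traj An `ml_traj` tibble.
#' @return Numeric length-3 vector `c(Lx, Ly, Lz)`, Å.
#' @export
traj_box <- function(traj) {
  box <- curve_meta(traj, "box")
  if (is.null(box)) abort("trajectory carries no box attribute")
  box
}
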