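test_that("Voronoi areas are exact on lattices and conserve the box area", {
  traj <- gen_toy_monolayer(16, c(CHOL = 1), lattice = "hexagonal", seed = 1)
  box <- traj_box(traj)
  apl <- area_per_lipid(traj)
  expect_equal(apl$apl, rep(box[1] * box[2] / 16, nrow(apl)), tolerance = 1e-12)
  for (lf in c("upper", "lower")) {
    expect_equal(sum(apl$apl[apl$leaflet == lf]), box[1] * box[2],
      tolerance = 1e-9
    )
  }
})

test_that("Voronoi areas conserve and translate for mixed random layouts", {
  traj <- gen_toy_monolayer(25, c(DPPX = 0.6, CHOL = 0.4),
    lattice = "random", apl = 40, seed = 7
  )
  box <- traj_box(traj)
  apl <- area_per_lipid(traj)
  expect_equal(
    sum(apl$apl[apl$leaflet == "upper"]), box[1] * box[2],
    tolerance = 1e-9
  )
  # rigid xy translation (with wrap) leaves every cell area unchanged
  shifted <- traj
  shifted$x <- (shifted$x + 11.3) %% box[1]
  shifted$y <- (shifted$y + 4.7) %% box[2]
  apl2 <- area_per_lipid(shifted)
  expect_equal(apl2$apl, apl$apl, tolerance = 1e-9)
})

test_that("Voronoi cells match a dense-grid nearest-seed oracle", {
  set.seed(31)
  L <- 50
  xy <- cbind(runif(40, 0, L), runif(40, 0, L))
  areas <- leafletlab:::voronoi_areas_periodic(xy, c(L, L))
  expect_equal(sum(areas), L^2, tolerance = 1e-9)
  grid_areas <- oracle_voronoi_grid(xy, c(L, L), n_grid = 1500L)
  expect_lt(max(abs(areas - grid_areas) / areas), 0.005)
})

test_that("order parameters hit the closed forms for ideal geometries", {
  # all-trans chains along z: every C-H bond at beta = 90 deg -> 0.5
  traj <- gen_toy_monolayer(9, c(DPPX = 1), lattice = "square", seed = 3)
  op <- order_parameter(traj)
  expect_equal(op$s_cd, rep(0.5, nrow(op)), tolerance = 1e-12)
  expect_equal(sort(unique(op$tail)), c("sn1", "sn2"))
  expect_equal(nrow(op), 2 * 15) # C2..C16 per tail

  # isotropically oriented bonds average to zero
  top <- list(X = list(
    type = "phospholipid",
    tails = list(sn1 = list(carbons = "C2A", hydrogens = list(C2A = "H2A1")))
  ))
  n <- 1e5
  set.seed(99)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- 1.09 * v / sqrt(rowSums(v^2))
  iso <- make_traj(tibble::tibble(
    mol_id = rep(seq_len(n), each = 2),
    species = "X", leaflet = "upper",
    atom = rep(c("C2A", "H2A1"), n),
    element = rep(c("C", "H"), n),
    x = as.vector(rbind(0, v[, 1])),
    y = as.vector(rbind(0, v[, 2])),
    z = as.vector(rbind(0, v[, 3]))
  ), box = c(100, 100, 100))
  op_iso <- order_parameter(iso, topology = top)
  expect_lt(abs(op_iso$s_cd), 0.01)

  # bonds parallel to z give -1: outside the physical range, flagged
  par <- make_traj(tibble::tibble(
    mol_id = rep(1:2, each = 2),
    species = "X", leaflet = "upper",
    atom = rep(c("C2A", "H2A1"), 2),
    element = rep(c("C", "H"), 2),
    x = 0, y = 0,
    z = c(0, 1.09, 5, 6.09)
  ), box = c(10, 10, 10))
  expect_warning(op_par <- order_parameter(par, topology = top), "S_CD")
  expect_equal(op_par$s_cd, -1)
})

test_that("order parameter estimator is invariant under rotation about z", {
  traj <- gen_toy_monolayer(9, c(DPPX = 1),
    lattice = "square",
    chain_conformation = "random_walk", seed = 12
  )
  op <- order_parameter(traj)
  th <- 0.7
  rot <- traj
  rot$x <- cos(th) * traj$x - sin(th) * traj$y
  rot$y <- sin(th) * traj$x + cos(th) * traj$y
  expect_equal(order_parameter(rot)$s_cd, op$s_cd, tolerance = 1e-12)
})

test_that("thickness decomposition reads off constructed geometry", {
  # the printed DPPC decomposition placed by construction
  top <- list(L = list(
    type = "phospholipid", tails = list(),
    carbonyl = "C1A", terminal = "C16A", phosphorus = "P"
  ))
  traj <- make_traj(tibble::tibble(
    mol_id = 1L, species = "L", leaflet = "upper",
    atom = c("C16A", "C1A", "P"),
    z = c(0, 16.1, 23.7), x = 0, y = 0
  ), box = c(20, 20, 30))
  th <- thicknesses(traj, topology = top)
  expect_equal(th$tail, 16.1)
  expect_equal(th$head, 7.6)
  expect_equal(th$total, 23.7)

  # tilting a rigid z-aligned lipid by 60 deg halves every z distance
  tilted <- traj
  tilted$z <- tilted$z * cos(60 * pi / 180)
  th2 <- thicknesses(tilted, topology = top)
  expect_equal(th2$total, 23.7 / 2)

  # total = tail + head for every species of the toy generator
  gt <- gen_toy_monolayer(9, c(DPPX = 1), lattice = "square", seed = 5)
  tg <- thicknesses(gt)
  expect_equal(tg$total, tg$tail + tg$head)

  # sterols carry no phosphorus and are excluded with a notice
  expect_message(
    ts <- thicknesses(gen_toy_monolayer(16, c(CHOL = 1), seed = 2)),
    "sterol"
  )
  expect_equal(nrow(ts), 0)
})

test_that("electron density histogram is conservative and correctly normalised", {
  one <- make_traj(
    tibble::tibble(element = "P", x = 5, y = 5, z = 12.3),
    box = c(10, 10, 40)
  )
  edp <- electron_density_profile(one, bins = 40)
  dz <- 40 / 40
  expect_equal(sum(edp$rho > 0), 1L)
  expect_equal(max(edp$rho), 15 / (10 * 10 * dz))

  traj <- gen_toy_monolayer(9, c(DPPX = 0.78, CHOL = 0.22),
    lattice = "square", seed = 9
  )
  box <- traj_box(traj)
  Z <- c(H = 1, C = 6, N = 7, O = 8, P = 15)
  for (fold in c(FALSE, TRUE)) {
    edp <- electron_density_profile(traj, bins = 64, fold = fold)
    bw <- curve_meta(edp, "bin_width")
    integral <- sum(edp$rho) * box[1] * box[2] * bw * (if (fold) 2 else 1)
    expect_equal(integral, sum(Z[traj$element]), tolerance = 1e-9)
  }

  # uniform random positions give a flat profile within Poisson bounds
  set.seed(77)
  n <- 20000
  unif <- make_traj(tibble::tibble(
    element = "C", x = runif(n, 0, 20), y = runif(n, 0, 20),
    z = runif(n, 0, 50)
  ), box = c(20, 20, 50))
  edp_u <- electron_density_profile(unif, bins = 20)
  expected <- n * 6 / (20 * 20 * 50)
  sd_bin <- 6 * sqrt(n / 20) / (20 * 20 * 50 / 20)
  expect_true(all(abs(edp_u$rho - expected) < 3.5 * sd_bin))
})

test_that("axis orientation angles match constructed vectors", {
  top <- list(S = list(type = "sterol", axis = c("C3", "C17")))
  mk <- function(v) make_traj(tibble::tibble(
    mol_id = 1L, species = "S",
    atom = c("C3", "C17"),
    x = c(0, v[1]), y = c(0, v[2]), z = c(0, v[3])
  ), box = c(20, 20, 20))
  expect_equal(vector_orientation(mk(c(0, 0, 5)), top, "S")$mean_angle, 0)
  expect_equal(vector_orientation(mk(c(3, 4, 0)), top, "S")$mean_angle, 90)
  expect_error(vector_orientation(mk(c(0, 0, 0)), top, "S"), "zero-length")

  # isotropic axes: density ~ sin(theta), mean angle 1 rad = 57.3 deg
  n <- 1e5
  set.seed(123)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  iso <- make_traj(tibble::tibble(
    mol_id = rep(seq_len(n), each = 2), species = "S",
    atom = rep(c("C3", "C17"), n),
    x = as.vector(rbind(0, v[, 1])),
    y = as.vector(rbind(0, v[, 2])),
    z = as.vector(rbind(0, v[, 3]))
  ), box = c(10, 10, 10))
  vo <- vector_orientation(iso, top, "S")
  expect_equal(vo$mean_angle, 180 / pi, tolerance = 1 / 57.3)
})

test_that("contact heatmaps normalise to 1 and match brute force", {
  # exactly one atom pair within the cutoff
  two <- make_traj(tibble::tibble(
    mol_id = c(1L, 1L, 2L, 2L),
    species = c("S", "S", "L", "L"),
    atom = c("O3", "C17", "P", "N"),
    x = c(0, 0, 3, 14), y = 0, z = c(0, 9, 0, 0)
  ), box = c(30, 30, 30))
  ch <- contact_heatmap(two, "S", "L")
  expect_equal(sum(ch$matrix), 1)
  expect_equal(ch$matrix["O3", "P"], 1)
  expect_equal(ch$n_events, 1L)

  # multi-frame toy system against exhaustive enumeration
  traj <- gen_toy_monolayer(4, c(DPPX = 0.5, CHOL = 0.5),
    lattice = "square",
    apl = 24, n_frames = 3, jitter_sd = 0.4, seed = 21
  )
  box <- traj_box(traj)
  ch2 <- contact_heatmap(traj, "CHOL", "DPPX")
  ev <- oracle_contacts(traj, box, "CHOL", "DPPX", 4.0)
  expect_equal(ch2$n_events, length(ev))
  tab <- table(
    factor(vapply(ev, `[`, character(1), 1), levels = rownames(ch2$counts)),
    factor(vapply(ev, `[`, character(1), 2), levels = colnames(ch2$counts))
  )
  expect_equal(unclass(ch2$counts), unclass(tab), ignore_attr = TRUE)
  expect_equal(sum(ch2$matrix), 1)
})

test_that("hydrogen bonds obey the geometric criteria and match brute force", {
  top <- list(
    A = list(
      type = "sterol", donors = list(c(donor = "O3", hydrogen = "HO3")),
      acceptors = character(0), tails = list()
    ),
    B = list(type = "water", donors = list(), acceptors = "OW", tails = list())
  )
  mk <- function(angle_deg) {
    # donor O at origin, H along +x; acceptor placed to give the
    # requested D-H-A angle at the hydrogen, with d(D,A) = 2.8
    th <- angle_deg * pi / 180
    dOH <- 1.0
    # law of cosines for |H-A| given |D-A| = 2.8, |D-H| = 1, angle at H
    hA <- dOH * cos(th) + sqrt(2.8^2 - (dOH * sin(th))^2)
    ax <- 1 - hA * cos(th)
    ay <- hA * sin(th)
    make_traj(tibble::tibble(
      mol_id = c(1L, 1L, 2L),
      species = c("A", "A", "B"),
      atom = c("O3", "HO3", "OW"),
      element = c("O", "H", "O"),
      x = c(0, 1, ax) + 10, y = c(0, 0, ay) + 10, z = 10
    ), box = c(20, 20, 20))
  }
  hb180 <- hydrogen_bonds(mk(180), topology = top)
  expect_equal(sum(hb180$n), 1L)
  hb140 <- hydrogen_bonds(mk(140), topology = top)
  expect_equal(nrow(hb140), 0L)

  # random many-molecule frame against triple enumeration
  traj <- gen_toy_monolayer(4, c(CHOL = 1),
    lattice = "random", apl = 30,
    water_thickness = 12, n_frames = 2, jitter_sd = 0.3, seed = 17
  )
  hb <- hydrogen_bonds(traj)
  donors <- tibble::tibble(
    species = c("CHOL", "W", "W"),
    donor = c("O3", "OW", "OW"),
    hydrogen = c("HO3", "HW1", "HW2")
  )
  acceptors <- tibble::tibble(
    species = c("CHOL", "W"), acceptor = c("O3", "OW")
  )
  ref <- oracle_hbonds(traj, traj_box(traj), donors, acceptors, 3.5, 150)
  hb_sum <- dplyr::count(hb,
    frame, donor_species, donor_atom, acceptor_species, acceptor_atom,
    wt = n, name = "n"
  )
  expect_equal(
    as.data.frame(dplyr::arrange(hb_sum, frame, donor_species, donor_atom,
      acceptor_species, acceptor_atom
    )),
    as.data.frame(dplyr::arrange(ref, frame, donor_species, donor_atom,
      acceptor_species, acceptor_atom
    ))
  )
})

test_that("radial distribution function is correctly normalised", {
  # two atoms at distance r0: a single populated bin at r0
  pairT <- make_traj(tibble::tibble(
    mol_id = 1:2, x = c(2, 6.5), y = 2, z = 2
  ), box = c(20, 20, 20))
  out <- rdf(pairT, list(atom = "A"), list(atom = "A"), r_max = 9, bins = 18)
  expect_equal(sum(out$g > 0), 1L)
  expect_equal(out$r[out$g > 0], 4.75) # bin centre containing 4.5

  # ideal gas: flat at 1 beyond the first bins
  set.seed(8)
  n <- 6000
  L <- 30
  idg <- make_traj(tibble::tibble(
    mol_id = seq_len(n),
    x = runif(n, 0, L), y = runif(n, 0, L), z = runif(n, 0, L)
  ), box = c(L, L, L))
  g <- rdf(idg, list(atom = "A"), list(atom = "A"), r_max = 10, bins = 25)$g
  expect_true(all(g >= 0))
  expect_true(all(abs(g[-(1:2)] - 1) <= 0.05))

  expect_error(
    rdf(idg, list(atom = "A"), list(atom = "A"), r_max = 16),
    "half the smallest"
  )
  expect_error(
    rdf(idg, list(species = "nope"), list(atom = "A"), r_max = 5),
    "empty selection"
  )
})

test_that("hydration histogram localises water and plateaus at bulk density", {
  # one water at a known distance from a one-atom surface
  top1 <- list(L = list(type = "phospholipid", head_atoms = "P", tails = list()))
  one <- make_traj(tibble::tibble(
    mol_id = 1:2, species = c("L", "W"), atom = c("P", "OW"),
    element = c("P", "O"), leaflet = c("upper", NA),
    x = 5, y = 5, z = c(5, 11.2)
  ), box = c(10, 10, 30))
  h <- hydration_histogram(one, topology = top1, bin_width = 0.5, r_max = 10, sides = 1)
  expect_equal(sum(h$g > 0), 1L)
  expect_equal(h$distance[h$g > 0], 6.25)

  # translating the water shifts the histogram support
  moved <- one
  moved$z[moved$species == "W"] <- moved$z[moved$species == "W"] + 5
  h2 <- hydration_histogram(moved, topology = top1, bin_width = 0.5, r_max = 15, sides = 1)
  expect_equal(h2$distance[h2$g > 0], 6.25 + 5)

  # bulk water far above a planar surface (dense atom grid at z = 0):
  # histogram plateaus at 1 when normalised by the bulk density
  set.seed(4)
  L <- 40
  gp <- expand.grid(x = seq(0.5, L - 0.5, 1), y = seq(0.5, L - 0.5, 1))
  n_w <- round(0.0334 * L * L * 30)
  bulk <- make_traj(dplyr::bind_rows(
    tibble::tibble(
      mol_id = 1L, species = "L", atom = "P", element = "P",
      leaflet = "upper", x = gp$x, y = gp$y, z = 0
    ),
    tibble::tibble(
      mol_id = 1L + seq_len(n_w), species = "W", atom = "OW", element = "O",
      leaflet = NA_character_,
      x = runif(n_w, 0, L), y = runif(n_w, 0, L), z = runif(n_w, 20, 50)
    )
  ), box = c(L, L, 55))
  hb <- hydration_histogram(bulk,
    topology = top1, bin_width = 2, r_max = 28,
    sides = 1
  )
  plateau <- hb$g[hb$distance > 22 & hb$distance < 27]
  expect_equal(mean(plateau), 1, tolerance = 0.1)
})

test_that("hydration maps count per-atom events and normalise to 1", {
  traj <- gen_toy_monolayer(16, c(CHOL = 1), apl = 30, seed = 6)
  hm <- hydration_map(traj, "CHOL")
  expect_equal(sum(hm$probability), 1)
  expect_true(all(hm$probability >= 0))

  # one water oxygen 3 A from exactly one atom
  solo <- make_traj(tibble::tibble(
    mol_id = c(1L, 1L, 2L),
    species = c("S", "S", "W"),
    atom = c("O3", "C17", "OW"),
    element = c("O", "C", "O"),
    x = c(5, 5, 5), y = 5, z = c(5, 21, 8)
  ), box = c(10, 10, 30))
  hm1 <- hydration_map(solo, "S")
  expect_equal(hm1$probability[hm1$atom == "O3"], 1)

  # atom A hydrated in 3 frames, atom B in 1 -> probabilities 0.75/0.25
  frames <- dplyr::bind_rows(lapply(1:4, function(fr) {
    wz <- if (fr <= 3) 8 else 24
    tibble::tibble(
      frame = fr, mol_id = c(1L, 1L, 2L),
      species = c("S", "S", "W"),
      atom = c("AA", "BB", "OW"),
      element = c("C", "C", "O"),
      x = 5, y = 5, z = c(5, 21, wz)
    )
  }))
  multi <- make_traj(frames, box = c(10, 10, 30))
  hm2 <- hydration_map(multi, "S")
  expect_equal(hm2$probability[hm2$atom == "AA"], 0.75)
  expect_equal(hm2$probability[hm2$atom == "BB"], 0.25)

  far <- make_traj(tibble::tibble(
    mol_id = c(1L, 2L), species = c("S", "W"), atom = c("AA", "OW"),
    element = c("C", "O"), x = 5, y = 5, z = c(2, 28)
  ), box = c(10, 10, 30))
  expect_error(hydration_map(far, "S"), "never hydrated")
})
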