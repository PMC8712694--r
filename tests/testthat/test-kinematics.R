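# Helix axes, rotation recovery, SASA, displacements, chi1, atom contacts.

test_that("helix axis fitting recovers direction and tilt", {
  # a finite discrete helix has a small residual xy-z covariance, so the
  # principal axis approaches z as the helix grows (~1/n^2)
  hx <- build_ideal_helix(200)
  ca <- hx$xyz[hx$atoms$name == "CA", ]
  ax <- helix_axis(ca)
  expect_lt(sqrt(sum((ax$direction - c(0, 0, 1))^2)), 1e-3)
  hx_short <- build_ideal_helix(20)
  ca20 <- hx_short$xyz[hx_short$atoms$name == "CA", ]
  tilted <- poregate:::rotate_about(ca20, c(1, 0, 0), 10)
  ax2 <- helix_axis(tilted)
  tilt <- poregate:::rad2deg(acos(sum(ax2$direction *
                                        helix_axis(ca20)$direction)))
  expect_equal(tilt, 10, tolerance = 0.1)
  expect_error(helix_axis(ca20[1:4, ]), "at least 5")
})

test_that("rotation angles are zero on an identity trajectory and recover a rigid rotation", {
  m <- fx_model()
  top <- m$topology
  static <- pore_trajectory(m$atoms, array(m$xyz, c(nrow(m$xyz), 3L, 2L)), 0.1)
  rot0 <- rotation_series(static, top)
  expect_true(all(abs(rot0$angle) < 1e-8))
  # rigid 10-degree rotation of every pore helix about its own axis:
  # same angle at all four levels
  sc <- gating_script(3L, twist = matrix(c(0, 5, 10), 3L, 4L,
                                         dimnames = list(NULL,
                                           c("E_ring", "hydrophobic",
                                             "basic_upper", "basic_lower"))))
  run <- script_gating_trajectory(m, sc)
  rot <- rotation_series(run$trajectory, top)
  fin <- rot[rot$frame == 3L, ]
  # exact up to the (small) per-frame axis-fit tilt of a discrete helix
  expect_true(all(abs(fin$angle - 10) < 0.05))
})

test_that("imposed per-level twists are recovered within 0.5 deg (noiseless)", {
  run <- fx_open_run()
  rot <- rotation_series(run$trajectory, fx_model()$topology,
                         reference_frames = 1L)
  rec <- rotation_summary(rot)
  plateau <- rec[rec$frame >= 165, ]
  got <- tapply(plateau$angle, plateau$level, mean)
  imposed <- run$ground_truth$twist[200, names(got)]
  expect_true(all(abs(got - imposed) < 0.5))
})

test_that("twist recovery survives 0.3 A jitter within 2 deg", {
  run <- fx_noisy_run()
  rot <- rotation_series(run$trajectory, fx_model()$topology,
                         reference_frames = 1:40)
  rec <- rotation_summary(rot)
  plateau <- rec[rec$frame >= 165, ]
  got <- tapply(plateau$angle, plateau$level, mean)
  imposed <- run$ground_truth$twist[200, names(got)]
  expect_true(all(abs(got - imposed) < 2))
})

test_that("SASA: analytic sphere, buried atom, two-sphere closed form", {
  one <- channel_structure(atom_table(1L, "CA", "ALA", 1L, "A",
                                      element = "C"),
                           matrix(0, 1L, 3L))
  expect_equal(region_sasa(one, 1L), 4 * pi * 3.1^2, tolerance = 1e-9)
  # an atom caged by 12 neighbours at 2.5 A is fully buried
  cage_xyz <- rbind(c(0, 0, 0), poregate:::fibonacci_sphere(12L) * 2.5)
  cage <- channel_structure(
    atom_table(1:13, rep("CA", 13), rep("ALA", 13), 1:13, rep("A", 13),
               element = rep("C", 13)), cage_xyz)
  expect_equal(region_sasa(cage, 1L), 0)
  # two carbons 3 A apart: default quadrature vs 1e5-point vs closed form
  two <- channel_structure(
    atom_table(1:2, c("CA", "CA"), c("ALA", "ALA"), 1:2, c("A", "B"),
               element = c("C", "C")),
    rbind(c(0, 0, 0), c(3, 0, 0)))
  got <- region_sasa(two, 1L, n_points = 960L)
  hi <- region_sasa(two, 1L, n_points = 1e5L)
  R <- 3.1; d <- 3
  cap_h <- R - (d^2) / (2 * d)  # equal radii
  analytic <- 4 * pi * R^2 - 2 * pi * R * cap_h
  expect_lt(abs(got - hi) / hi, 0.01)
  expect_equal(hi, analytic, tolerance = 1e-3)
})

test_that("SASA is rigid-transform invariant and non-increasing on approach", {
  m <- fx_model()
  sel <- select_atoms(m$atoms, m$topology, chain = "A", resid = 171L)
  s0 <- region_sasa(m, sel)
  shifted <- channel_structure(m$atoms, m$xyz + 5)
  expect_equal(region_sasa(shifted, sel), s0, tolerance = 1e-9)  # exact
  moved <- channel_structure(m$atoms,
                             poregate:::rotate_about(m$xyz, c(1, 2, 3), 37) + 5)
  # rotation invariance holds to quadrature precision (fixed point lattice)
  expect_equal(region_sasa(moved, sel), s0, tolerance = 0.05)
  # two-body approach: SASA of body A decreases monotonically
  mk2 <- function(d) channel_structure(
    atom_table(1:2, c("CA", "CA"), c("ALA", "ALA"), 1:2, c("A", "B"),
               element = c("C", "C")),
    rbind(c(0, 0, 0), c(d, 0, 0)))
  s <- vapply(c(7, 5, 4, 3, 2.5), function(d) region_sasa(mk2(d), 1L),
              numeric(1))
  expect_true(all(diff(s) <= 1e-9))
})

test_that("projected displacements use the approach-positive convention", {
  atoms <- atom_table(1:2, c("CA", "CA"), c("ALA", "ALA"), 1:2, c("A", "B"),
                      element = c("C", "C"))
  base <- rbind(c(0, 0, 0), c(10, 0, 0))
  # frame 2: A translated 2 A straight toward B
  co <- array(0, c(2, 3, 3))
  co[, , 1] <- base
  co[, , 2] <- rbind(c(2, 0, 0), c(10, 0, 0))
  # frame 3: A moved perpendicular to the A-B line
  co[, , 3] <- rbind(c(0, 2, 0), c(10, 0, 0))
  traj <- pore_trajectory(atoms, co, 0.1)
  ih <- interhelix_series(traj, 1L, 2L)
  expect_equal(ih$disp_a[1], 0)
  expect_equal(ih$distance[1], 10)
  expect_equal(ih$disp_a[2], 2)          # approach is positive
  expect_equal(ih$distance[2], 8)
  expect_equal(ih$disp_a[3], 0)          # perpendicular motion projects to 0
  expect_equal(ih$distance[3], sqrt(104))  # and the distance grows
  # single-mover consistency: distance change = -projected displacement
  expect_equal(ih$distance[2] - ih$distance[1], -ih$disp_a[2])
})

test_that("chi1 reproduces constructed dihedrals and rejects Ala/Gly", {
  # N-CA-CB-CG geometry built with an exact 60-degree torsion
  mk <- function(chi) {
    n <- c(0, 1.4, 0); ca <- c(0, 0, 0); cb <- c(1.5, 0, 0)
    cg0 <- matrix(c(1.5, 1.4, 0), 1L)
    cg <- poregate:::rotate_about(cg0, c(1, 0, 0), -chi, origin = cb)
    rbind(n, ca, cb, as.numeric(cg))
  }
  atoms <- atom_table(1:4, c("N", "CA", "CB", "CG"), rep("HIS", 4),
                      rep(1L, 4), rep("A", 4))
  for (chi in c(0, 60, -120, 175)) {
    traj <- pore_trajectory(atoms, mk(chi), 0.1)
    expect_equal(chi1_series(traj, 1L, "A")$chi1, chi, tolerance = 1e-9)
  }
  ala <- atom_table(1:3, c("N", "CA", "CB"), rep("ALA", 3), rep(1L, 3),
                    rep("A", 3))
  traj_ala <- pore_trajectory(ala, matrix(rnorm(9), 3L), 0.1)
  expect_error(chi1_series(traj_ala, 1L, "A"), "chi1 is undefined")
})

test_that("atom-contact counts respect the cutoff and match a double-loop oracle", {
  # isolated residue
  one <- channel_structure(atom_table(1:2, c("CB", "CG"), c("HIS", "HIS"),
                                      c(1L, 1L), c("A", "A"),
                                      element = c("C", "C")),
                           rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(atom_contact_count(one, 1L, "A"), 0L)
  # one neighbour atom at 7.4 A with cutoff 7.5 counts; at 7.6 it does not
  mk <- function(d) channel_structure(
    atom_table(1:2, c("CB", "CB"), c("HIS", "LEU"), 1:2, c("A", "A"),
               element = c("C", "C")),
    rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(atom_contact_count(mk(7.4), 1L, "A", cutoff = 7.5), 1L)
  expect_equal(atom_contact_count(mk(7.6), 1L, "A", cutoff = 7.5), 0L)
  # oracle agreement around the gate residue of the full model
  m <- fx_model()
  got <- atom_contact_count(m, 206L, "A", cutoff = 7.5)
  heavy <- m$atoms$element != "H"
  self <- m$atoms$resid == 206L & m$atoms$chain == "A"
  a_idx <- which(heavy & self); b_idx <- which(heavy & !self)
  cnt <- 0L
  for (j in b_idx) {
    for (i in a_idx) {
      if (sqrt(sum((m$xyz[i, ] - m$xyz[j, ])^2)) < 7.5) { cnt <- cnt + 1L; break }
    }
  }
  expect_equal(got, cnt)
  expect_gt(got, 0L)
})
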