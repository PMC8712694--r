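# Water counting, dewetting detection, PMFs, hydrophobicity profile.

test_that("water counting requires waters and respects region geometry", {
  run <- fx_short_run()  # protein only
  expect_error(water_series(run$trajectory, fx_regions()),
               "empty water selection")
  run2 <- fx_open_run()
  ws <- water_series(run2$trajectory, fx_regions())
  wide <- tidyr::pivot_wider(ws, names_from = "region", values_from = "count")
  expect_true(all(wide$E_ring + wide$hydrophobic + wide$basic <=
                    wide$whole_pore))
  expect_true(all(ws$count >= 0))
})

test_that("dewetting detection recovers the scripted bubble to the frame", {
  run <- fx_open_run()
  ws <- water_series(run$trajectory, fx_regions())
  hy <- ws[ws$region == "hydrophobic", ]
  iv <- detect_dewetting(hy, count_threshold = 1L, persistence_ns = 1.0)
  expect_equal(nrow(iv), 1L)
  bub <- run$ground_truth$bubble_interval
  expect_lte(abs(iv$start_frame - bub[1]), 1L)
  expect_lte(abs(iv$end_frame - bub[2]), 1L)
})

test_that("dewetting intervals: persistence filter, idempotence, append invariance", {
  mk <- function(counts) tibble::tibble(frame = seq_along(counts),
                                        time_ns = (seq_along(counts) - 1) * 0.1,
                                        count = counts)
  # an all-dry series is one interval covering the trajectory
  iv <- detect_dewetting(mk(rep(0L, 30)), 1L, 0.5)
  expect_equal(c(iv$start_frame, iv$end_frame), c(1L, 30L))
  # a single-frame dip shorter than the persistence window is ignored
  cnt <- rep(10L, 30); cnt[15] <- 0L
  expect_equal(nrow(detect_dewetting(mk(cnt), 1L, 0.5)), 0L)
  # appending wet frames does not change detected intervals
  cnt2 <- c(rep(0L, 12), rep(10L, 10))
  iv1 <- detect_dewetting(mk(cnt2), 1L, 0.5)
  iv2 <- detect_dewetting(mk(c(cnt2, rep(10L, 20))), 1L, 0.5)
  expect_equal(iv1, iv2)
  expect_error(detect_dewetting(mk(cnt2), 1L, persistence_ns = 0.01),
               "at least one frame")
})

test_that("a uniform-density system has a flat PMF within 3x sampling SEM", {
  traj <- uniform_water_traj()
  dens <- 400 / (pi * 36 * 30)
  pm <- pmf_axial(traj, z_edges = seq(0, 30, 2), bulk_density = dens,
                  radial_cutoff = 6)
  # per-bin SEM of F by the delta method from per-frame count spread
  counts <- sapply(seq_len(n_frames(traj)), function(f) {
    z <- frame_coords(traj, f)[, 3]
    graphics::hist(z, breaks = seq(0, 30, 2), plot = FALSE)$counts
  })
  sem_F <- kB_T300 * apply(counts, 1, stats::sd) /
    rowMeans(counts) / sqrt(ncol(counts))
  expect_true(all(abs(pm$free_energy) <= 3 * sem_F))
})

test_that("Boltzmann inversion gives -kT ln(rho/rho_bulk) exactly", {
  # constructed two-bin system: one bin at bulk density, one at half
  nf <- 8L
  co <- array(0, c(3L, 3L, nf))
  for (f in seq_len(nf))
    co[, , f] <- cbind(0, 0, c(0.5, 1.1, 1.9))  # 1 in bin1, 2 in bin2
  atoms <- atom_table(1:3, rep("OH2", 3), rep("HOH", 3), 1:3, rep("W", 3),
                      element = rep("O", 3))
  traj <- pore_trajectory(atoms, co, 0.1)
  vol <- pi * 10^2 * 1
  pm <- pmf_axial(traj, z_edges = c(0, 1, 2), temperature = 300,
                  bulk_density = 2 / vol, radial_cutoff = 10)
  expect_equal(pm$free_energy[2], 0, tolerance = 1e-9)
  expect_equal(pm$free_energy[1], -kB_T300 * log(0.5), tolerance = 1e-9)
  expect_equal(pm$free_energy[1], 0.4132266, tolerance = 1e-6)
})

test_that("empty bins take the maximal finite free energy of the grid", {
  traj <- uniform_water_traj(n_waters = 100L, n_frames = 10L)
  dens <- 100 / (pi * 36 * 30)
  pm <- pmf_axial(traj, z_edges = seq(0, 40, 2), bulk_density = dens,
                  radial_cutoff = 6)
  expect_true(any(pm$empty))
  expect_true(all(is.finite(pm$free_energy)))
  expect_true(all(pm$free_energy[pm$empty] == max(pm$free_energy)))
  expect_equal(attr(pm, "empty_bin_value"), max(pm$free_energy))
})

test_that("radial-axial PMF uses cylindrical-shell volumes and stays flat for uniform density", {
  traj <- uniform_water_traj(n_waters = 800L, n_frames = 60L, seed = 13L)
  dens <- 800 / (pi * 36 * 30)
  pm <- pmf_radial_axial(traj, z_edges = seq(0, 30, 5),
                         r_edges = seq(0, 6, 2), bulk_density = dens,
                         radial_cutoff = 6)
  # shell areas sum to the full disc: total mean count / cylinder volume = bulk
  expect_equal(sum(pm$n_mean), 800, tolerance = 1e-9)
  expect_true(all(abs(pm$free_energy) < 0.08))  # ~3 sigma for this sampling
})

test_that("radius-rotation PMF is min-referenced with the expected support", {
  # constant series: a single occupied bin at F = 0
  pm <- pmf_radius_rotation(rep(3.3, 50), rep(5, 50))
  expect_equal(sum(!pm$empty), 1L)
  expect_equal(min(pm$free_energy), 0)
  # perfectly correlated series: occupied bins on the diagonal (slanted)
  r <- seq(2, 5, length.out = 200)
  th <- seq(0, 15, length.out = 200)
  pm2 <- pmf_radius_rotation(r, th, radius_breaks = seq(2, 5, 0.5),
                             rotation_breaks = seq(0, 15, 2.5))
  occ <- pm2[!pm2$empty, ]
  # occupancy tracks the linear map rotation = 5 * (radius - 2)
  expect_true(all(abs(occ$rotation_mid - 5 * (occ$radius_mid - 2)) <= 2.5))
  expect_equal(min(pm2$free_energy), 0)
  # independent series fill an axis-aligned rectangle
  g <- expand.grid(r = seq(2.25, 4.75, 0.5), th = seq(1.25, 13.75, 2.5))
  pm3 <- pmf_radius_rotation(g$r, g$th, radius_breaks = seq(2, 5, 0.5),
                             rotation_breaks = seq(0, 15, 2.5))
  expect_true(all(!pm3$empty))
  expect_error(pmf_radius_rotation(1:5, 1:4), "time-aligned")
})

test_that("hydrophobicity profile: flat for uniform scales, peaked mid-pore here", {
  m <- fx_model()
  flat <- hydrophobicity_profile(m, m$topology,
                                 scale = stats::setNames(
                                   rep(0.42, 20), names(ww_interface_scale())))
  expect_true(all(abs(flat$hydrophobicity - 0.42) < 1e-12))
  hp <- hydrophobicity_profile(m, m$topology)
  reg <- fx_regions()
  pk <- hp$z[which.max(hp$hydrophobicity)]
  expect_gt(pk, reg$z_min[reg$region == "hydrophobic"])
  expect_lt(pk, reg$z_max[reg$region == "hydrophobic"])
  expect_gt(max(hp$hydrophobicity), 0)   # hydrophobic stretch is positive
  expect_lt(min(hp$hydrophobicity), 0)   # charged/polar flanks are negative
  expect_error(hydrophobicity_profile(m, m$topology, scale = c(ALA = 1)),
               "scale entry")
})

test_that("the sliding-window mean matches a brute-force windowed mean", {
  m <- fx_model()
  hp <- hydrophobicity_profile(m, m$topology, window = 4, dz = 1)
  # brute force: recompute residue plane z and window means directly
  tm1 <- m$topology$helix_ranges$TM1
  ids <- tm1[1]:tm1[2]
  res_z <- 1.5 * (ids - 144)
  scale <- ww_interface_scale()
  rn <- vapply(ids, function(r)
    m$atoms$resname[which(m$atoms$resid == r)[1]], character(1))
  vals <- unname(scale[rn])
  brute <- vapply(hp$z, function(z) {
    sel <- abs(res_z - z) <= 2
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  expect_equal(hp$hydrophobicity, brute, tolerance = 1e-9)
})
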