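# Atom classification, structure/trajectory I/O, regions.

test_that("atom classification separates backbone, side-chain heavy and H", {
  at <- atom_table(1:4, c("N", "CA", "CB", "HB1"), rep("ALA", 4), rep(1L, 4),
                   rep("A", 4))
  expect_equal(at$is_backbone, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(at$is_sidechain_heavy, c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(at$is_backbone & at$is_sidechain_heavy))
  expect_true(all(at$vdw_radius > 0))
  # water oxygens are neither backbone nor side chain
  w <- atom_table(1L, "OH2", "HOH", 1L, "W", element = "O")
  expect_false(w$is_backbone | w$is_sidechain_heavy)
})

test_that("unknown elements fall back to a default radius with a warning", {
  expect_warning(at <- atom_table(1L, "XX", "LIG", 1L, "A", element = "XQ"),
                 "unknown element")
  expect_equal(at$vdw_radius, 1.70)
})

test_that("PDB round trip preserves atoms, chains and coordinates", {
  m <- fx_model()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_channel_pdb(m, path)
  st <- read_channel_pdb(path)
  expect_equal(nrow(st$atoms), nrow(m$atoms))
  expect_equal(st$atoms$chain, m$atoms$chain)   # ring order preserved
  expect_equal(st$atoms$resid, m$atoms$resid)
  expect_equal(st$atoms$is_sidechain_heavy, m$atoms$is_sidechain_heavy)
  expect_lt(max(abs(st$xyz - m$xyz)), 1e-3 + 1e-9)  # PDB: 3 decimals
})

test_that("DCD write/read round-trips coordinates to format precision", {
  run <- fx_short_run()
  traj <- run$trajectory
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(traj, path)
  back <- load_trajectory(path, traj$atoms, frame_interval = 0.1)
  expect_equal(n_frames(back), n_frames(traj))
  expect_lt(max(abs(back$coords - traj$coords)), 1e-4)  # float32 storage
})

test_that("single-frame trajectories load and atom-count mismatch errors", {
  m <- fx_model()
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(array(m$xyz, dim = c(nrow(m$xyz), 3L, 1L)), path)
  tr <- load_trajectory(path, m$atoms)
  expect_equal(n_frames(tr), 1L)
  expect_error(load_trajectory(path, m$atoms[-1, ]), "atom count mismatch")
  expect_error(pore_trajectory(m$atoms, m$xyz, frame_interval = 0),
               "frame_interval")
})

test_that("region bounds follow the generator's ring planes", {
  reg <- fx_regions()
  # ring planes by construction: z = 1.5 * (resid - 144)
  zp <- function(r) 1.5 * (r - 144)
  get <- function(nm, col) reg[[col]][reg$region == nm]
  expect_equal(get("basic", "z_min"), zp(155))
  expect_equal(get("basic", "z_max"), zp(163))
  expect_equal(get("hydrophobic", "z_min"), zp(167) - 1)
  expect_equal(get("hydrophobic", "z_max"), zp(174) + 1)
  expect_equal(get("E_ring", "z_min"), zp(178) - 1)
  expect_equal(get("whole_pore", "z_min"), zp(155))
  expect_equal(get("whole_pore", "z_max"), zp(178) + 1)
})

test_that("regions are pairwise disjoint and inside whole_pore on every frame", {
  run <- fx_short_run()
  traj <- run$trajectory
  top <- fx_model()$topology
  for (f in c(1L, 20L, 40L)) {
    st <- channel_structure(traj$atoms, frame_coords(traj, f))
    reg <- define_regions(st, top)
    sub <- reg[reg$region != "whole_pore", ]
    sub <- sub[order(sub$z_min), ]
    expect_true(all(sub$z_max[-nrow(sub)] <= sub$z_min[-1]))
    wp <- reg[reg$region == "whole_pore", ]
    expect_true(all(sub$z_min >= wp$z_min - 1e-9 & sub$z_max <= wp$z_max + 1e-9))
  }
})

test_that("degenerate ring geometry is reported, not silently reordered", {
  m <- fx_model()
  top_bad <- m$topology
  # swap the hydrophobic bounds: planes now out of order
  top_bad$region_rings[["hydrophobic_top"]] <- 167L
  top_bad$region_rings[["hydrophobic_bottom"]] <- 174L
  expect_error(define_regions(m, top_bad), "out of order")
})

test_that("pore-axis alignment recovers the convention from a tilted copy", {
  m <- fx_model()
  tilted <- channel_structure(
    m$atoms, poregate:::rotate_about(m$xyz, c(1, 1, 0), 25) + 3)
  back <- align_pore_axis(tilted, m$topology)
  reg0 <- fx_regions()
  reg1 <- define_regions(back, m$topology)
  # ring-plane spacings are restored (absolute z offset is free)
  expect_equal(diff(attr(reg1, "ring_planes")),
               diff(attr(reg0, "ring_planes")), tolerance = 1e-6)
  # E-ring above the basic region: orientation convention respected
  expect_gt(attr(reg1, "ring_planes")[["E_ring"]],
            attr(reg1, "ring_planes")[["basic_bottom"]])
})

test_that("topology validation catches malformed annotations", {
  expect_error(channel_topology(subunits = LETTERS[1:5]), "6 subunits")
  expect_error(channel_topology(gate_residue = 180L), "TM2")
  hr <- channel_topology()$helix_ranges
  hr$TM2 <- c(180L, 225L)  # overlaps TM1
  expect_error(channel_topology(helix_ranges = hr), "overlap")
})

test_that("topology YAML round trip preserves the annotation", {
  top <- fx_model()$topology
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(subunits = top$subunits,
                        helix_ranges = top$helix_ranges,
                        marker_rings = as.list(top$marker_rings),
                        region_rings = as.list(top$region_rings),
                        gate_residue = top$gate_residue), path)
  top2 <- read_topology(path)
  expect_equal(top2$helix_ranges, top$helix_ranges)
  expect_equal(unname(top2$marker_rings[names(top$marker_rings)]),
               unname(top$marker_rings))
  expect_equal(top2$gate_residue, top$gate_residue)
})
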