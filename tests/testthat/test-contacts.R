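# Contact maps, event timing with flicker suppression, six-fold consensus.

two_residue_structure <- function(gaps, resnames = c("LEU", "LEU"),
                                  chains = c("A", "A")) {
  # residue 1: CB+CG at origin-ish; residue 2: atoms at the given x gaps
  xyz1 <- rbind(c(0, 0, 0), c(0, 3, 0))
  xyz2 <- cbind(gaps, c(0, 3)[seq_along(gaps)], 0)
  n1 <- 2L; n2 <- length(gaps)
  atoms <- atom_table(seq_len(n1 + n2),
                      c("CB", "CG", c("CB", "CG")[seq_len(n2)]),
                      rep(resnames, c(n1, n2)),
                      rep(c(1L, 2L), c(n1, n2)),
                      rep(chains, c(n1, n2)),
                      element = rep("C", n1 + n2))
  channel_structure(atoms, rbind(xyz1, xyz2))
}

test_that("the pair rule needs at least two qualifying heavy-atom pairs", {
  # both residue-2 atoms at 4.9 A from their residue-1 partners: 2 pairs
  st2 <- two_residue_structure(c(4.9, 4.9))
  expect_equal(nrow(contact_map(st2, cutoff = 5.0, min_atom_pairs = 2L)), 1L)
  # only one atom close enough: a single pair does not qualify
  st1 <- two_residue_structure(c(4.9, 40))
  expect_equal(nrow(contact_map(st1, cutoff = 5.0, min_atom_pairs = 2L)), 0L)
  expect_equal(nrow(contact_map(st1, cutoff = 5.0, min_atom_pairs = 1L)), 1L)
  # one atom may participate in both qualifying pairs
  st_shared <- two_residue_structure(c(0.5))  # 1 atom near both CB and CG of res 1
  expect_equal(nrow(contact_map(st_shared, cutoff = 5.0,
                                min_atom_pairs = 2L)), 1L)
})

test_that("glycine has no side-chain heavy atoms and never makes contact", {
  atoms <- atom_table(1:4, c("N", "CA", "CB", "CG"),
                      c("GLY", "GLY", "LEU", "LEU"), c(1L, 1L, 2L, 2L),
                      rep("A", 4))
  st <- channel_structure(atoms, rbind(c(0, 0, 0), c(1, 0, 0),
                                       c(1.2, 0, 0), c(2, 0, 0)))
  expect_equal(nrow(contact_map(st, min_atom_pairs = 1L)), 0L)
})

test_that("gridded neighbour search equals the all-pairs oracle exactly", {
  m <- fx_model()
  cm_g <- contact_map(m, method = "grid")
  cm_b <- contact_map(m, method = "brute")
  expect_identical(cm_g, cm_b)
  expect_gt(nrow(cm_g), 100L)
  # also on a deformed frame
  run <- fx_short_run()
  st <- channel_structure(run$trajectory$atoms,
                          frame_coords(run$trajectory, 40L))
  expect_identical(contact_map(st, method = "grid"),
                   contact_map(st, method = "brute"))
})

test_that("the base model shows both intra and neighbour-subunit contacts", {
  m <- fx_model()
  cm <- contact_map(m)
  cls <- mapply(poregate:::classify_pair, cm$chain_i, cm$chain_j,
                MoreArgs = list(topology = m$topology))
  expect_true(any(cls == "intra"))
  expect_true(any(cls == "inter_n_nplus1"))
})

test_that("flicker suppression removes short excursions", {
  sp <- poregate:::smooth_presence
  x <- c(rep(TRUE, 10), FALSE, rep(TRUE, 10))
  expect_equal(sp(x, 5L), rep(TRUE, 21))
  y <- c(rep(TRUE, 10), rep(FALSE, 6), rep(TRUE, 2), rep(FALSE, 10))
  expect_equal(sp(y, 5L), c(rep(TRUE, 10), rep(FALSE, 18)))
  expect_equal(sp(x, 1L), x)
})

test_that("a static trajectory yields stable pairs and no events", {
  m <- fx_model()
  static <- pore_trajectory(m$atoms, array(m$xyz, c(nrow(m$xyz), 3L, 12L)), 0.1)
  sub <- select_atoms(m$atoms, m$topology, helix = c("TM3", "TM4ext"))
  ev <- contact_events(static, m$topology, subset = sub, persistence = 3L)
  expect_true(all(ev$kind == "stable"))
  expect_equal(nrow(consensus_events(ev, m$topology)), 0L)
})

test_that("scripted separation is detected at the scripted frame in all six subunits", {
  run <- fx_open_run()
  top <- fx_model()$topology
  sub <- select_atoms(run$trajectory$atoms, top, helix = c("TM3", "TM4ext"))
  ev <- contact_events(run$trajectory, top, subset = sub, persistence = 5L)
  broken <- ev[ev$kind == "broken", ]
  expect_gt(nrow(broken), 0L)
  gt_frame <- run$ground_truth$tm4_bend_event_frame
  expect_true(all(abs(broken$tau_frame - gt_frame) <= 5L))
  ce <- consensus_events(ev, top)
  expect_true(all(ce$n_subunits == 6L))
  expect_true(all(abs(ce$tau_ns - (gt_frame - 1) * 0.1) <= 5 * 0.1))
})

test_that("event detection is invariant under subunit relabelling (C6)", {
  run <- fx_short_run()
  top <- fx_model()$topology
  traj <- run$trajectory
  sub <- select_atoms(traj$atoms, top, helix = c("TM3", "TM4ext"))
  ev1 <- consensus_events(contact_events(traj, top, subset = sub,
                                         persistence = 3L), top)
  # rotate every frame by 60 degrees and relabel chains one step around
  co <- traj$coords
  for (f in seq_len(n_frames(traj)))
    co[, , f] <- poregate:::rotate_about(co[, , f], c(0, 0, 1), 60)
  atoms2 <- traj$atoms
  atoms2$chain <- top$subunits[c(2:6, 1)][match(atoms2$chain, top$subunits)]
  traj2 <- pore_trajectory(atoms2, co, traj$frame_interval)
  sub2 <- select_atoms(atoms2, top, helix = c("TM3", "TM4ext"))
  ev2 <- consensus_events(contact_events(traj2, top, subset = sub2,
                                         persistence = 3L), top)
  expect_equal(ev1, ev2)
})

test_that("the consensus rule keeps >= 3 subunits and averages times arithmetically", {
  top <- fx_model()$topology
  mk_events <- function(chains, taus) {
    tibble::tibble(
      chain_i = chains, resid_i = 240L, helix_i = "TM3",
      chain_j = chains, resid_j = 312L, helix_j = "TM4ext",
      kind = "broken", class = "intra",
      tau_frame = as.integer(taus * 10) + 1L, tau_ns = taus)
  }
  ce3 <- consensus_events(mk_events(c("A", "C", "E"), c(10, 20, 30)), top)
  expect_equal(nrow(ce3), 1L)
  expect_equal(ce3$tau_ns, 20)
  expect_equal(ce3$n_subunits, 3L)
  ce2 <- consensus_events(mk_events(c("A", "D"), c(10, 20)), top)
  expect_equal(nrow(ce2), 0L)
})

test_that("events between non-adjacent subunits are excluded with a warning", {
  top <- fx_model()$topology
  ev <- tibble::tibble(
    chain_i = c("A", "A", "A"), resid_i = 150L, helix_i = "TM1",
    chain_j = c("C", "C", "C"), resid_j = 150L, helix_j = "TM1",
    kind = "broken", class = unname(vapply(c("C", "C", "C"), function(cj)
      poregate:::classify_pair("A", cj, top), character(1))),
    tau_frame = 5L, tau_ns = 0.5)
  expect_equal(ev$class[1], "other")
  expect_warning(out <- consensus_events(ev, top), "non-adjacent")
  expect_equal(nrow(out), 0L)
})

test_that("inter-subunit consensus orients pairs along the ring direction", {
  top <- fx_model()$topology
  # the same physical contact seen in 3 subunit pairs, with mixed orderings
  ev <- tibble::tibble(
    chain_i = c("A", "B", "D"), resid_i = c(150L, 150L, 160L),
    helix_i = "TM1",
    chain_j = c("B", "C", "C"), resid_j = c(160L, 160L, 150L),
    helix_j = "TM1",
    kind = "broken", class = "inter_n_nplus1",
    tau_frame = c(11L, 21L, 31L), tau_ns = c(1, 2, 3))
  # rows 1, 2: residue 150 on subunit n, 160 on n+1; row 3 is the reverse
  # orientation (D -> C is n+1 -> n), so its residues swap on grouping
  out <- consensus_events(ev, top)
  expect_equal(nrow(out), 1L)
  expect_equal(out$resid_i, 150L)
  expect_equal(out$resid_j, 160L)
  expect_equal(out$tau_ns, 2)
  expect_equal(out$n_subunits, 3L)
})
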