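# Writers for the synthetic module: frame-0 PDB via bio3d and a minimal
# CHARMM-format DCD writer (single precision, no unit cell, no fixed atoms).
# No DCD writer exists in the installed R stack, hence the hand-written one;
# round-tripping through bio3d::read.dcd is covered by tests.

#' Write a trajectory to a CHARMM-format DCD file
#'
#' Coordinates are stored as 32-bit floats, so a round trip preserves them to
#' about 1e-5 A relative precision.
#'
#' @param coords `n_atoms x 3 x n_frames` array (A), or a [pore_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(coords, path) {
  if (inherits(coords, "pore_trajectory")) coords <- coords$coords
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  natom <- dim(coords)[1]
  nfr <- dim(coords)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload wrapped in its byte length
    tmp <- raw(0)
    tcon <- rawConnection(tmp, "wb")
    writer(tcon)
    payload <- rawConnectionValue(tcon)
    close(tcon)
    writeBin(length(payload), con, size = 4L, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L, endian = "little")
  }
  icntrl <- integer(20L)
  icntrl[1] <- nfr      # number of frames
  icntrl[2] <- 1L       # first step
  icntrl[3] <- 1L       # step interval
  icntrl[4] <- nfr      # last step
  icntrl[20] <- 24L     # CHARMM version stamp
  rec(function(c_) {
    writeBin(charToRaw("CORD"), c_)
    writeBin(icntrl[1:9], c_, size = 4L, endian = "little")
    writeBin(1.0, c_, size = 4L, endian = "little")  # timestep (float slot 10)
    writeBin(icntrl[11:20], c_, size = 4L, endian = "little")
  })
  rec(function(c_) {
    writeBin(1L, c_, size = 4L, endian = "little")
    writeBin(charToRaw(formatC("Synthetic channel trajectory", width = -80)), c_)
  })
  rec(function(c_) writeBin(natom, c_, size = 4L, endian = "little"))
  for (f in seq_len(nfr)) {
    for (d in 1:3) {
      v <- coords[, d, f]
      rec(function(c_) writeBin(v, c_, size = 4L, endian = "little"))
    }
  }
  invisible(path)
}

#' Write a structure (or one trajectory frame) to a PDB file
#'
#' @param structure a [channel_structure()] (or `channel_model`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(structure$xyz)),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Generate a complete synthetic gating fixture on disk
#'
#' Builds the hexamer, scripts a preset gating trajectory with pore water,
#' and writes: the frame-0 structure (PDB), the trajectory (DCD), the channel
#' annotation (YAML) and the scripted ground truth (JSON).
#'
#' @param dir output directory (created if missing).
#' @param preset `"open"` or `"close"` (see [preset_gating_script()]).
#' @param n_frames number of frames.
#' @param noise_sigma per-atom Gaussian jitter (A).
#' @param seed RNG seed for water placement and jitter.
#' @return named list of output paths, invisibly; the full in-memory objects
#'   are attached as attribute `"objects"`.
#' @export
generate_gating_fixture <- function(dir, preset = "open", n_frames = 200L,
                                    noise_sigma = 0, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- build_hexamer()
  regions <- define_regions(model, model$topology)
  script <- preset_gating_script(preset, n_frames = n_frames,
                                 noise_sigma = noise_sigma, seed = seed)
  waters <- populate_water(regions, n_frames,
                           bubble_interval = script$bubble_interval,
                           seed = seed + 1L)
  run <- script_gating_trajectory(model, script, waters = waters)
  paths <- list(
    pdb = file.path(dir, "channel.pdb"),
    dcd = file.path(dir, paste0("gating_", preset, ".dcd")),
    topology = file.path(dir, "topology.yaml"),
    ground_truth = file.path(dir, "ground_truth.json"))
  frame0 <- channel_structure(run$trajectory$atoms,
                              frame_coords(run$trajectory, 1L))
  write_channel_pdb(frame0, paths$pdb)
  write_dcd(run$trajectory, paths$dcd)
  top <- model$topology
  yaml::write_yaml(list(subunits = top$subunits,
                        helix_ranges = top$helix_ranges,
                        marker_rings = as.list(top$marker_rings),
                        region_rings = as.list(top$region_rings),
                        gate_residue = top$gate_residue),
                   paths$topology)
  gt <- run$ground_truth
  gt$twist <- as.data.frame(gt$twist)
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  out <- paths
  attr(out, "objects") <- list(model = model, regions = regions,
                               script = script, run = run)
  invisible(out)
}
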