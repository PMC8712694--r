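#' Channel annotation: subunits, helices, marker rings
#'
#' Static annotation of a hexameric channel: the six chain labels in ring
#' order (subunit n is a ring neighbour of n+1, wrapping around), the residue
#' interval of each transmembrane helix (shared by all subunits), the marker
#' residues whose Calpha rings anchor the four axial rotation levels, the
#' residues whose ring planes bound the axial pore regions, and the gate
#' ("steric brake") histidine.
#'
#' The defaults follow Orai numbering: E-ring E178, hydrophobic rings
#' L167/F171/V174, basic rings R155/K159/K163, gate residue H206 on TM2.
#'
#' @param subunits six chain labels in ring order n -> n+1.
#' @param helix_ranges named list of length-2 integer vectors (first, last
#'   residue id) for helices TM1, TM2, TM3, TM4a, TM4b, TM4ext. Ranges must be
#'   disjoint within a subunit.
#' @param marker_rings named integer vector with entries `E_ring`,
#'   `hydrophobic`, `basic_upper`, `basic_lower`: the Calpha anchors of the
#'   four rotation levels. All must lie inside TM1.
#' @param region_rings named integer vector with entries `E_ring`,
#'   `hydrophobic_top`, `hydrophobic_bottom`, `basic_top`, `basic_bottom`:
#'   residues whose ring planes bound the axial regions.
#' @param gate_residue residue id of the steric-brake histidine (inside TM2).
#' @return an object of class `channel_topology`.
#' @export
channel_topology <- function(
    subunits = LETTERS[1:6],
    helix_ranges = list(
      TM1 = c(144L, 184L), TM2 = c(195L, 225L), TM3 = c(235L, 265L),
      TM4a = c(275L, 289L), TM4b = c(290L, 304L), TM4ext = c(306L, 320L)),
    marker_rings = c(E_ring = 178L, hydrophobic = 171L,
                     basic_upper = 163L, basic_lower = 155L),
    region_rings = c(E_ring = 178L, hydrophobic_top = 174L,
                     hydrophobic_bottom = 167L, basic_top = 163L,
                     basic_bottom = 155L),
    gate_residue = 206L) {
  if (length(subunits) != 6L) stop("a hexameric channel needs exactly 6 subunits")
  if (anyDuplicated(subunits)) stop("subunit labels must be unique")
  need <- c("TM1", "TM2", "TM3", "TM4a", "TM4b", "TM4ext")
  if (!all(need %in% names(helix_ranges)))
    stop("helix_ranges must name ", paste(need, collapse = ", "))
  rng <- lapply(helix_ranges, function(r) sort(as.integer(r)))
  covered <- unlist(lapply(rng, function(r) r[1]:r[2]))
  if (anyDuplicated(covered)) stop("helix residue ranges overlap within a subunit")
  in_tm1 <- function(r) r >= rng$TM1[1] & r <= rng$TM1[2]
  if (!all(in_tm1(marker_rings)) || !all(in_tm1(region_rings)))
    stop("all marker/region ring residues must lie inside TM1")
  if (gate_residue < rng$TM2[1] || gate_residue > rng$TM2[2])
    stop("gate_residue must lie inside TM2")
  structure(list(subunits = as.character(subunits), helix_ranges = rng,
                 marker_rings = marker_rings, region_rings = region_rings,
                 gate_residue = as.integer(gate_residue)),
            class = "channel_topology")
}

#' @export
print.channel_topology <- function(x, ...) {
  cat("<channel_topology> subunits:", paste(x$subunits, collapse = ""),
      "| gate residue:", x$gate_residue, "\n")
  for (h in names(x$helix_ranges))
    cat("  ", h, ": ", x$helix_ranges[[h]][1], "-", x$helix_ranges[[h]][2],
        "\n", sep = "")
  invisible(x)
}

#' Read a channel annotation from YAML or JSON
#'
#' The file must provide `subunits`, `helix_ranges`, and may override
#' `marker_rings`, `region_rings` and `gate_residue`; missing entries fall
#' back to the [channel_topology()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` annotation file.
#' @return a [channel_topology()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(cfg$subunits)) args$subunits <- cfg$subunits
  if (!is.null(cfg$helix_ranges)) args$helix_ranges <- lapply(cfg$helix_ranges, as.integer)
  for (fld in c("marker_rings", "region_rings"))
    if (!is.null(cfg[[fld]])) args[[fld]] <- unlist(cfg[[fld]])
  if (!is.null(cfg$gate_residue)) args$gate_residue <- cfg$gate_residue
  do.call(channel_topology, args)
}

# Indices of the Calpha atoms of residue `resid` across all six chains.
ring_ca_idx <- function(atoms, resid) {
  which(atoms$name == "CA" & atoms$resid == resid &
          !(atoms$resname %in% water_resnames))
}

# Mean z of the six Calpha atoms of a marker ring.
ring_plane_z <- function(atoms, xyz, resid) {
  idx <- ring_ca_idx(atoms, resid)
  if (length(idx) != 6L)
    stop("marker residue ", resid, " must have exactly 6 Calpha atoms (found ",
         length(idx), ")")
  mean(xyz[idx, 3L])
}

#' Align a structure or trajectory to the pore-axis convention
#'
#' The channel axis convention used throughout the package: the C6 symmetry
#' axis is the z axis, z increases toward the extracellular side (E-ring at
#' high z), and the pore-helix Calpha centroid of the reference frame sits at
#' the xy origin. The transform is fitted once, on the reference frame, by a
#' principal-axis fit of the pore-helix (TM1) Calpha atoms, and the same rigid
#' transform is applied to every frame.
#'
#' @param traj a [pore_trajectory()] or [channel_structure()].
#' @param topology a [channel_topology()].
#' @param reference_frame frame used to fit the transform (trajectories only).
#' @return the input object with transformed coordinates.
#' @export
align_pore_axis <- function(traj, topology, reference_frame = 1L) {
  is_traj <- inherits(traj, "pore_trajectory")
  atoms <- traj$atoms
  ref <- if (is_traj) frame_coords(traj, reference_frame) else traj$xyz
  tm1 <- topology$helix_ranges$TM1
  idx <- which(atoms$name == "CA" & atoms$resid >= tm1[1] & atoms$resid <= tm1[2])
  if (length(idx) < 6L) stop("too few pore-helix Calpha atoms to fit the axis")
  ctr <- centroid(ref, idx)
  X <- sweep(ref[idx, , drop = FALSE], 2L, ctr)
  ax <- svd(X, nu = 0L, nv = 3L)$v[, 1L]
  # orient toward the extracellular side: E-ring centroid above the TM1 centroid
  ze <- ring_ca_idx(atoms, topology$marker_rings[["E_ring"]])
  zb <- ring_ca_idx(atoms, topology$marker_rings[["basic_lower"]])
  dir_ref <- centroid(ref, ze) - centroid(ref, zb)
  if (sum(ax * dir_ref) < 0) ax <- -ax
  R <- rotation_to_z(ax)
  apply_tf <- function(m) sweep(m, 2L, ctr) %*% t(R)
  if (is_traj) {
    out <- traj
    for (f in seq_len(n_frames(traj)))
      out$coords[, , f] <- apply_tf(traj$coords[, , f])
    # keep the reference frame's z origin at the TM1 centroid; nothing else to do
    out
  } else {
    channel_structure(atoms, apply_tf(traj$xyz))
  }
}

# Rotation matrix mapping unit vector v onto +z.
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- pracma_cross(v, z)
  rotation_matrix(ax, rad2deg(acos(c_)))
}

#' Define the axial pore regions from marker-ring planes
#'
#' Each ring's axial position is the mean z of its six Calpha atoms. The
#' hydrophobic region spans from the lower hydrophobic ring plane to the upper
#' hydrophobic ring plane, extended by `padding` on both sides; the basic
#' region spans the lower-to-upper basic ring planes; the E-ring is a slab of
#' width `2 * padding` about the glutamate ring; the whole pore spans the
#' basic lower bound to the E-ring upper bound. Degenerate geometry (ring
#' planes out of order, overlapping regions) is an error, never silently
#' reordered.
#'
#' @param structure a [channel_structure()], or a [pore_trajectory()] (the
#'   frame given by `frame` is used).
#' @param topology a [channel_topology()].
#' @param padding slab padding in Angstrom (>= 0).
#' @param frame frame index when `structure` is a trajectory.
#' @return a tibble with columns `region`, `z_min`, `z_max` (rows
#'   `whole_pore`, `E_ring`, `hydrophobic`, `basic`), with the padding and the
#'   ring planes attached as attributes `padding` and `ring_planes`.
#' @export
define_regions <- function(structure, topology, padding = 1.0, frame = 1L) {
  if (padding < 0) stop("padding must be >= 0")
  xyz <- if (inherits(structure, "pore_trajectory"))
    frame_coords(structure, frame) else structure$xyz
  atoms <- structure$atoms
  rr <- topology$region_rings
  zp <- vapply(rr, function(r) ring_plane_z(atoms, xyz, r), numeric(1))
  if (!(zp[["basic_bottom"]] < zp[["basic_top"]] &&
        zp[["basic_top"]] < zp[["hydrophobic_bottom"]] &&
        zp[["hydrophobic_bottom"]] < zp[["hydrophobic_top"]] &&
        zp[["hydrophobic_top"]] < zp[["E_ring"]]))
    stop("ring planes are out of order along the pore axis; ",
         "check the alignment and the region_rings annotation")
  regions <- tibble(
    region = c("whole_pore", "E_ring", "hydrophobic", "basic"),
    z_min = c(zp[["basic_bottom"]], zp[["E_ring"]] - padding,
              zp[["hydrophobic_bottom"]] - padding, zp[["basic_bottom"]]),
    z_max = c(zp[["E_ring"]] + padding, zp[["E_ring"]] + padding,
              zp[["hydrophobic_top"]] + padding, zp[["basic_top"]]))
  if (any(regions$z_min >= regions$z_max))
    stop("degenerate region: z_min >= z_max (coincident ring planes?)")
  sub <- regions[regions$region != "whole_pore", ]
  sub <- sub[order(sub$z_min), ]
  if (any(sub$z_max[-nrow(sub)] > sub$z_min[-1L]))
    stop("regions overlap; reduce padding or check ring annotation")
  wp <- regions[regions$region == "whole_pore", ]
  if (any(sub$z_min < wp$z_min - 1e-9) || any(sub$z_max > wp$z_max + 1e-9))
    stop("a region escapes the whole_pore bounds")
  attr(regions, "padding") <- padding
  attr(regions, "ring_planes") <- zp
  regions
}
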