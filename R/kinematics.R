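# Calpha-based helix kinematics: axis fitting, per-level rotation angles,
# Shrake-Rupley SASA, inter-helical distances with signed projected
# displacements, chi1 dihedral series, and atom-contact density.

#' Fit a helix axis from Calpha coordinates
#'
#' First principal direction of the centroid-removed Calpha coordinates,
#' oriented toward increasing z.
#'
#' @param ca_xyz an n x 3 matrix of Calpha coordinates (n >= 5).
#' @return list with `point` (centroid) and `direction` (unit vector).
#' @export
helix_axis <- function(ca_xyz) {
  ca_xyz <- as.matrix(ca_xyz)
  if (nrow(ca_xyz) < 5L)
    stop("helix axis fit needs at least 5 Calpha atoms")
  ctr <- colMeans(ca_xyz)
  v <- svd(sweep(ca_xyz, 2L, ctr), nu = 0L, nv = 1L)$v[, 1L]
  if (v[3L] < 0) v <- -v
  list(point = ctr, direction = v)
}

# Signed angle from vector a to vector b about unit normal u (degrees,
# positive = counter-clockwise when viewed from the tip of u).
signed_angle_about <- function(a, b, u) {
  rad2deg(atan2(sum(u * pracma_cross(a, b)), sum(a * b)))
}

#' Per-level pore-helix rotation angles
#'
#' For every pore (TM1) helix and every axial level, the signed angle between
#' the in-plane components (perpendicular to the helix's own fitted axis) of
#' the axis-to-marker-Calpha vector at frame t and at the reference. Positive
#' angles are counter-clockwise viewed from the extracellular (+z) side. The
#' reference direction can be averaged over several frames
#' (`reference_frames`), which tames per-frame jitter in the zero point.
#'
#' Levels default to the topology's four marker rings (E-ring, hydrophobic,
#' upper and lower basic). The difference between levels of the same helix is
#' the twist.
#'
#' @param traj a [pore_trajectory()].
#' @param topology a [channel_topology()].
#' @param levels named integer vector of marker residues (default
#'   `topology$marker_rings`).
#' @param reference_frames frame indices defining the zero of rotation.
#' @return tibble `frame`, `time_ns`, `subunit`, `level`, `angle` (degrees;
#'   exactly 0 at the reference when `reference_frames` is a single frame).
#' @export
rotation_series <- function(traj, topology, levels = NULL,
                            reference_frames = 1L) {
  stopifnot(inherits(traj, "pore_trajectory"))
  if (is.null(levels)) levels <- topology$marker_rings
  atoms <- traj$atoms
  tm1 <- topology$helix_ranges$TM1
  nf <- n_frames(traj)
  subs <- topology$subunits
  ca_idx <- lapply(subs, function(ch)
    which(atoms$chain == ch & atoms$name == "CA" &
            atoms$resid >= tm1[1] & atoms$resid <= tm1[2]))
  mark_idx <- lapply(subs, function(ch) {
    vapply(levels, function(r) {
      i <- which(atoms$chain == ch & atoms$name == "CA" & atoms$resid == r)
      if (length(i) != 1L)
        stop("marker residue ", r, " missing (or duplicated) on chain ", ch)
      i
    }, integer(1))
  })
  # raw axis->marker vectors, projected off the per-frame helix axis
  inplane <- function(f) {
    xyz <- traj$coords[, , f]
    lapply(seq_along(subs), function(s) {
      ax <- helix_axis(xyz[ca_idx[[s]], , drop = FALSE])
      u <- ax$direction
      vs <- sweep(xyz[mark_idx[[s]], , drop = FALSE], 2L, ax$point)
      vs - outer(c(vs %*% u), u)
    })
  }
  ref_acc <- NULL
  for (f in reference_frames) {
    v <- inplane(f)
    ref_acc <- if (is.null(ref_acc)) v
      else Map(`+`, ref_acc, v)
  }
  ref <- lapply(ref_acc, function(m) m / length(reference_frames))
  out <- vector("list", nf)
  times <- frame_times(traj)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    rows <- vector("list", length(subs))
    for (s in seq_along(subs)) {
      ax <- helix_axis(xyz[ca_idx[[s]], , drop = FALSE])
      u <- ax$direction
      cur <- sweep(xyz[mark_idx[[s]], , drop = FALSE], 2L, ax$point)
      cur <- cur - outer(c(cur %*% u), u)
      rf <- ref[[s]] - outer(c(ref[[s]] %*% u), u)  # re-project on this frame's plane
      ang <- vapply(seq_along(levels), function(k)
        signed_angle_about(rf[k, ], cur[k, ], u), numeric(1))
      rows[[s]] <- tibble(frame = f, time_ns = times[f], subunit = subs[s],
                          level = names(levels), angle = ang)
    }
    out[[f]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(level = factor(.data$level, levels = names(levels)))
}

#' Six-helix mean rotation per level
#'
#' @param rot output of [rotation_series()].
#' @return tibble `frame`, `time_ns`, `level`, `angle` (mean over subunits).
#' @export
rotation_summary <- function(rot) {
  dplyr::summarise(rot, angle = mean(.data$angle),
                   .by = c("frame", "time_ns", "level"))
}

#' Solvent accessible surface area of a residue set
#'
#' Shrake-Rupley quadrature: for each atom of the region's residues, points
#' on the sphere of radius `vdw + probe` are tested for occlusion by every
#' other atom supplied in `structure`; the SASA is the exposed fraction times
#' `4 pi (vdw + probe)^2`, summed over region atoms. Hydrogens (if any) are
#' ignored both as surface and as occluders.
#'
#' @param structure a [channel_structure()] or a trajectory plus `frame`.
#' @param region_sel indices (or logical) of the atoms whose surface is
#'   measured; occlusion is tested against all atoms of `structure`.
#' @param probe probe radius (A), default 1.4 (water).
#' @param n_points quadrature points per atom (>= 100).
#' @param frame frame index for trajectories.
#' @return total SASA in A^2.
#' @export
region_sasa <- function(structure, region_sel, probe = 1.4, n_points = 960L,
                        frame = 1L) {
  if (n_points < 100L) stop("SASA quadrature needs at least 100 points")
  xyz <- if (inherits(structure, "pore_trajectory"))
    frame_coords(structure, frame) else structure$xyz
  atoms <- structure$atoms
  if (is.logical(region_sel)) region_sel <- which(region_sel)
  if (!length(region_sel)) stop("empty SASA region selection")
  heavy <- atoms$element != "H"
  occ_idx <- which(heavy)
  region_sel <- region_sel[heavy[region_sel]]
  pts <- fibonacci_sphere(n_points)
  vdw <- atoms$vdw_radius
  total <- 0
  occ_xyz <- xyz[occ_idx, , drop = FALSE]
  occ_vdw <- vdw[occ_idx]
  for (i in region_sel) {
    R <- vdw[i] + probe
    # neighbours whose probe-inflated spheres can reach atom i's surface
    d2 <- (occ_xyz[, 1] - xyz[i, 1])^2 + (occ_xyz[, 2] - xyz[i, 2])^2 +
      (occ_xyz[, 3] - xyz[i, 3])^2
    reach <- (R + occ_vdw + probe)^2
    nb <- which(d2 < reach & d2 > 1e-12)
    sp <- sweep(pts * R, 2L, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      rj <- occ_vdw[j] + probe
      dj2 <- (sp[, 1] - occ_xyz[j, 1])^2 + (sp[, 2] - occ_xyz[j, 2])^2 +
        (sp[, 3] - occ_xyz[j, 3])^2
      exposed <- exposed & dj2 >= rj^2
      if (!any(exposed)) break
    }
    total <- total + mean(exposed) * 4 * pi * R^2
  }
  total
}

#' Per-frame SASA of the axial marker regions
#'
#' Convenience wrapper measuring, per frame, the SASA of the residues of each
#' marker ring group (E-ring, hydrophobic rings, basic rings) across all six
#' subunits, with all protein atoms occluding.
#'
#' @param traj a [pore_trajectory()].
#' @param topology a [channel_topology()].
#' @param frames frame indices (default all).
#' @param ... passed to [region_sasa()].
#' @return tibble `frame`, `time_ns`, `region`, `sasa`.
#' @export
sasa_series <- function(traj, topology, frames = NULL, ...) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  atoms <- traj$atoms
  rr <- topology$region_rings
  groups <- list(
    E_ring = rr[["E_ring"]],
    hydrophobic = rr[["hydrophobic_bottom"]]:rr[["hydrophobic_top"]],
    basic = rr[["basic_bottom"]]:rr[["basic_top"]])
  times <- frame_times(traj)
  rows <- list()
  for (f in frames) {
    st <- channel_structure(atoms[!is_water_atom(atoms), , drop = FALSE],
                            frame_coords(traj, f)[!is_water_atom(atoms), ,
                                                  drop = FALSE])
    for (g in names(groups)) {
      sel <- which(st$atoms$resid %in% groups[[g]])
      rows[[length(rows) + 1L]] <- tibble(
        frame = f, time_ns = times[f], region = g,
        sasa = region_sasa(st, sel, ...))
    }
  }
  dplyr::bind_rows(rows)
}

#' Inter-helix distance and projected displacement series
#'
#' Per frame: the distance between the Calpha centres of mass of two
#' selections, and the displacement of each COM from its reference position
#' projected onto the unit vector toward the partner's reference COM - so a
#' positive projected displacement always means approach. Using the COM of
#' all pore helices as the partner turns the projection into a
#' centripetal(+) / centrifugal(-) measure.
#'
#' @param traj a [pore_trajectory()].
#' @param sel_a,sel_b atom index vectors (typically Calpha of a helix
#'   subrange; see [select_atoms()]).
#' @param reference_frame frame defining the reference COMs.
#' @return tibble `frame`, `time_ns`, `distance`, `disp_a`, `disp_b`
#'   (projected displacements, A, positive = approach).
#' @export
interhelix_series <- function(traj, sel_a, sel_b, reference_frame = 1L) {
  if (is.logical(sel_a)) sel_a <- which(sel_a)
  if (is.logical(sel_b)) sel_b <- which(sel_b)
  if (!length(sel_a) || !length(sel_b)) stop("empty helix selection")
  ref <- frame_coords(traj, reference_frame)
  com_a0 <- centroid(ref, sel_a)
  com_b0 <- centroid(ref, sel_b)
  u_ab <- (com_b0 - com_a0) / sqrt(sum((com_b0 - com_a0)^2))
  nf <- n_frames(traj)
  times <- frame_times(traj)
  out <- tibble(frame = seq_len(nf), time_ns = times, distance = NA_real_,
                disp_a = NA_real_, disp_b = NA_real_)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    ca <- centroid(xyz, sel_a)
    cb <- centroid(xyz, sel_b)
    out$distance[f] <- sqrt(sum((ca - cb)^2))
    out$disp_a[f] <- sum((ca - com_a0) * u_ab)
    out$disp_b[f] <- sum((cb - com_b0) * (-u_ab))
  }
  out
}

#' Atom selection helper
#'
#' Builds atom index vectors by chain, helix, residue range and atom name,
#' with the helix ranges taken from a [channel_topology()].
#'
#' @param atoms atom tibble.
#' @param topology optional [channel_topology()] (needed for `helix`).
#' @param chain chain label(s); `NULL` for all.
#' @param helix helix name(s), e.g. `"TM1"`.
#' @param resid residue id vector; `NULL` for all.
#' @param name atom name(s), e.g. `"CA"`; `NULL` for all.
#' @param lower_half keep only the cytosolic (low-z residue-id) half of the
#'   selected helix range.
#' @return integer atom indices.
#' @export
select_atoms <- function(atoms, topology = NULL, chain = NULL, helix = NULL,
                         resid = NULL, name = NULL, lower_half = FALSE) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(helix)) {
    stopifnot(!is.null(topology))
    ids <- unlist(lapply(helix, function(h) {
      r <- topology$helix_ranges[[h]]
      if (is.null(r)) stop("unknown helix: ", h)
      if (lower_half) r[1]:(r[1] + (r[2] - r[1]) %/% 2) else r[1]:r[2]
    }))
    keep <- keep & atoms$resid %in% ids
  }
  if (!is.null(resid)) keep <- keep & atoms$resid %in% resid
  if (!is.null(name)) keep <- keep & atoms$name %in% name
  which(keep)
}

gamma_atom_names <- c("CG", "CG1", "OG", "OG1", "SG")

#' chi1 dihedral time series
#'
#' Standard N-CA-CB-gamma side-chain dihedral in (-180, 180] for one residue
#' of one subunit. Residues without a gamma heavy atom (Gly, Ala) are an
#' explicit error.
#'
#' @param traj a [pore_trajectory()].
#' @param resid residue id.
#' @param chain chain label.
#' @return tibble `frame`, `time_ns`, `chi1` (degrees).
#' @export
chi1_series <- function(traj, resid, chain) {
  atoms <- traj$atoms
  res <- which(atoms$resid == resid & atoms$chain == chain)
  if (!length(res)) stop("residue ", resid, " not found on chain ", chain)
  pick <- function(nms) {
    i <- res[atoms$name[res] %in% nms]
    if (!length(i))
      stop("residue ", resid, chain, " (", atoms$resname[res[1]],
           ") lacks atom(s) ", paste(nms, collapse = "/"),
           "; chi1 is undefined")
    i[1]
  }
  i_n <- pick("N"); i_ca <- pick("CA"); i_cb <- pick("CB")
  i_g <- pick(gamma_atom_names)
  nf <- n_frames(traj)
  chi <- vapply(seq_len(nf), function(f) {
    xyz <- traj$coords[, , f]
    dihedral_angle(xyz[i_n, ], xyz[i_ca, ], xyz[i_cb, ], xyz[i_g, ])
  }, numeric(1))
  tibble(frame = seq_len(nf), time_ns = frame_times(traj), chi1 = chi)
}

#' Atom-contact count around a residue
#'
#' Number of heavy atoms belonging to other residues that lie within `cutoff`
#' of any heavy atom of the given residue - a local atom-density measure for
#' steric-brake release.
#'
#' @param structure a [channel_structure()] or trajectory plus `frame`.
#' @param resid residue id.
#' @param chain chain label.
#' @param cutoff distance cutoff (A), default 7.5.
#' @param frame frame index for trajectories.
#' @return integer count.
#' @export
atom_contact_count <- function(structure, resid, chain, cutoff = 7.5,
                               frame = 1L) {
  stopifnot(cutoff > 0)
  xyz <- if (inherits(structure, "pore_trajectory"))
    frame_coords(structure, frame) else structure$xyz
  atoms <- structure$atoms
  heavy <- atoms$element != "H" & !is_water_atom(atoms)
  self <- atoms$resid == resid & atoms$chain == chain
  a <- which(heavy & self)
  if (!length(a)) stop("residue ", resid, " not found on chain ", chain)
  b <- which(heavy & !self)
  if (!length(b)) return(0L)
  mind2 <- rep(Inf, length(b))
  for (i in a) {
    d2 <- (xyz[b, 1] - xyz[i, 1])^2 + (xyz[b, 2] - xyz[i, 2])^2 +
      (xyz[b, 3] - xyz[i, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  sum(mind2 < cutoff^2)
}

#' @rdname atom_contact_count
#' @param traj a [pore_trajectory()].
#' @param frames frame indices (default all).
#' @return for the series variant, a tibble `frame`, `time_ns`, `n_contacts`.
#' @export
atom_contact_series <- function(traj, resid, chain, cutoff = 7.5,
                                frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  times <- frame_times(traj)
  tibble(frame = frames, time_ns = times[frames],
         n_contacts = vapply(frames, function(f)
           atom_contact_count(traj, resid, chain, cutoff, frame = f),
           integer(1)))
}
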