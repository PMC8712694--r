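# Synthetic hexameric channel: an idealized C6-symmetric bundle of four-helix
# subunits with scripted gating motions and scriptable pore water. The
# generator's job is to provide trajectories whose every imposed quantity
# (per-level twist, dilation, outer-helix bend, chi1 flip, bubble interval,
# per-region water counts, geometric pore radius) is known exactly, so that
# each analysis in the package can be validated by parameter recovery.

#' Build an ideal alpha-helix with pseudo-side chains
#'
#' Calpha atoms lie on a regular helix (default rise 1.5 A, twist 100 deg per
#' residue, radius 2.3 A). Each residue carries a backbone set (N, CA, C, O)
#' and two heavy pseudo-side-chain atoms (CB, CG) extending radially outward
#' from the helix axis to `sidechain_extent`, so contact, SASA, chi1 and
#' rotation analyses all have something to measure. The CG atom of residue i
#' lies exactly in the plane z = z(CA_i), at `sidechain_extent` from the axis.
#'
#' @param n_res number of residues (>= 4).
#' @param rise helical rise per residue (A).
#' @param twist helical twist per residue (degrees).
#' @param radius Calpha helix radius (A).
#' @param sidechain_extent distance of the outermost side-chain atom from the
#'   helix axis (A).
#' @param axis_xy xy position of the (vertical) helix axis.
#' @param phi0 phase of the first residue (degrees).
#' @param z0 z of the first Calpha (A).
#' @param resid_start residue id of the first residue.
#' @param chain chain label.
#' @param resnames single residue name or vector of length `n_res`.
#' @return list with `atoms` (tibble without serials) and `xyz` (matrix).
#' @export
build_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                              sidechain_extent = 3.0, axis_xy = c(0, 0),
                              phi0 = 0, z0 = 0, resid_start = 1L,
                              chain = "A", resnames = "LEU") {
  if (n_res < 4L) stop("an ideal helix needs at least 4 residues")
  if (length(resnames) == 1L) resnames <- rep(resnames, n_res)
  stopifnot(length(resnames) == n_res)
  place <- function(angle_deg, r, z) {
    a <- deg2rad(angle_deg)
    c(axis_xy[1] + r * cos(a), axis_xy[2] + r * sin(a), z)
  }
  rows <- vector("list", n_res)
  xyz <- matrix(0, n_res * 6L, 3L)
  cb_r <- (radius + sidechain_extent) / 2
  for (i in seq_len(n_res)) {
    th <- phi0 + (i - 1L) * twist
    z <- z0 + (i - 1L) * rise
    k <- (i - 1L) * 6L
    xyz[k + 1L, ] <- place(th - 0.35 * twist, 1.6, z - 0.35 * rise)  # N
    xyz[k + 2L, ] <- place(th, radius, z)                            # CA
    xyz[k + 3L, ] <- place(th + 0.35 * twist, 1.6, z + 0.35 * rise)  # C
    xyz[k + 4L, ] <- place(th + 0.35 * twist, 2.1, z + 0.35 * rise + 0.6) # O
    xyz[k + 5L, ] <- place(th, cb_r, z + 0.8)                        # CB
    xyz[k + 6L, ] <- place(th, sidechain_extent, z)                  # CG
    rows[[i]] <- tibble(
      name = c("N", "CA", "C", "O", "CB", "CG"),
      element = c("N", "C", "C", "O", "C", "C"),
      resname = resnames[i],
      resid = resid_start + i - 1L,
      chain = chain)
  }
  list(atoms = dplyr::bind_rows(rows), xyz = xyz)
}

# Default TM1 sequence: hydrophilic flanks, basic rings (R155/K159/K163),
# hydrophobic block L167..L176 with the F171 ring, E-ring at 178.
tm1_sequence <- function(range) {
  ids <- range[1]:range[2]
  nm <- rep("SER", length(ids))
  nm[ids == 155] <- "ARG"
  nm[ids %in% c(159, 163)] <- "LYS"
  nm[ids %in% c(164, 165, 166)] <- "ALA"
  nm[ids %in% c(167, 168, 170, 172, 175, 176)] <- "LEU"
  nm[ids %in% c(169, 173, 174)] <- "VAL"
  nm[ids == 171] <- "PHE"
  nm[ids == 178] <- "GLU"
  nm
}

#' Build an idealized C6-symmetric hexameric channel
#'
#' Six identical four-helix subunits arranged in three concentric layers:
#' TM1 helices (innermost, pore-lining), TM2/TM3 (middle layer), TM4a/TM4b
#' (outer layer) and a cytosolic TM4ext helix between the middle and outer
#' layers. Subunit B..F are exact 60-degree rotated copies of subunit A, so
#' the C6 symmetry of the noiseless model is exact to machine precision.
#'
#' The TM1 phase is chosen so the hydrophobic marker ring (F171 by default)
#' points straight at the pore axis; the geometric inscribed-sphere pore
#' radius at that level is therefore exactly
#' `layer_radii["TM1"] - sidechain_extent - 1.7` (carbon vdW radius), which is
#' recorded in the model for ground-truth comparisons.
#'
#' @param layer_radii named vector `c(TM1 = , TM23 = , TM4 = )` of strictly
#'   increasing ring radii (A) for the three concentric layers.
#' @param sidechain_extent side-chain reach from each helix axis (A).
#' @param topology a [channel_topology()]; its helix ranges set residue
#'   numbering and lengths.
#' @param rise,twist helical parameters passed to [build_ideal_helix()].
#' @return an object of class `channel_model` (also a `channel_structure`):
#'   list with `atoms`, `xyz`, `topology`, and `geometry` (the generator
#'   parameters including `base_pore_radius`).
#' @export
build_hexamer <- function(layer_radii = c(TM1 = 8, TM23 = 14, TM4 = 20),
                          sidechain_extent = 3.0,
                          topology = channel_topology(),
                          rise = 1.5, twist = 100) {
  if (any(diff(layer_radii[c("TM1", "TM23", "TM4")]) <= 0))
    stop("layer radii must be strictly increasing (TM1 < TM23 < TM4)")
  hr <- topology$helix_ranges
  r_tm4e <- (layer_radii[["TM23"]] + layer_radii[["TM4"]]) / 2
  # helix placements within one subunit: (radius, angle offset deg, z0)
  lay <- list(
    TM1   = list(r = layer_radii[["TM1"]],  ang = 0,   z0 = 0),
    TM2   = list(r = layer_radii[["TM23"]], ang = 13,  z0 = 5),
    TM3   = list(r = layer_radii[["TM23"]], ang = -13, z0 = 5),
    TM4a  = list(r = layer_radii[["TM4"]],  ang = -8,  z0 = 35),
    TM4b  = list(r = layer_radii[["TM4"]],  ang = 15,  z0 = 7),
    TM4ext = list(r = r_tm4e,               ang = 10,  z0 = -14))
  # phase so that the hydrophobic marker Calpha points at the pore axis
  mk <- topology$marker_rings[["hydrophobic"]]
  i_mk <- mk - hr$TM1[1]
  phi0_tm1 <- 180 - i_mk * twist
  sub_atoms <- list(); sub_xyz <- list()
  for (h in names(lay)) {
    p <- lay[[h]]
    n_res <- hr[[h]][2] - hr[[h]][1] + 1L
    resnames <- if (h == "TM1") tm1_sequence(hr$TM1) else {
      nm <- rep("LEU", n_res)
      ids <- hr[[h]][1]:hr[[h]][2]
      nm[ids == topology$gate_residue] <- "HIS"
      nm
    }
    ax <- p$r * c(cos(deg2rad(p$ang)), sin(deg2rad(p$ang)))
    hx <- build_ideal_helix(
      n_res, rise = rise, twist = twist, sidechain_extent = sidechain_extent,
      axis_xy = ax, phi0 = if (h == "TM1") phi0_tm1 else 0, z0 = p$z0,
      resid_start = hr[[h]][1], chain = topology$subunits[1],
      resnames = resnames)
    sub_atoms[[h]] <- hx$atoms
    sub_xyz[[h]] <- hx$xyz
  }
  a0 <- dplyr::bind_rows(sub_atoms)
  x0 <- do.call(rbind, sub_xyz)
  all_atoms <- list(); all_xyz <- list()
  for (s in 0:5) {
    as <- a0
    as$chain <- topology$subunits[s + 1L]
    all_atoms[[s + 1L]] <- as
    all_xyz[[s + 1L]] <- if (s == 0) x0 else rotate_about(x0, c(0, 0, 1), 60 * s)
  }
  atoms <- dplyr::bind_rows(all_atoms)
  atoms <- atom_table(seq_len(nrow(atoms)), atoms$name, atoms$resname,
                      atoms$resid, atoms$chain, element = atoms$element)
  xyz <- do.call(rbind, all_xyz)
  geometry <- list(layer_radii = layer_radii, sidechain_extent = sidechain_extent,
                   rise = rise, twist = twist, helix_layout = lay,
                   base_pore_radius = layer_radii[["TM1"]] - sidechain_extent - 1.70)
  structure(list(atoms = atoms, xyz = xyz, topology = topology,
                 geometry = geometry),
            class = c("channel_model", "channel_structure"))
}

profile_or_zero <- function(x, n) {
  if (is.null(x)) return(rep(0, n))
  stopifnot(length(x) == n)
  as.numeric(x)
}

#' Gating script for the synthetic trajectory generator
#'
#' Per-frame target values of every scripted gating motion. Profiles are
#' absolute offsets from the base model geometry.
#'
#' @param n_frames number of frames.
#' @param twist `n_frames x 4` matrix of per-level pore-helix rotation targets
#'   (degrees), columns `E_ring`, `hydrophobic`, `basic_upper`, `basic_lower`;
#'   `NULL` for no twist.
#' @param dilation radial TM1 offset per frame (A); positive widens the pore.
#' @param tm4_bend outward bend angle of the TM4ext helix per frame (degrees),
#'   about its bottom (cytosolic) end.
#' @param chi1_flip_frame frame at which the gate residue's CG swings by
#'   `chi1_flip_angle` about the CA-CB bond; `NA` for no flip.
#' @param chi1_flip_angle flip amplitude in degrees.
#' @param bubble_interval `c(first, last)` frame interval during which the
#'   hydrophobic region is emptied of water; `NULL` for never.
#' @param noise_sigma per-atom, per-frame Gaussian jitter (A, >= 0).
#' @param seed RNG seed controlling jitter (and nothing else).
#' @return an object of class `gating_script`.
#' @export
gating_script <- function(n_frames, twist = NULL, dilation = NULL,
                          tm4_bend = NULL, chi1_flip_frame = NA_integer_,
                          chi1_flip_angle = 120, bubble_interval = NULL,
                          noise_sigma = 0, seed = 1L) {
  stopifnot(n_frames >= 1L, noise_sigma >= 0)
  lev <- c("E_ring", "hydrophobic", "basic_upper", "basic_lower")
  if (is.null(twist)) {
    twist <- matrix(0, n_frames, 4L, dimnames = list(NULL, lev))
  } else {
    twist <- as.matrix(twist)
    stopifnot(nrow(twist) == n_frames, all(lev %in% colnames(twist)))
    twist <- twist[, lev, drop = FALSE]
  }
  if (!is.null(bubble_interval)) {
    bubble_interval <- as.integer(bubble_interval)
    stopifnot(length(bubble_interval) == 2L,
              bubble_interval[1] >= 1L, bubble_interval[2] <= n_frames,
              bubble_interval[1] <= bubble_interval[2])
  }
  structure(list(n_frames = as.integer(n_frames), twist = twist,
                 dilation = profile_or_zero(dilation, n_frames),
                 tm4_bend = profile_or_zero(tm4_bend, n_frames),
                 chi1_flip_frame = as.integer(chi1_flip_frame),
                 chi1_flip_angle = chi1_flip_angle,
                 bubble_interval = bubble_interval,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "gating_script")
}

#' Piecewise-linear profile builders
#'
#' `ramp_profile()` holds at `from` for the first `hold_start` fraction of the
#' frames, ramps linearly, and holds at `to` for the last `hold_end` fraction
#' (the hold windows give time averages of recovered quantities something to
#' average over). `step_profile()` jumps from `from` to `to` at frame `at`.
#'
#' @param n_frames number of frames.
#' @param to,from end and start values.
#' @param hold_start,hold_end fractions of the trajectory held constant.
#' @param at step frame (the first frame at the new value).
#' @return numeric vector of length `n_frames`.
#' @export
ramp_profile <- function(n_frames, to, from = 0, hold_start = 0.2,
                         hold_end = 0.2) {
  i0 <- max(1L, floor(n_frames * hold_start))
  i1 <- min(n_frames, ceiling(n_frames * (1 - hold_end)))
  out <- rep(from, n_frames)
  if (i1 > i0) out[i0:i1] <- seq(from, to, length.out = i1 - i0 + 1L)
  if (i1 < n_frames) out[(i1 + 1L):n_frames] <- to
  out
}

#' @rdname ramp_profile
#' @export
step_profile <- function(n_frames, to, at, from = 0) {
  out <- rep(from, n_frames)
  if (at <= n_frames) out[at:n_frames] <- to
  out
}

#' Preset opening / closing gating scripts
#'
#' Canned scripts emulating the two transition directions: per-level twist
#' ramps (small at the E-ring, largest in the basic region, matching the
#' twisting - not rigid rotation - character of pore-helix motion), a radial
#' dilation of the pore helices, a step-like outward bend of the TM4ext helix
#' midway, a gate-residue chi1 flip at 75% of the run, and a scripted bubble:
#' present until 70% of the run for `"open"`, appearing at 70% for `"close"`.
#'
#' @param preset `"open"` (closed-to-open) or `"close"`.
#' @param n_frames number of frames (default 200).
#' @param noise_sigma Gaussian jitter (A).
#' @param seed RNG seed.
#' @return a [gating_script()].
#' @export
preset_gating_script <- function(preset = c("open", "close"), n_frames = 200L,
                                 noise_sigma = 0, seed = 1L) {
  preset <- match.arg(preset)
  final <- if (preset == "open")
    c(E_ring = 2, hydrophobic = 11, basic_upper = 14, basic_lower = 16)
  else
    c(E_ring = 2, hydrophobic = 16, basic_upper = 20, basic_lower = 22)
  twist <- sapply(final, function(v) ramp_profile(n_frames, v))
  dil <- ramp_profile(n_frames, if (preset == "open") 1.5 else -1.5)
  bend_at <- as.integer(ceiling(0.55 * n_frames))
  bend <- if (preset == "open") step_profile(n_frames, 25, bend_at)
          else step_profile(n_frames, 0, bend_at, from = 25)
  bubble <- if (preset == "open") c(1L, as.integer(floor(0.7 * n_frames)))
            else c(as.integer(ceiling(0.7 * n_frames)), n_frames)
  gating_script(n_frames, twist = twist, dilation = dil, tm4_bend = bend,
                chi1_flip_frame = as.integer(ceiling(0.75 * n_frames)),
                bubble_interval = bubble, noise_sigma = noise_sigma,
                seed = seed)
}

#' Scripted pore water
#'
#' Places single-site water pseudo-particles by uniform sampling at the given
#' number density inside a pore cylinder spanning the whole-pore region plus a
#' bulk slab above the extracellular mouth. During `bubble_interval` the
#' hydrophobic region slab is excluded from the sampling volume, so that
#' region holds exactly zero particles in those frames. The particle count is
#' Poisson-drawn once (the trajectory atom count must be constant) and held
#' fixed across frames; positions are resampled every frame.
#'
#' @param regions region table from [define_regions()].
#' @param n_frames number of frames.
#' @param density bulk number density (A^-3); default 0.0334, ambient water.
#' @param bubble_interval `c(first, last)` frames of the dry spell, or `NULL`.
#' @param pore_radius radius of the pore sampling cylinder (A).
#' @param bulk_radius,bulk_thickness bulk slab geometry (A).
#' @param seed RNG seed.
#' @return list with `atoms` (water atom tibble), `coords`
#'   (`n_waters x 3 x n_frames` array) and `counts` (tibble `frame`, `region`,
#'   `count` - the scripted ground truth).
#' @export
populate_water <- function(regions, n_frames, density = 0.0334,
                           bubble_interval = NULL, pore_radius = 4.5,
                           bulk_radius = 12, bulk_thickness = 10, seed = 1L) {
  stopifnot(density > 0, pore_radius > 0)
  wp <- regions[regions$region == "whole_pore", ]
  hy <- regions[regions$region == "hydrophobic", ]
  z0 <- wp$z_min; z1 <- wp$z_max
  if (z1 - z0 <= 0) stop("whole_pore region has zero height")
  v_pore_lo <- pi * pore_radius^2 * (hy$z_min - z0)
  v_pore_hy <- pi * pore_radius^2 * (hy$z_max - hy$z_min)
  v_pore_hi <- pi * pore_radius^2 * (z1 - hy$z_max)
  v_bulk <- pi * bulk_radius^2 * bulk_thickness
  withr::with_seed(seed, {
    n_w <- stats::rpois(1L, density * (v_pore_lo + v_pore_hy + v_pore_hi + v_bulk))
    if (n_w < 1L) stop("water region has essentially zero free volume")
    coords <- array(0, dim = c(n_w, 3L, n_frames))
    counts <- matrix(0L, n_frames, 4L,
                     dimnames = list(NULL, regions$region))
    comp <- list(
      lo = c(z0, hy$z_min, pore_radius),
      hy = c(hy$z_min, hy$z_max, pore_radius),
      hi = c(hy$z_max, z1, pore_radius),
      bulk = c(z1, z1 + bulk_thickness, bulk_radius))
    vols <- c(lo = v_pore_lo, hy = v_pore_hy, hi = v_pore_hi, bulk = v_bulk)
    for (f in seq_len(n_frames)) {
      dry <- !is.null(bubble_interval) &&
        f >= bubble_interval[1] && f <= bubble_interval[2]
      w <- vols
      if (dry) w[["hy"]] <- 0
      pick <- sample(names(vols), n_w, replace = TRUE, prob = w)
      zlim <- do.call(rbind, comp[pick])
      z <- stats::runif(n_w, zlim[, 1], zlim[, 2])
      r <- sqrt(stats::runif(n_w)) * zlim[, 3]
      th <- stats::runif(n_w, 0, 2 * pi)
      coords[, , f] <- cbind(r * cos(th), r * sin(th), z)
      for (k in seq_len(nrow(regions)))
        counts[f, k] <- sum(z >= regions$z_min[k] & z < regions$z_max[k] &
                              r <= pore_radius + 1e-9)
    }
  })
  atoms <- atom_table(seq_len(n_w), rep("OH2", n_w), rep("HOH", n_w),
                      seq_len(n_w), rep("W", n_w), element = rep("O", n_w))
  counts_tbl <- tibble(
    frame = rep(seq_len(n_frames), times = 4L),
    region = rep(regions$region, each = n_frames),
    count = as.integer(c(counts)))
  list(atoms = atoms, coords = coords, counts = counts_tbl)
}

#' Generate a scripted gating trajectory with ground truth
#'
#' Applies the gating script to the base model frame by frame: each pore
#' helix is rotated about its own axis by the per-level twist (interpolated
#' linearly in z between the four marker-ring planes), displaced radially by
#' the dilation, the TM4ext helix is bent outward about its cytosolic end,
#' the gate residue's CG swings about the CA-CB bond at the flip frame, and
#' Gaussian jitter is added last. Deterministic given the script's seed.
#'
#' @param model a `channel_model` from [build_hexamer()].
#' @param script a [gating_script()].
#' @param waters optional result of [populate_water()]; its particles are
#'   appended to the trajectory (never jittered - their placement is already
#'   stochastic).
#' @return list with `trajectory` (a [pore_trajectory()]) and `ground_truth`
#'   (list of every imposed per-frame quantity).
#' @export
script_gating_trajectory <- function(model, script, waters = NULL) {
  stopifnot(inherits(model, "channel_model"), inherits(script, "gating_script"))
  top <- model$topology
  atoms <- model$atoms
  base <- model$xyz
  nf <- script$n_frames
  lay <- model$geometry$helix_layout
  hr <- top$helix_ranges
  # level z planes (base geometry), sorted ascending in z
  lev_z <- vapply(top$marker_rings, function(r) ring_plane_z(atoms, base, r),
                  numeric(1))
  ord <- order(lev_z)
  lev_z_s <- lev_z[ord]
  # per-subunit TM1 bookkeeping
  tm1_by_sub <- lapply(top$subunits, function(ch)
    which(atoms$chain == ch & atoms$resid >= hr$TM1[1] & atoms$resid <= hr$TM1[2]))
  tm4e_by_sub <- lapply(top$subunits, function(ch)
    which(atoms$chain == ch & atoms$resid >= hr$TM4ext[1] & atoms$resid <= hr$TM4ext[2]))
  # base CA z per TM1 residue (identical across subunits)
  tm1_ids <- hr$TM1[1]:hr$TM1[2]
  ca_z <- vapply(tm1_ids, function(r) {
    base[which(atoms$chain == top$subunits[1] & atoms$resid == r &
                 atoms$name == "CA")[1], 3L]
  }, numeric(1))
  sub_phi <- 60 * (0:5)
  r_tm1 <- lay$TM1$r
  tm4e_ang <- sub_phi + lay$TM4ext$ang
  tm4e_r <- lay$TM4ext$r
  tm4e_z0 <- lay$TM4ext$z0
  gate_idx <- lapply(top$subunits, function(ch) {
    res <- which(atoms$chain == ch & atoms$resid == top$gate_residue)
    list(ca = res[atoms$name[res] == "CA"], cb = res[atoms$name[res] == "CB"],
         cg = res[atoms$name[res] == "CG"])
  })
  n_prot <- nrow(atoms)
  n_w <- if (is.null(waters)) 0L else nrow(waters$atoms)
  coords <- array(0, dim = c(n_prot + n_w, 3L, nf))
  chi1_truth <- numeric(nf)
  g1 <- gate_idx[[1]]
  chi1_base <- dihedral_angle(base[which(atoms$chain == top$subunits[1] &
                                           atoms$resid == top$gate_residue &
                                           atoms$name == "N"), ],
                              base[g1$ca, ], base[g1$cb, ], base[g1$cg, ])
  withr::with_seed(script$seed, {
    for (f in seq_len(nf)) {
      xyz <- base
      tw <- script$twist[f, c("E_ring", "hydrophobic", "basic_upper",
                              "basic_lower")][ord]
      d <- script$dilation[f]
      bend <- script$tm4_bend[f]
      for (s in 1:6) {
        idx <- tm1_by_sub[[s]]
        axis_pt <- c(r_tm1 * cos(deg2rad(sub_phi[s])),
                     r_tm1 * sin(deg2rad(sub_phi[s])), 0)
        if (any(tw != 0)) {
          # per-residue rotation about the helix's own (vertical) axis
          res_ang <- stats::approx(lev_z_s, tw, xout = ca_z, rule = 2L)$y
          ang_by_atom <- res_ang[match(atoms$resid[idx], tm1_ids)]
          for (a in unique(ang_by_atom)) {
            sel <- idx[ang_by_atom == a]
            if (a != 0)
              xyz[sel, ] <- rotate_about(xyz[sel, , drop = FALSE],
                                         c(0, 0, 1), a, origin = axis_pt)
          }
        }
        if (d != 0)
          xyz[idx, 1:2] <- sweep(xyz[idx, 1:2, drop = FALSE], 2L,
                                 d * c(cos(deg2rad(sub_phi[s])),
                                       sin(deg2rad(sub_phi[s]))), `+`)
        if (bend != 0) {
          a4 <- deg2rad(tm4e_ang[s])
          pivot <- c(tm4e_r * cos(a4), tm4e_r * sin(a4), tm4e_z0)
          tangent <- c(-sin(a4), cos(a4), 0)
          j <- tm4e_by_sub[[s]]
          xyz[j, ] <- rotate_about(xyz[j, , drop = FALSE], tangent, bend,
                                   origin = pivot)
        }
        if (!is.na(script$chi1_flip_frame) && f >= script$chi1_flip_frame) {
          g <- gate_idx[[s]]
          # rotating CG right-handed about the CA->CB direction decreases the
          # N-CA-CB-CG torsion, so apply the negated angle: a positive
          # chi1_flip_angle then increases chi1 by exactly that amount
          u <- xyz[g$cb, ] - xyz[g$ca, ]
          xyz[g$cg, ] <- as.numeric(
            rotate_about(matrix(xyz[g$cg, ], 1L), u, -script$chi1_flip_angle,
                         origin = xyz[g$cb, ]))
        }
      }
      chi1_truth[f] <- if (!is.na(script$chi1_flip_frame) &&
                           f >= script$chi1_flip_frame)
        wrap_angle(chi1_base + script$chi1_flip_angle) else chi1_base
      if (script$noise_sigma > 0)
        xyz <- xyz + stats::rnorm(length(xyz), sd = script$noise_sigma)
      coords[seq_len(n_prot), , f] <- xyz
      if (n_w > 0) coords[n_prot + seq_len(n_w), , f] <- waters$coords[, , f]
    }
  })
  all_atoms <- if (n_w > 0) {
    wa <- waters$atoms
    wa$serial <- n_prot + seq_len(n_w)
    dplyr::bind_rows(atoms, wa)
  } else atoms
  traj <- pore_trajectory(all_atoms, coords, frame_interval = 0.1)
  gt <- list(
    twist = script$twist, dilation = script$dilation,
    tm4_bend = script$tm4_bend,
    tm4_bend_event_frame = {
      ch <- which(diff(script$tm4_bend) != 0)
      if (length(ch)) ch[1] + 1L else NA_integer_
    },
    chi1_flip_frame = script$chi1_flip_frame,
    chi1 = chi1_truth,
    bubble_interval = script$bubble_interval,
    water_counts = if (n_w > 0) waters$counts else NULL,
    pore_radius = model$geometry$base_pore_radius + script$dilation,
    noise_sigma = script$noise_sigma, seed = script$seed)
  list(trajectory = traj, ground_truth = gt)
}
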