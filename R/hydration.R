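# Region-resolved water counting, dewetting (bubble) detection, and
# Boltzmann-inversion potentials of mean force:
#   F = -kB T ln(rho / rho_ref)
# with the empty-bin rule: bins devoid of samples are assigned the maximal
# finite free energy of the grid (the value of the least-occupied non-empty
# bin), so no emitted grid ever contains infinities.

kB_kcal <- 0.0019872  # Boltzmann constant, kcal/(mol K)

is_water_atom <- function(atoms) atoms$resname %in% water_resnames

#' Per-region water count time series
#'
#' A water counts toward a region in a frame iff its z lies within the
#' region's bounds and its in-plane distance from the pore axis is at most
#' `radial_cutoff`.
#'
#' @param traj a [pore_trajectory()] aligned to the pore-axis convention.
#' @param regions region table from [define_regions()].
#' @param radial_cutoff in-plane membership cutoff (A, > 0).
#' @param water_sel optional logical vector / indices selecting the water
#'   atoms; defaults to residues named like water (HOH, TIP3, SOL, ...).
#' @return tibble `frame`, `time_ns`, `region`, `count`.
#' @export
water_series <- function(traj, regions, radial_cutoff = 10, water_sel = NULL) {
  stopifnot(radial_cutoff > 0)
  if (is.null(water_sel)) water_sel <- which(is_water_atom(traj$atoms))
  if (is.logical(water_sel)) water_sel <- which(water_sel)
  if (!length(water_sel)) stop("empty water selection")
  nf <- n_frames(traj)
  counts <- matrix(0L, nf, nrow(regions))
  for (f in seq_len(nf)) {
    w <- traj$coords[water_sel, , f, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(w))) w <- matrix(w, ncol = 3L)
    r2 <- w[, 1]^2 + w[, 2]^2
    inside_r <- r2 <= radial_cutoff^2
    for (k in seq_len(nrow(regions)))
      counts[f, k] <- sum(inside_r & w[, 3] >= regions$z_min[k] &
                            w[, 3] < regions$z_max[k])
  }
  tibble(frame = rep(seq_len(nf), times = nrow(regions)),
         time_ns = rep(frame_times(traj), times = nrow(regions)),
         region = rep(regions$region, each = nf),
         count = as.integer(counts)) |>
    dplyr::mutate(region = factor(.data$region, levels = regions$region))
}

#' Detect dewetting (bubble) intervals in a water-count series
#'
#' Maximal intervals during which the count stays at or below
#' `count_threshold` for at least `persistence_ns`. The default threshold of 1
#' tolerates the occasional single-molecule intrusion without breaking a
#' bubble. Idempotent, and invariant to appending above-threshold frames.
#'
#' @param series a tibble with columns `frame`, `time_ns`, `count` (one
#'   region; filter a [water_series()] result first), ordered by frame.
#' @param count_threshold maximum count still considered "dry".
#' @param persistence_ns minimal dry duration to report (>= frame interval).
#' @return tibble `start_frame`, `end_frame`, `start_ns`, `end_ns`,
#'   `duration_ns`, sorted and non-overlapping.
#' @export
detect_dewetting <- function(series, count_threshold = 1L,
                             persistence_ns = 1.0) {
  stopifnot(all(c("frame", "time_ns", "count") %in% names(series)))
  series <- dplyr::arrange(series, .data$frame)
  dt <- if (nrow(series) > 1L) diff(series$time_ns[1:2]) else persistence_ns
  if (persistence_ns < dt)
    stop("persistence_ns must be at least one frame interval")
  dry <- series$count <= count_threshold
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= persistence_ns)
  tibble(
    start_frame = series$frame[starts[keep]],
    end_frame = series$frame[ends[keep]],
    start_ns = series$time_ns[starts[keep]],
    end_ns = series$time_ns[ends[keep]]) |>
    dplyr::mutate(duration_ns = .data$end_ns - .data$start_ns + dt)
}

new_pmf_grid <- function(table, axes, temperature, reference,
                         bulk_density = NA_real_, empty_bin_value) {
  structure(table,
            axes = axes, temperature = temperature, reference = reference,
            bulk_density = bulk_density, empty_bin_value = empty_bin_value,
            kB = kB_kcal,
            class = c("pmf_grid", class(table)))
}

finish_pmf <- function(tbl, temperature, reference, bulk_density, axes) {
  occupied <- tbl$density > 0
  if (!any(occupied)) stop("all bins are empty; no PMF can be formed")
  fe <- rep(NA_real_, nrow(tbl))
  if (reference == "bulk_referenced") {
    fe[occupied] <- -kB_kcal * temperature *
      log(tbl$density[occupied] / bulk_density)
  } else {
    fe[occupied] <- -kB_kcal * temperature *
      log(tbl$density[occupied] / max(tbl$density))
  }
  empty_val <- max(fe[occupied])
  fe[!occupied] <- empty_val
  tbl$free_energy <- fe
  tbl$empty <- !occupied
  new_pmf_grid(tbl, axes, temperature, reference, bulk_density, empty_val)
}

#' Axial PMF of water occupancy
#'
#' Boltzmann inversion of the time-averaged axial water density inside a
#' cylinder of radius `radial_cutoff`:
#' `F(z) = -kB T ln(rho(z) / rho_bulk)`. Bins without any sample get the
#' maximal finite free energy of the profile.
#'
#' @param traj a [pore_trajectory()], pore axis along z.
#' @param z_edges axial bin edges (A); default 1 A bins over the water span.
#' @param temperature absolute temperature (K).
#' @param bulk_density reference bulk number density (A^-3).
#' @param radial_cutoff cylinder radius defining pore membership (A).
#' @param water_sel water atom selection (see [water_series()]).
#' @return a `pmf_grid` tibble: `z_lo`, `z_hi`, `z_mid`, `n_mean`, `density`,
#'   `free_energy`, `empty`; metadata in attributes (`temperature`,
#'   `reference`, `bulk_density`, `empty_bin_value`).
#' @export
pmf_axial <- function(traj, z_edges = NULL, temperature = 300,
                      bulk_density = 0.0334, radial_cutoff = 10,
                      water_sel = NULL) {
  stopifnot(bulk_density > 0, n_frames(traj) >= 1L)
  if (is.null(water_sel)) water_sel <- which(is_water_atom(traj$atoms))
  if (is.logical(water_sel)) water_sel <- which(water_sel)
  if (!length(water_sel)) stop("empty water selection")
  nf <- n_frames(traj)
  zs <- c(traj$coords[water_sel, 3, ])
  rs2 <- c(traj$coords[water_sel, 1, ])^2 + c(traj$coords[water_sel, 2, ])^2
  keep <- rs2 <= radial_cutoff^2
  zs <- zs[keep]
  if (is.null(z_edges)) {
    zr <- range(zs)
    z_edges <- seq(floor(zr[1]), ceiling(zr[2]), by = 1)
  }
  h <- graphics::hist(zs[zs >= z_edges[1] & zs <= z_edges[length(z_edges)]],
                      breaks = z_edges, plot = FALSE)
  vol <- pi * radial_cutoff^2 * diff(z_edges)
  tbl <- tibble(z_lo = z_edges[-length(z_edges)], z_hi = z_edges[-1],
                z_mid = h$mids, n_mean = h$counts / nf,
                density = (h$counts / nf) / vol)
  finish_pmf(tbl, temperature, "bulk_referenced", bulk_density, axes = "z")
}

#' Radial-axial PMF of water occupancy
#'
#' Two-dimensional Boltzmann inversion on (z, r) with cylindrical-shell bin
#' volumes `pi (r_out^2 - r_in^2) dz`; same reference and empty-bin rule as
#' [pmf_axial()].
#'
#' @inheritParams pmf_axial
#' @param r_edges radial bin edges (A); default 0.5 A bins to `radial_cutoff`.
#' @return a `pmf_grid` tibble in long form: `z_mid`, `r_mid`, bin bounds,
#'   `n_mean`, `density`, `free_energy`, `empty`.
#' @export
pmf_radial_axial <- function(traj, z_edges = NULL, r_edges = NULL,
                             temperature = 300, bulk_density = 0.0334,
                             radial_cutoff = 10, water_sel = NULL) {
  stopifnot(bulk_density > 0, n_frames(traj) >= 1L)
  if (is.null(water_sel)) water_sel <- which(is_water_atom(traj$atoms))
  if (is.logical(water_sel)) water_sel <- which(water_sel)
  if (!length(water_sel)) stop("empty water selection")
  nf <- n_frames(traj)
  zs <- c(traj$coords[water_sel, 3, ])
  rs <- sqrt(c(traj$coords[water_sel, 1, ])^2 +
               c(traj$coords[water_sel, 2, ])^2)
  if (is.null(r_edges)) r_edges <- seq(0, radial_cutoff, by = 0.5)
  if (is.null(z_edges)) {
    zr <- range(zs)
    z_edges <- seq(floor(zr[1]), ceiling(zr[2]), by = 1)
  }
  keep <- rs <= r_edges[length(r_edges)] & zs >= z_edges[1] &
    zs <= z_edges[length(z_edges)]
  zi <- cut(zs[keep], z_edges, include.lowest = TRUE, labels = FALSE)
  ri <- cut(rs[keep], r_edges, include.lowest = TRUE, labels = FALSE)
  nz <- length(z_edges) - 1L; nr <- length(r_edges) - 1L
  cnt <- matrix(0, nz, nr)
  tt <- table(factor(zi, levels = seq_len(nz)), factor(ri, levels = seq_len(nr)))
  cnt[] <- as.numeric(tt)
  shell_area <- pi * (r_edges[-1]^2 - r_edges[-length(r_edges)]^2)
  vol <- outer(diff(z_edges), shell_area)
  tbl <- tibble(
    z_lo = rep(z_edges[-length(z_edges)], times = nr),
    z_hi = rep(z_edges[-1], times = nr),
    z_mid = rep((z_edges[-1] + z_edges[-length(z_edges)]) / 2, times = nr),
    r_lo = rep(r_edges[-length(r_edges)], each = nz),
    r_hi = rep(r_edges[-1], each = nz),
    r_mid = rep((r_edges[-1] + r_edges[-length(r_edges)]) / 2, each = nz),
    n_mean = c(cnt) / nf,
    density = c(cnt) / nf / c(vol))
  finish_pmf(tbl, temperature, "bulk_referenced", bulk_density,
             axes = c("z", "r"))
}

#' PMF over (pore radius, helix rotation)
#'
#' Two-dimensional histogram of time-aligned (radius, rotation) series,
#' Boltzmann-inverted against the most-populated bin:
#' `F = -kB T ln(count / count_max)`, so the minimum over non-empty bins is 0
#' (`min_referenced`). Computed upstream twice - with the radius including or
#' excluding side chains - to separate rotation-driven from
#' displacement-driven radius change.
#'
#' @param radius per-frame pore radius (A).
#' @param rotation per-frame rotation angle (degrees), same length.
#' @param radius_breaks,rotation_breaks bin edges; defaults 0.25 A and 2 deg.
#' @param temperature absolute temperature (K).
#' @return a `pmf_grid` tibble: `radius_mid`, `rotation_mid`, bin bounds,
#'   `count`, `free_energy`, `empty`.
#' @export
pmf_radius_rotation <- function(radius, rotation, radius_breaks = NULL,
                                rotation_breaks = NULL, temperature = 300) {
  if (length(radius) != length(rotation))
    stop("radius and rotation series must be time-aligned (equal length)")
  ok <- !is.na(radius) & !is.na(rotation)
  radius <- radius[ok]; rotation <- rotation[ok]
  pad_breaks <- function(x, by) {
    lo <- floor(min(x) / by) * by
    hi <- ceiling(max(x) / by) * by
    if (hi <= lo) hi <- lo + by
    seq(lo, hi, by = by)
  }
  if (is.null(radius_breaks)) radius_breaks <- pad_breaks(radius, 0.25)
  if (is.null(rotation_breaks)) rotation_breaks <- pad_breaks(rotation, 2)
  ii <- cut(radius, radius_breaks, include.lowest = TRUE, labels = FALSE)
  jj <- cut(rotation, rotation_breaks, include.lowest = TRUE, labels = FALSE)
  ni <- length(radius_breaks) - 1L; nj <- length(rotation_breaks) - 1L
  cnt <- matrix(as.numeric(table(factor(ii, levels = seq_len(ni)),
                                 factor(jj, levels = seq_len(nj)))), ni, nj)
  tbl <- tibble(
    radius_lo = rep(radius_breaks[-length(radius_breaks)], times = nj),
    radius_hi = rep(radius_breaks[-1], times = nj),
    radius_mid = rep((radius_breaks[-1] +
                        radius_breaks[-length(radius_breaks)]) / 2, times = nj),
    rotation_lo = rep(rotation_breaks[-length(rotation_breaks)], each = ni),
    rotation_hi = rep(rotation_breaks[-1], each = ni),
    rotation_mid = rep((rotation_breaks[-1] +
                          rotation_breaks[-length(rotation_breaks)]) / 2,
                       each = ni),
    count = c(cnt),
    density = c(cnt))
  out <- finish_pmf(tbl, temperature, "min_referenced", NA_real_,
                    axes = c("radius", "rotation"))
  out$density <- NULL
  out
}

# Wimley-White interfacial hydropathy, kcal/mol, sign-flipped so that
# positive means hydrophobic (favourable transfer from water to the POPC
# interface). The interfacial variant is the shipped default; any
# residue -> value map can be supplied instead.
#' @rdname hydrophobicity_profile
#' @export
ww_interface_scale <- function() {
  c(ALA = -0.17, ARG = -0.81, ASN = -0.42, ASP = -1.23, CYS = 0.24,
    GLN = -0.58, GLU = -2.02, GLY = -0.01, HIS = -0.17, ILE = 0.31,
    LEU = 0.56, LYS = -0.99, MET = 0.23, PHE = 1.13, PRO = -0.45,
    SER = -0.13, THR = -0.14, TRP = 1.85, TYR = 0.94, VAL = 0.07)
}

#' Pore hydrophobicity profile
#'
#' Each pore-lining (TM1) residue contributes its hydropathy-scale value at
#' the mean z of its six Calpha atoms; the profile is the sliding-window mean
#' of those contributions along z. Positive values mark hydrophobic stretches
#' of the pore wall.
#'
#' @param structure a [channel_structure()] (aligned to the pore axis).
#' @param topology a [channel_topology()].
#' @param scale named residue -> value map (kcal/mol, positive =
#'   hydrophobic); default [ww_interface_scale()].
#' @param window full window width of the sliding mean (A).
#' @param dz output grid spacing (A).
#' @return tibble `z`, `hydrophobicity` (NA where no residue maps within the
#'   window).
#' @export
hydrophobicity_profile <- function(structure, topology,
                                   scale = ww_interface_scale(),
                                   window = 3, dz = 0.5) {
  atoms <- structure$atoms
  xyz <- structure$xyz
  tm1 <- topology$helix_ranges$TM1
  ids <- tm1[1]:tm1[2]
  res_z <- vapply(ids, function(r) ring_plane_z(atoms, xyz, r), numeric(1))
  rn <- vapply(ids, function(r)
    atoms$resname[which(atoms$resid == r)[1]], character(1))
  missing <- setdiff(unique(rn), names(scale))
  if (length(missing))
    stop("no hydropathy scale entry for residue(s): ",
         paste(missing, collapse = ", "))
  vals <- unname(scale[rn])
  z_grid <- seq(floor(min(res_z)), ceiling(max(res_z)), by = dz)
  prof <- vapply(z_grid, function(z) {
    sel <- abs(res_z - z) <= window / 2
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  tibble(z = z_grid, hydrophobicity = prof)
}
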