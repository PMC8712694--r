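# Inscribed-sphere pore radius profiles. At each axial position z the pore
# radius is the radius of the largest sphere centred at (cx, cy, z) that
# touches no atom's van der Waals surface:
#   r(z) = max over (cx,cy) of min over atoms i of ( |c - x_i| - vdw_i ).
# The in-plane maximisation uses a Nelder-Mead search seeded from the
# previous slice's centre with seeded random restarts; a dense-grid brute
# force is provided as an independent oracle.

r_water_probe <- 1.15  # HOLE-convention water probe radius (A)

classify_radius <- function(r, r_water = r_water_probe) {
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r >= 2 * r_water ~ "multi_water",
    r >= r_water ~ "single_water",
    TRUE ~ "none")
}

slab_objective <- function(xyz, vdw, z, max_center_offset = Inf) {
  function(c_xy) {
    d <- sqrt((xyz[, 1] - c_xy[1])^2 + (xyz[, 2] - c_xy[2])^2 +
                (xyz[, 3] - z)^2)
    out <- min(d - vdw)
    # soft constraint: the sphere centre must stay near the pore axis,
    # otherwise open geometries (a single ring, a half-open slab) let the
    # centre escape to infinity where the objective is unbounded
    excess <- sqrt(sum(c_xy^2)) - max_center_offset
    if (excess > 0) out <- out - 1e4 * excess^2
    out
  }
}

#' Pore radius profile of a single frame
#'
#' Computes the maximal inscribed-sphere radius at each z of `z_grid`.
#' Atoms within `capture_pad + max(vdw)` of the slice plane participate in
#' the minimisation (spheres feel atoms outside the exact plane). When
#' `include_side_chains = FALSE`, side-chain heavy atoms are excluded, giving
#' the backbone-only profile. Slices with no atoms in reach get `NA` (missing,
#' not zero). Each radius is classified HOLE-style against the water probe
#' radius 1.15 A: `none` below one probe, `single_water` up to two probes,
#' `multi_water` beyond.
#'
#' @param structure a [channel_structure()] / `channel_model`, or a
#'   [pore_trajectory()] together with `frame`.
#' @param z_grid axial positions (A); default 0.5 A spacing over the atom span.
#' @param include_side_chains include side-chain heavy atoms (default TRUE).
#' @param method `"local"` (Nelder-Mead with restarts) or `"grid"` (dense
#'   brute force, slow; intended as the testing oracle).
#' @param frame frame index when `structure` is a trajectory.
#' @param capture_pad slab half-thickness beyond `max(vdw)` (A).
#' @param n_restarts random restarts of the centre search per slice.
#' @param grid_dx grid spacing of the brute-force method (A).
#' @param grid_halfwidth half-width of the brute-force search square (A).
#' @param max_center_offset maximal in-plane distance of a sphere centre from
#'   the pore axis (A); keeps the search bounded in open geometries.
#' @param seed seed for the restart RNG.
#' @return tibble with columns `z`, `radius`, `center_x`, `center_y`,
#'   `classification`, plus attribute `include_side_chains`.
#' @export
radius_profile <- function(structure, z_grid = NULL,
                           include_side_chains = TRUE,
                           method = c("local", "grid"), frame = 1L,
                           capture_pad = 3.0, n_restarts = 5L,
                           grid_dx = 0.1, grid_halfwidth = 5.0,
                           max_center_offset = 5.0, seed = 1L) {
  method <- match.arg(method)
  xyz <- if (inherits(structure, "pore_trajectory"))
    frame_coords(structure, frame) else structure$xyz
  atoms <- structure$atoms
  keep <- !(atoms$resname %in% water_resnames)
  if (!include_side_chains) keep <- keep & !atoms$is_sidechain_heavy
  xyz <- xyz[keep, , drop = FALSE]
  vdw <- atoms$vdw_radius[keep]
  if (is.null(z_grid)) {
    zr <- range(xyz[, 3])
    z_grid <- seq(zr[1], zr[2], by = 0.5)
  }
  reach <- max(vdw) + capture_pad
  out <- tibble(z = z_grid, radius = NA_real_,
                center_x = NA_real_, center_y = NA_real_)
  prev_center <- c(0, 0)
  restart_offsets <- withr::with_seed(seed, {
    matrix(stats::runif(2L * n_restarts, -3, 3), ncol = 2L)
  })
  for (k in seq_along(z_grid)) {
    z <- z_grid[k]
    sel <- abs(xyz[, 3] - z) <= reach
    if (!any(sel)) { prev_center <- c(0, 0); next }
    f <- slab_objective(xyz[sel, , drop = FALSE], vdw[sel], z,
                        max_center_offset = max_center_offset)
    if (method == "grid") {
      gx <- seq(-grid_halfwidth, grid_halfwidth, by = grid_dx)
      gr <- expand.grid(x = gx, y = gx)
      vals <- apply(gr, 1L, f)
      best <- which.max(vals)
      out$radius[k] <- vals[best]
      out$center_x[k] <- gr$x[best]
      out$center_y[k] <- gr$y[best]
    } else {
      starts <- rbind(prev_center, c(0, 0),
                      sweep(restart_offsets, 2L, prev_center, `+`))
      best_val <- -Inf; best_par <- prev_center
      for (s in seq_len(nrow(starts))) {
        op <- stats::optim(starts[s, ], f, method = "Nelder-Mead",
                           control = list(fnscale = -1, reltol = 1e-10,
                                          maxit = 500L))
        if (op$value > best_val) { best_val <- op$value; best_par <- op$par }
      }
      out$radius[k] <- best_val
      out$center_x[k] <- best_par[1]
      out$center_y[k] <- best_par[2]
      prev_center <- best_par
    }
  }
  out$classification <- classify_radius(out$radius)
  attr(out, "include_side_chains") <- include_side_chains
  out
}

#' Trajectory-averaged pore radius profile
#'
#' Per-z mean and population standard deviation of the inscribed-sphere
#' radius over frames; slices missing in a frame are excluded from that z's
#' statistics, and a z missing in every frame stays missing.
#'
#' @param traj a [pore_trajectory()] with at least 2 frames.
#' @param z_grid axial grid (A).
#' @param include_side_chains see [radius_profile()].
#' @param frames frame indices to use (default all).
#' @param ... passed to [radius_profile()].
#' @return tibble `z`, `radius_mean`, `radius_sd`, `n_frames`,
#'   `classification` (of the mean radius).
#' @export
average_radius_profile <- function(traj, z_grid = NULL,
                                   include_side_chains = TRUE,
                                   frames = NULL, ...) {
  stopifnot(inherits(traj, "pore_trajectory"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) < 2L)
    stop("averaging a radius profile needs at least 2 frames")
  if (is.null(z_grid)) {
    zr <- range(frame_coords(traj, frames[1])[, 3])
    z_grid <- seq(zr[1], zr[2], by = 0.5)
  }
  acc <- vapply(frames, function(f) {
    radius_profile(traj, z_grid = z_grid,
                   include_side_chains = include_side_chains,
                   frame = f, ...)$radius
  }, numeric(length(z_grid)))
  acc <- matrix(acc, nrow = length(z_grid))
  m <- apply(acc, 1L, function(v) mean(v, na.rm = TRUE))
  pop_sd <- apply(acc, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  })
  n_ok <- apply(acc, 1L, function(v) sum(!is.na(v)))
  m[n_ok == 0L] <- NA_real_
  out <- tibble(z = z_grid, radius_mean = m, radius_sd = pop_sd,
                n_frames = n_ok,
                classification = classify_radius(m))
  attr(out, "include_side_chains") <- include_side_chains
  out
}
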