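# Selection-based RMSD with Kabsch superposition, block-average error
# analysis, and targeted-MD schedule / bias-energy utilities.

#' Resolve a named RMSD selection preset
#'
#' `all_backbone` = backbone atoms {N, CA, C, O} of every helix;
#' `tm4_backbone` = backbone of TM4a/TM4b/TM4ext; `pore_helix_backbone` =
#' backbone of TM1. "Backbone" deliberately excludes CB.
#'
#' @param atoms atom tibble.
#' @param topology a [channel_topology()].
#' @param preset one of `"all_backbone"`, `"tm4_backbone"`,
#'   `"pore_helix_backbone"`.
#' @return integer atom indices.
#' @export
rmsd_selection <- function(atoms, topology,
                           preset = c("all_backbone", "tm4_backbone",
                                      "pore_helix_backbone")) {
  preset <- match.arg(preset)
  helices <- switch(preset,
    all_backbone = names(topology$helix_ranges),
    tm4_backbone = c("TM4a", "TM4b", "TM4ext"),
    pore_helix_backbone = "TM1")
  select_atoms(atoms, topology, helix = helices, name = c("N", "CA", "C", "O"))
}

#' RMSD time series with selection-based superposition
#'
#' Per frame: an optimal least-squares (Kabsch) superposition of the frame
#' onto the reference using `align_sel`, then the RMSD evaluated over
#' `measure_sel`. Superposition and measurement selections may differ (e.g.
#' align on all backbone, measure on the TM4 helices only).
#'
#' @param traj a [pore_trajectory()].
#' @param reference a [channel_structure()] with the same atoms, or a frame
#'   index into `traj`.
#' @param align_sel,measure_sel atom index vectors (see [rmsd_selection()]);
#'   `measure_sel` defaults to `align_sel`.
#' @return tibble `frame`, `time_ns`, `rmsd` (A).
#' @export
rmsd_series <- function(traj, reference, align_sel, measure_sel = align_sel) {
  if (is.logical(align_sel)) align_sel <- which(align_sel)
  if (is.logical(measure_sel)) measure_sel <- which(measure_sel)
  if (!length(align_sel) || !length(measure_sel)) stop("empty RMSD selection")
  ref_xyz <- if (inherits(reference, "channel_structure")) reference$xyz
    else frame_coords(traj, reference)
  if (nrow(ref_xyz) != nrow(traj$atoms))
    stop("reference and trajectory atom counts differ")
  ref_vec <- as.numeric(t(ref_xyz))
  xyz_ind <- function(sel) as.integer(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  ai <- xyz_ind(align_sel)
  mi <- xyz_ind(measure_sel)
  nf <- n_frames(traj)
  times <- frame_times(traj)
  r <- vapply(seq_len(nf), function(f) {
    mob <- as.numeric(t(traj$coords[, , f]))
    fitted <- bio3d::fit.xyz(fixed = ref_vec, mobile = mob,
                             fixed.inds = ai, mobile.inds = ai)
    bio3d::rmsd(ref_vec, fitted, a.inds = mi, b.inds = mi, fit = FALSE)
  }, numeric(1))
  tibble(frame = seq_len(nf), time_ns = times, rmsd = r)
}

#' Block-average error analysis of a time series
#'
#' Splits the series into `n_blocks` contiguous equal blocks (any remainder
#' is dropped from the end) and reports the block means and the standard
#' error `sd(block means) / sqrt(n_blocks)`.
#'
#' @param x numeric series (length >= `n_blocks`).
#' @param n_blocks number of blocks (>= 2).
#' @return list with `block_means`, `mean`, `se`, `block_size`, `n_blocks`.
#' @export
block_average <- function(x, n_blocks) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("block averaging needs at least 2 blocks")
  if (length(x) < n_blocks)
    stop("series shorter than the number of blocks (", length(x), " < ",
         n_blocks, ")")
  bs <- length(x) %/% n_blocks
  xm <- matrix(x[seq_len(bs * n_blocks)], nrow = bs)
  bm <- colMeans(xm)
  list(block_means = bm, mean = mean(bm),
       se = stats::sd(bm) / sqrt(n_blocks),
       block_size = bs, n_blocks = n_blocks)
}

#' Targeted-MD schedule
#'
#' The linear target-RMSD schedule of a targeted-MD run: rho(t) decreases
#' linearly from the initial closed-open RMSD to zero over the run, giving a
#' constant drift rate `initial_rmsd / duration`.
#'
#' @param initial_rmsd RMSD between the end states (A, >= 0).
#' @param duration_ns simulation length (ns, > 0).
#' @param k biasing force constant (kcal/(mol A^2)), default 1e5.
#' @param n_atoms number of biased atoms.
#' @return object of class `tmd_schedule`: list with the inputs plus
#'   `drift_rate` (A/ns) and `rho`, a function of time (ns).
#' @export
tmd_schedule <- function(initial_rmsd, duration_ns, k = 1e5, n_atoms = 1L) {
  if (initial_rmsd < 0) stop("initial_rmsd must be >= 0")
  if (duration_ns <= 0) stop("duration_ns must be > 0")
  rho <- function(t) initial_rmsd * pmax(0, 1 - t / duration_ns)
  structure(list(initial_rmsd = initial_rmsd, duration_ns = duration_ns,
                 k = k, n_atoms = as.integer(n_atoms),
                 drift_rate = initial_rmsd / duration_ns, rho = rho),
            class = "tmd_schedule")
}

#' @export
print.tmd_schedule <- function(x, ...) {
  cat("<tmd_schedule> ", x$initial_rmsd, " A over ", x$duration_ns,
      " ns (drift ", signif(x$drift_rate, 3), " A/ns), k = ", x$k,
      " kcal/mol/A^2 on ", x$n_atoms, " atoms\n", sep = "")
  invisible(x)
}

#' Targeted-MD bias energy
#'
#' The harmonic biasing potential on the RMSD,
#' `U = k / (2 N) * (RMSD - rho)^2`, with `k` the force constant and `N` the
#' number of biased atoms (the standard targeted-MD convention; the per-atom
#' division keeps the bias intensive in system size).
#'
#' @param rmsd current RMSD to the target conformation (A).
#' @param rho target RMSD from the schedule (A).
#' @param k force constant (kcal/(mol A^2), > 0).
#' @param n_atoms number of biased atoms (>= 1).
#' @return bias energy in kcal/mol (vectorised over `rmsd`/`rho`).
#' @export
tmd_bias_energy <- function(rmsd, rho, k = 1e5, n_atoms = 1L) {
  if (any(k <= 0)) stop("force constant must be > 0")
  if (any(n_atoms < 1L)) stop("n_atoms must be >= 1")
  (k / (2 * n_atoms)) * (rmsd - rho)^2
}
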