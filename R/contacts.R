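# Residue contact maps and contact-event timing. Two residues are in contact
# when at least `min_atom_pairs` distinct side-chain heavy-atom pairs are
# closer than `cutoff` (defaults 2 pairs, 5.0 A). "Distinct pairs" counts
# atom pairs, not atoms: one atom may participate in both qualifying pairs
# (the permissive reading of the pair criterion). Event times are extracted
# from flicker-suppressed presence series and averaged across the six
# symmetry-related subunits by the consensus rule (>= 3 subunits).

# Cell-list neighbour pairs: returns a 2-column matrix of atom-index pairs
# (i < j) with distance < cutoff. Complexity ~linear in atoms for bounded
# density; validated against the all-pairs route in tests.
grid_close_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  # pad the cell coordinates so +-1 offsets can never alias across an edge
  cell <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / cutoff) + 1L
  dims <- apply(cell, 2L, max) + 2L
  key <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
  by_cell <- split(seq_len(n), key)
  keys <- as.numeric(names(by_cell))
  keymap <- new.env(hash = TRUE, size = length(keys))
  for (k in seq_along(keys)) assign(as.character(keys[k]), k, envir = keymap)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off_key <- offsets[, 1] + dims[1] * (offsets[, 2] + dims[2] * offsets[, 3])
  acc_i <- list(); acc_j <- list(); nacc <- 0L
  cut2 <- cutoff^2
  for (k in seq_along(keys)) {
    ii <- by_cell[[k]]
    nb <- integer(0)
    for (ok in off_key) {
      hit <- get0(as.character(keys[k] + ok), envir = keymap)
      if (!is.null(hit)) nb <- c(nb, by_cell[[hit]])
    }
    nb <- unique(nb)
    # keep each unordered pair once: j strictly greater than i
    for (i in ii) {
      jj <- nb[nb > i]
      if (!length(jj)) next
      d2 <- (xyz[jj, 1] - xyz[i, 1])^2 + (xyz[jj, 2] - xyz[i, 2])^2 +
        (xyz[jj, 3] - xyz[i, 3])^2
      hit <- jj[d2 < cut2]
      if (length(hit)) {
        nacc <- nacc + 1L
        acc_i[[nacc]] <- rep.int(i, length(hit))
        acc_j[[nacc]] <- hit
      }
    }
  }
  if (!nacc) return(matrix(integer(0), 0L, 2L))
  cbind(unlist(acc_i), unlist(acc_j))
}

brute_close_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  d2 <- as.matrix(stats::dist(xyz))^2
  hit <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
  cbind(hit[, 1], hit[, 2])
}

#' Residue contact map of one frame
#'
#' @param structure a [channel_structure()] or a trajectory plus `frame`.
#' @param cutoff heavy-atom distance cutoff (A), default 5.0.
#' @param min_atom_pairs minimal number of qualifying side-chain heavy-atom
#'   pairs (default 2).
#' @param subset optional atom indices restricting the analysis (e.g. two
#'   helices of interest); side-chain heavy atoms are selected within it.
#' @param method `"grid"` (cell list) or `"brute"` (all pairs; the oracle).
#' @param frame frame index for trajectories.
#' @return tibble of unordered residue pairs in contact: `chain_i`,
#'   `resid_i`, `chain_j`, `resid_j`, `n_pairs`, canonically ordered.
#' @export
contact_map <- function(structure, cutoff = 5.0, min_atom_pairs = 2L,
                        subset = NULL, method = c("grid", "brute"),
                        frame = 1L) {
  stopifnot(cutoff > 0, min_atom_pairs >= 1L)
  method <- match.arg(method)
  xyz <- if (inherits(structure, "pore_trajectory"))
    frame_coords(structure, frame) else structure$xyz
  atoms <- structure$atoms
  keep <- atoms$is_sidechain_heavy
  if (!is.null(subset)) {
    if (is.logical(subset)) subset <- which(subset)
    keep <- keep & seq_len(nrow(atoms)) %in% subset
  }
  idx <- which(keep)
  if (length(idx) < 2L)
    return(tibble(chain_i = character(0), resid_i = integer(0),
                  chain_j = character(0), resid_j = integer(0),
                  n_pairs = integer(0)))
  pr <- if (method == "grid") grid_close_pairs(xyz[idx, , drop = FALSE], cutoff)
        else brute_close_pairs(xyz[idx, , drop = FALSE], cutoff)
  if (!nrow(pr))
    return(tibble(chain_i = character(0), resid_i = integer(0),
                  chain_j = character(0), resid_j = integer(0),
                  n_pairs = integer(0)))
  ai <- idx[pr[, 1]]; aj <- idx[pr[, 2]]
  ri <- atoms$resid[ai]; rj <- atoms$resid[aj]
  ci <- atoms$chain[ai]; cj <- atoms$chain[aj]
  same <- ri == rj & ci == cj
  ai <- ai[!same]; aj <- aj[!same]
  ri <- ri[!same]; rj <- rj[!same]; ci <- ci[!same]; cj <- cj[!same]
  if (!length(ri))
    return(tibble(chain_i = character(0), resid_i = integer(0),
                  chain_j = character(0), resid_j = integer(0),
                  n_pairs = integer(0)))
  # canonical residue-pair key (chain, then resid)
  swap <- (cj < ci) | (cj == ci & rj < ri)
  tmp_c <- ci[swap]; ci[swap] <- cj[swap]; cj[swap] <- tmp_c
  tmp_r <- ri[swap]; ri[swap] <- rj[swap]; rj[swap] <- tmp_r
  tibble(chain_i = ci, resid_i = ri, chain_j = cj, resid_j = rj) |>
    dplyr::count(.data$chain_i, .data$resid_i, .data$chain_j, .data$resid_j,
                 name = "n_pairs") |>
    dplyr::filter(.data$n_pairs >= min_atom_pairs) |>
    dplyr::arrange(.data$chain_i, .data$resid_i, .data$chain_j, .data$resid_j)
}

# Flicker suppression: runs shorter than `persistence` are absorbed into the
# preceding state (the leading run is absorbed into the following one).
smooth_presence <- function(x, persistence) {
  if (persistence <= 1L || length(x) < 2L) return(x)
  repeat {
    r <- rle(x)
    if (length(r$lengths) < 2L) return(inverse.rle(r))
    short <- which(r$lengths < persistence)
    if (!length(short)) return(inverse.rle(r))
    k <- short[1L]
    r$values[k] <- if (k == 1L) r$values[2L] else r$values[k - 1L]
    x <- inverse.rle(r)
  }
}

classify_pair <- function(chain_i, chain_j, topology) {
  if (chain_i == chain_j) return("intra")
  subs <- topology$subunits
  i <- match(chain_i, subs); j <- match(chain_j, subs)
  if (is.na(i) || is.na(j)) return("other")
  d <- (j - i) %% 6L
  if (d == 1L || d == 5L) "inter_n_nplus1" else "other"
}

helix_of <- function(resid, topology) {
  for (h in names(topology$helix_ranges)) {
    r <- topology$helix_ranges[[h]]
    if (resid >= r[1] && resid <= r[2]) return(h)
  }
  NA_character_
}

#' Contact formation / breakdown events along a trajectory
#'
#' Builds the per-frame contact map, smooths each residue pair's presence
#' series by requiring state changes to persist at least `persistence`
#' frames, and reports: pairs present at the start and absent at the end as
#' `broken` at the last present-to-absent transition; pairs absent at the
#' start and present at the end as `formed` at the last absent-to-present
#' transition; pairs present throughout as `stable`.
#'
#' @param traj a [pore_trajectory()].
#' @param topology a [channel_topology()] (for the intra/inter class).
#' @param cutoff,min_atom_pairs,subset,method see [contact_map()].
#' @param persistence minimal run length (frames) for a state to count.
#' @param frames frame indices to analyse (default all).
#' @return tibble: `chain_i`, `resid_i`, `helix_i`, `chain_j`, `resid_j`,
#'   `helix_j`, `kind` (`formed`/`broken`/`stable`), `class`, `tau_frame`,
#'   `tau_ns` (NA for stable pairs).
#' @export
contact_events <- function(traj, topology, cutoff = 5.0, min_atom_pairs = 2L,
                           persistence = 5L, subset = NULL,
                           method = c("grid", "brute"), frames = NULL) {
  stopifnot(persistence >= 1L)
  method <- match.arg(method)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nf <- length(frames)
  maps <- lapply(frames, function(f)
    contact_map(traj, cutoff = cutoff, min_atom_pairs = min_atom_pairs,
                subset = subset, method = method, frame = f))
  keys <- unique(dplyr::bind_rows(
    lapply(maps, function(m) m[c("chain_i", "resid_i", "chain_j", "resid_j")])))
  if (!nrow(keys))
    return(tibble(chain_i = character(0), resid_i = integer(0),
                  helix_i = character(0), chain_j = character(0),
                  resid_j = integer(0), helix_j = character(0),
                  kind = character(0), class = character(0),
                  tau_frame = integer(0), tau_ns = numeric(0)))
  key_str <- function(m) paste(m$chain_i, m$resid_i, m$chain_j, m$resid_j)
  all_keys <- key_str(keys)
  pres <- matrix(FALSE, nrow(keys), nf)
  for (f in seq_len(nf)) {
    if (nrow(maps[[f]]))
      pres[match(key_str(maps[[f]]), all_keys), f] <- TRUE
  }
  times <- frame_times(traj)
  rows <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    s <- smooth_presence(pres[k, ], persistence)
    first <- s[1L]; last <- s[nf]
    if (first && last && all(s)) { kind <- "stable"; tau <- NA_integer_ }
    else if (first && !last) {
      kind <- "broken"
      tau <- max(which(diff(s) == -1L)) + 1L  # first frame of the final absence
    } else if (!first && last) {
      kind <- "formed"
      tau <- max(which(diff(s) == 1L)) + 1L
    } else next  # transient or absent-throughout: no event
    rows[[k]] <- tibble(
      chain_i = keys$chain_i[k], resid_i = keys$resid_i[k],
      helix_i = helix_of(keys$resid_i[k], topology),
      chain_j = keys$chain_j[k], resid_j = keys$resid_j[k],
      helix_j = helix_of(keys$resid_j[k], topology),
      kind = kind,
      class = classify_pair(keys$chain_i[k], keys$chain_j[k], topology),
      tau_frame = if (is.na(tau)) NA_integer_ else frames[tau],
      tau_ns = if (is.na(tau)) NA_real_ else times[frames[tau]])
  }
  dplyr::bind_rows(rows)
}

#' Six-fold consensus contact events
#'
#' Groups formation/breakdown events across the six symmetry-related copies
#' by (residue-id pair, kind, class): for inter-subunit pairs the residue
#' pair is oriented along the ring (first residue on subunit n, second on
#' n + 1). Groups supported by at least `min_subunits` subunits are emitted
#' with the arithmetic mean of the member event times; pairs between
#' non-adjacent subunits are discarded with a warning.
#'
#' @param events output of [contact_events()].
#' @param topology a [channel_topology()].
#' @param min_subunits consensus threshold, between 1 and 6 (default 3).
#' @return tibble `resid_i`, `helix_i`, `resid_j`, `helix_j`, `kind`,
#'   `class`, `tau_ns`, `n_subunits`.
#' @export
consensus_events <- function(events, topology, min_subunits = 3L) {
  stopifnot(min_subunits >= 1L, min_subunits <= 6L)
  ev <- dplyr::filter(events, .data$kind %in% c("formed", "broken"))
  if (!nrow(ev))
    return(tibble(resid_i = integer(0), helix_i = character(0),
                  resid_j = integer(0), helix_j = character(0),
                  kind = character(0), class = character(0),
                  tau_ns = numeric(0), n_subunits = integer(0)))
  other <- ev$class == "other"
  if (any(other)) {
    warning(sum(other), " event(s) between non-adjacent subunits discarded",
            call. = FALSE)
    ev <- ev[!other, , drop = FALSE]
  }
  if (!nrow(ev))
    return(tibble(resid_i = integer(0), helix_i = character(0),
                  resid_j = integer(0), helix_j = character(0),
                  kind = character(0), class = character(0),
                  tau_ns = numeric(0), n_subunits = integer(0)))
  subs <- topology$subunits
  # orient inter pairs along the ring: first residue on subunit n, second on n+1
  ii <- match(ev$chain_i, subs); jj <- match(ev$chain_j, subs)
  flip <- ev$class == "inter_n_nplus1" & ((ii - jj) %% 6L == 1L)
  tmp <- ev$resid_i[flip]; ev$resid_i[flip] <- ev$resid_j[flip]
  ev$resid_j[flip] <- tmp
  tmp <- ev$helix_i[flip]; ev$helix_i[flip] <- ev$helix_j[flip]
  ev$helix_j[flip] <- tmp
  tmp <- ev$chain_i[flip]; ev$chain_i[flip] <- ev$chain_j[flip]
  ev$chain_j[flip] <- tmp
  # intra pairs: canonical residue order
  swap <- ev$class == "intra" & ev$resid_j < ev$resid_i
  tmp <- ev$resid_i[swap]; ev$resid_i[swap] <- ev$resid_j[swap]
  ev$resid_j[swap] <- tmp
  tmp <- ev$helix_i[swap]; ev$helix_i[swap] <- ev$helix_j[swap]
  ev$helix_j[swap] <- tmp
  dplyr::summarise(
    ev, tau_ns = mean(.data$tau_ns),
    n_subunits = dplyr::n_distinct(.data$chain_i),
    .by = c("resid_i", "helix_i", "resid_j", "helix_j", "kind", "class")) |>
    dplyr::filter(.data$n_subunits >= min_subunits) |>
    dplyr::arrange(.data$tau_ns)
}
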