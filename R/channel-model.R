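#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Bondi-style van der Waals radii (Angstrom). Elements missing from the table
# fall back to `default` with a warning; the table can be overridden by the
# `vdw_table` argument of the readers.
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, "NA" = 2.27, K = 2.75,
  MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.40
)

.backbone_names <- c("N", "CA", "C", "O", "OT1", "OT2", "OXT")

vdw_lookup <- function(element, vdw_table = .vdw_table, default = 1.70) {
  key <- toupper(element)
  r <- unname(vdw_table[key])
  bad <- is.na(r)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(key[bad]), collapse = ", "),
            "; using default vdW radius ", default, " A", call. = FALSE)
    r[bad] <- default
  }
  r
}

guess_element <- function(name, resname = NULL) {
  # PDB convention: element is the first letter of the atom name unless the
  # name starts with a digit (e.g. "1HB"). Waters and two-letter ions are
  # handled by the explicit table above through their first letter.
  nm <- toupper(sub("^[0-9]+", "", name))
  substr(nm, 1L, 1L)
}

water_resnames <- c("HOH", "TIP3", "TIP", "SOL", "WAT", "SPC")

#' Build the atom metadata table
#'
#' Classifies atoms into backbone ({N, CA, C, O} plus terminal oxygens),
#' side-chain heavy atoms (everything else that is not hydrogen and belongs to
#' a protein residue), and assigns van der Waals radii from an embedded
#' Bondi-style element table. Hydrogens are never side-chain heavy.
#'
#' @param serial integer atom serial numbers.
#' @param name atom name strings (PDB convention).
#' @param resname 3-letter residue codes.
#' @param resid integer residue ids (PDB numbering).
#' @param chain chain (subunit) labels.
#' @param element optional element symbols; guessed from `name` when `NULL`.
#' @param vdw_table named vector of vdW radii by element symbol.
#' @return a tibble with one row per atom: `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `is_backbone`, `is_sidechain_heavy`,
#'   `vdw_radius`.
#' @export
atom_table <- function(serial, name, resname, resid, chain,
                       element = NULL, vdw_table = .vdw_table) {
  if (is.null(element)) element <- guess_element(name, resname)
  is_h <- toupper(element) == "H"
  is_water <- toupper(resname) %in% water_resnames
  is_bb <- !is_water & toupper(name) %in% .backbone_names & !is_h
  is_sch <- !is_water & !is_bb & !is_h
  tibble(
    serial = as.integer(serial),
    name = as.character(name),
    element = toupper(as.character(element)),
    resname = toupper(as.character(resname)),
    resid = as.integer(resid),
    chain = as.character(chain),
    is_backbone = is_bb,
    is_sidechain_heavy = is_sch,
    vdw_radius = vdw_lookup(element, vdw_table)
  )
}

#' Read a channel structure from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] that returns the package's atom
#' metadata table plus a coordinate matrix in Angstrom.
#'
#' @param path path to a readable PDB file.
#' @param vdw_table optional named vdW radius table overriding the default.
#' @return an object of class `channel_structure`: a list with `atoms` (tibble,
#'   see [atom_table()]) and `xyz` (n_atoms x 3 matrix, Angstrom).
#' @export
read_channel_pdb <- function(path, vdw_table = .vdw_table) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) elem <- NULL
  else elem[is.na(elem) | elem == ""] <- guess_element(a$elety[is.na(elem) | elem == ""])
  atoms <- atom_table(a$eleno, a$elety, a$resid, a$resno, a$chain,
                      element = elem, vdw_table = vdw_table)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  channel_structure(atoms, xyz)
}

#' @rdname read_channel_pdb
#' @param atoms an atom tibble.
#' @param xyz an n x 3 coordinate matrix (Angstrom).
#' @export
channel_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == nrow(atoms))
  structure(list(atoms = atoms, xyz = xyz), class = "channel_structure")
}

#' @export
print.channel_structure <- function(x, ...) {
  cat("<channel_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chains\n", sep = "")
  invisible(x)
}

#' Trajectory container
#'
#' Frames of coordinates bound to atom metadata. Coordinates are stored as a
#' `n_atoms x 3 x n_frames` array in Angstrom.
#'
#' @param atoms atom tibble (see [atom_table()]).
#' @param coords `n_atoms x 3 x n_frames` array, or an `n_atoms x 3` matrix for
#'   a single frame.
#' @param frame_interval time between stored frames in ns (> 0).
#' @return an object of class `pore_trajectory`.
#' @export
pore_trajectory <- function(atoms, coords, frame_interval = 0.1) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(atoms))
    stop("atom count mismatch: trajectory has ", dim(coords)[1],
         " atoms, metadata has ", nrow(atoms))
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0 (ns)")
  structure(list(atoms = atoms, coords = coords,
                 frame_interval = frame_interval),
            class = "pore_trajectory")
}

#' @rdname pore_trajectory
#' @param x a `pore_trajectory`.
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' @rdname pore_trajectory
#' @param i frame index (1-based).
#' @export
frame_coords <- function(x, i) {
  stopifnot(i >= 1L, i <= n_frames(x))
  x$coords[, , i]
}

#' @rdname pore_trajectory
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1L) * x$frame_interval

#' @export
print.pore_trajectory <- function(x, ...) {
  cat("<pore_trajectory> ", nrow(x$atoms), " atoms x ", n_frames(x),
      " frames (dt = ", x$frame_interval, " ns)\n", sep = "")
  invisible(x)
}

#' Load a coordinate trajectory
#'
#' Reads a DCD trajectory (via [bio3d::read.dcd()]) or a multi-model PDB and
#' binds it to an existing atom table. The atom count of the file must match
#' the metadata exactly.
#'
#' @param path path to a DCD or multi-model PDB file.
#' @param atoms atom tibble describing the trajectory atoms, in file order.
#' @param frame_interval time per frame (ns).
#' @param format `"dcd"`, `"pdb"`, or `"auto"` (by file extension).
#' @return a [pore_trajectory()].
#' @export
load_trajectory <- function(path, atoms, frame_interval = 0.1,
                            format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "dcd") "dcd" else if (ext %in% c("pdb", "ent")) "pdb"
      else stop("cannot infer trajectory format from extension '.", ext,
                "'; supported formats are DCD and multi-model PDB")
  }
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
  }
  nat <- ncol(xyz) / 3L
  if (nat != nrow(atoms))
    stop("atom count mismatch: file has ", nat, " atoms, metadata has ",
         nrow(atoms))
  nfr <- nrow(xyz)
  coords <- array(0, dim = c(nat, 3L, nfr))
  for (f in seq_len(nfr)) coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  pore_trajectory(atoms, coords, frame_interval)
}
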