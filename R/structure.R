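#' Construct a structure object
#'
#' The in-memory representation of a (single-model) protein structure:
#' an ordered atom table with chain/residue/atom identity and Angstrom
#' coordinates. Invariants enforced: finite coordinates, unique
#' (chain, residue, atom name) keys, and at least one heavy atom per
#' residue.
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{res_num}, \code{res_name}, \code{chain_id},
#'   \code{x}, \code{y}, \code{z}. A logical \code{is_hydrogen} column is
#'   derived from \code{element} if absent.
#' @param title optional title string.
#' @param source optional source file path.
#' @return An object of class \code{"gj_structure"}.
#' @export
gj_structure <- function(atoms, title = "", source = NA_character_) {
  req <- c("serial", "name", "element", "res_num", "res_name", "chain_id",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_num <- as.integer(atoms$res_num)
  atoms$element <- toupper(as.character(atoms$element))
  atoms$is_hydrogen <- atoms$element == "H"
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz)))
    stop("non-finite coordinates in atom table", call. = FALSE)
  key <- paste(atoms$chain_id, atoms$res_num, atoms$name, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicate atom key(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  rk <- paste(atoms$chain_id, atoms$res_num, sep = "/")
  heavy_per_res <- tapply(!atoms$is_hydrogen, rk, any)
  if (any(!heavy_per_res))
    stop("residue(s) with no heavy atom: ",
         paste(names(heavy_per_res)[!heavy_per_res], collapse = ", "),
         call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title, source = source),
            class = "gj_structure")
}

#' @export
print.gj_structure <- function(x, ...) {
  a <- x$atoms
  cat("<gj_structure> ", nrow(a), " atoms, ",
      length(unique(a$chain_id)), " chain(s) [",
      paste(sort(unique(a$chain_id)), collapse = ""), "], ",
      length(unique(paste(a$chain_id, a$res_num))), " residues",
      if (nzchar(x$title)) paste0("\n  ", x$title) else "", "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a \code{\link{gj_structure}}.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinate matrix of a structure
#' @param structure a \code{\link{gj_structure}}.
#' @return Numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure a \code{\link{gj_structure}}.
#' @param xyz n x 3 matrix.
#' @return The modified structure.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == n_atoms(structure), ncol(xyz) == 3L)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Select atoms by chain, residue and atom identity
#'
#' Clause-based atom selection in the spirit of \code{bio3d::atom.select}:
#' each supplied clause restricts the selection, clauses combine with AND,
#' and the result keeps the original atom order. An empty selection is
#' valid and returns a zero-row structure.
#'
#' @param structure a \code{\link{gj_structure}}.
#' @param chain chain letters to keep.
#' @param resno residue numbers to keep (vector; build ranges with
#'   \code{seq} or \code{\link{expand_ranges}}).
#' @param resid 3-letter residue names to keep.
#' @param elety atom names to keep (e.g. \code{"SG"}).
#' @param element element symbols to keep.
#' @param heavy if \code{TRUE}, drop hydrogens.
#' @param value \code{"structure"} (default) returns a subsetted
#'   \code{gj_structure}; \code{"indices"} returns integer row indices.
#' @return Subsetted structure or indices, in topology order.
#' @export
#' @examples
#' # all EL1 heavy atoms of chain A:
#' # select_atoms(s, chain = "A", resno = 47:73, heavy = TRUE)
select_atoms <- function(structure, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, element = NULL, heavy = FALSE,
                         value = c("structure", "indices")) {
  value <- match.arg(value)
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  chk <- function(x, test, type, clause) {
    if (!is.null(x) && !test(x))
      stop("malformed selection clause '", clause, "': expected ", type,
           call. = FALSE)
    x
  }
  if (!is.null(chk(chain, is.character, "character", "chain"))) keep <- keep & a$chain_id %in% chain
  if (!is.null(chk(resno, is.numeric, "numeric", "resno"))) keep <- keep & a$res_num %in% as.integer(resno)
  if (!is.null(chk(resid, is.character, "character", "resid"))) keep <- keep & a$res_name %in% resid
  if (!is.null(chk(elety, is.character, "character", "elety"))) keep <- keep & a$name %in% elety
  if (!is.null(chk(element, is.character, "character", "element"))) keep <- keep & a$element %in% toupper(element)
  if (!is.logical(heavy) || length(heavy) != 1L)
    stop("malformed selection clause 'heavy': expected single logical", call. = FALSE)
  if (heavy) keep <- keep & !a$is_hydrogen
  idx <- which(keep)
  if (value == "indices") return(idx)
  out <- structure
  out$atoms <- a[idx, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Split a structure into per-residue atom tables
#'
#' @param structure a \code{\link{gj_structure}}.
#' @param heavy keep heavy atoms only.
#' @return Named list of atom data.frames, names "chain/res_num", in
#'   (chain, res_num) order.
#' @keywords internal
.residue_split <- function(structure, heavy = TRUE) {
  a <- structure$atoms
  if (heavy) a <- a[!a$is_hydrogen, , drop = FALSE]
  key <- paste(a$chain_id, a$res_num, sep = "/")
  sp <- split(a, key)
  ord <- order(vapply(sp, function(d) d$chain_id[1], ""),
               vapply(sp, function(d) d$res_num[1], 1L))
  sp[ord]
}

#' Construct a trajectory object
#'
#' A trajectory is a fixed topology plus an ordered stack of coordinate
#' sets. Frame coordinates are stored bio3d-style as an
#' \code{n_frames x (3 n_atoms)} matrix. Frame i carries time
#' \code{i * frame_interval_ps}.
#'
#' @param topology a \code{\link{gj_structure}} (coordinates of frame 1).
#' @param xyz numeric matrix, one row per frame, \code{3 * n_atoms} columns
#'   in x1,y1,z1,x2,... order.
#' @param frame_interval_ps positive frame spacing in picoseconds.
#' @return An object of class \code{"gj_trajectory"}.
#' @export
gj_trajectory <- function(topology, xyz, frame_interval_ps = 10) {
  if (!inherits(topology, "gj_structure"))
    stop("topology must be a gj_structure", call. = FALSE)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("xyz has ", ncol(xyz), " columns; topology implies ",
         3L * n_atoms(topology), call. = FALSE)
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0)
    stop("frame_interval_ps must be > 0", call. = FALSE)
  structure(list(topology = topology, xyz = xyz,
                 frame_interval_ps = frame_interval_ps),
            class = "gj_trajectory")
}

#' @export
print.gj_trajectory <- function(x, ...) {
  cat("<gj_trajectory> ", n_frames(x), " frames x ", n_atoms(x$topology),
      " atoms, dt = ", x$frame_interval_ps, " ps (",
      n_frames(x) * x$frame_interval_ps / 1000, " ns)\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a \code{\link{gj_trajectory}}.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

#' Frame times in picoseconds
#' @param trajectory a \code{\link{gj_trajectory}}.
#' @return Numeric vector, frame i at \code{i * frame_interval_ps}.
#' @export
frame_times <- function(trajectory) {
  seq_len(n_frames(trajectory)) * trajectory$frame_interval_ps
}

#' Extract one frame of a trajectory as a structure
#' @param trajectory a \code{\link{gj_trajectory}}.
#' @param i frame index (1-based).
#' @return A \code{\link{gj_structure}} with that frame's coordinates.
#' @export
frame_structure <- function(trajectory, i) {
  if (i < 1L || i > n_frames(trajectory))
    stop("frame index ", i, " out of range 1..", n_frames(trajectory),
         call. = FALSE)
  xyz <- matrix(trajectory$xyz[i, ], ncol = 3L, byrow = TRUE)
  set_coords(trajectory$topology, xyz)
}

#' Frame coordinates as an n x 3 matrix
#' @inheritParams frame_structure
#' @return Numeric n_atoms x 3 matrix.
#' @export
frame_coords <- function(trajectory, i) {
  matrix(trajectory$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element columns (77-78) of a PDB record are empty.
#' Leading digits are ignored; names beginning with H map to hydrogen;
#' otherwise the first letter is taken.
#'
#' @param name character vector of atom names.
#' @return Character vector of element symbols.
#' @export
infer_element <- function(name) {
  core <- sub("^[0-9]+", "", trimws(name))
  ifelse(substr(core, 1, 1) == "H", "H", substr(core, 1, 1))
}
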