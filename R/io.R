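#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records with PDB v3 fixed-column conventions
#' (via \code{bio3d::read.pdb}). The element is taken from columns 77-78
#' when present and inferred from the atom name otherwise. Hydrogens are
#' read and preserved; two of the hydrogen-bond detectors require them.
#' For multi-MODEL files only the first model is returned, with a notice
#' (use \code{\link{read_trajectory}} for all models). Alternate
#' locations beyond the first encountered are dropped.
#'
#' @param path PDB file path.
#' @return A \code{\link{gj_structure}}.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  multi <- .has_models(path)
  if (multi)
    message("'", basename(path), "' contains MODEL records; returning the ",
            "first model (use read_trajectory() for all frames)")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  .atoms_from_bio3d(at, path)
}

.has_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sum(startsWith(lines, "MODEL")) > 1L
}

.atoms_from_bio3d <- function(at, path) {
  # altlocs: keep the first conformer of each (chain, res, atom) key;
  # a repeated key not explained by a distinct altloc letter is an error
  key <- paste(at$chain, at$resno, at$elety, sep = "/")
  dup <- duplicated(key)
  if (any(dup)) {
    first_alt <- at$alt[match(key, key)]
    distinct_alt <- !is.na(at$alt) & !is.na(first_alt) & at$alt != first_alt
    hard <- dup & !distinct_alt
    if (any(hard))
      stop("duplicate atom key(s) in '", path, "': ",
           paste(unique(key[hard]), collapse = ", "), call. = FALSE)
    at <- at[!dup, , drop = FALSE]
  }
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- infer_element(at$elety[bad])
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = toupper(trimws(elem)),
    res_num = at$resno, res_name = at$resid, chain_id = chain,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  gj_structure(atoms, source = path)
}

#' Read a multi-MODEL PDB trajectory
#'
#' All MODEL blocks must contain the same number of coordinate records in
#' the same atom order; the first offending model is named otherwise.
#' A file without MODEL records yields a single-frame trajectory.
#'
#' @param path multi-MODEL PDB file.
#' @param frame_interval_ps declared frame spacing in ps (default 10, the
#'   usual MD export interval here).
#' @return A \code{\link{gj_trajectory}}; frame i is at time
#'   \code{i * frame_interval_ps}.
#' @export
read_trajectory <- function(path, frame_interval_ps = 10) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  starts <- which(startsWith(lines, "MODEL"))
  if (length(starts) >= 1L) {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records in '", path, "'", call. = FALSE)
    counts <- vapply(seq_along(starts), function(i)
      sum(is_atom[starts[i]:ends[i]]), 0L)
    bad <- which(counts != counts[1])
    if (length(bad))
      stop("model ", bad[1], " of '", path, "' has ", counts[bad[1]],
           " atoms; model 1 has ", counts[1], call. = FALSE)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  topo <- .atoms_from_bio3d(pdb$atom, path)
  xyz <- unclass(pdb$xyz)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  gj_trajectory(topo, xyz, frame_interval_ps)
}

# hybrid-36 encoding of atom serials wider than 99999 (uppercase range only)
.h36_serial <- function(serial) {
  enc1 <- function(n) {
    if (n <= 99999L) return(formatC(n, width = 5))
    v <- n - 100000L + 10L * 36L^4L
    digs <- character(5)
    alphabet <- c(0:9, LETTERS)
    for (i in 5:1) { digs[i] <- alphabet[v %% 36L + 1L]; v <- v %/% 36L }
    paste(digs, collapse = "")
  }
  vapply(serial, enc1, "")
}

.format_atom_lines <- function(atoms, xyz, serial_overflow = "hybrid36") {
  n <- nrow(atoms)
  serial <- seq_len(n)
  if (n > 99999L && serial_overflow == "error")
    stop("structure has ", n, " atoms; serial field overflows ",
         "(set serial_overflow = \"hybrid36\")", call. = FALSE)
  name <- ifelse(nchar(atoms$name) >= 4L, substr(atoms$name, 1, 4),
                 sprintf(" %-3s", atoms$name))
  sprintf("ATOM  %5s %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          .h36_serial(serial), name, atoms$res_name, atoms$chain_id,
          atoms$res_num, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          substr(atoms$element, 1, 2))
}

#' Write a structure to a PDB file
#'
#' Atom serial numbers are reassigned sequentially. Structures beyond
#' 99,999 atoms either switch the serial field to hybrid-36 encoding or
#' raise an error, per \code{serial_overflow}.
#'
#' @param structure a \code{\link{gj_structure}} (non-empty).
#' @param path output file path.
#' @param serial_overflow \code{"hybrid36"} (default) or \code{"error"}.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(structure, path,
                            serial_overflow = c("hybrid36", "error")) {
  serial_overflow <- match.arg(serial_overflow)
  if (n_atoms(structure) == 0L) stop("refusing to write an empty structure",
                                     call. = FALSE)
  lines <- .format_atom_lines(structure$atoms, coords(structure),
                              serial_overflow)
  con <- file(path, "wb")  # fixed newline convention for byte-identical output
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' Each frame becomes one MODEL/ENDMDL block; serials restart at 1 in
#' every model.
#'
#' @param trajectory a \code{\link{gj_trajectory}}.
#' @param path output file path.
#' @inheritParams write_structure
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path,
                             serial_overflow = c("hybrid36", "error")) {
  serial_overflow <- match.arg(serial_overflow)
  atoms <- trajectory$topology$atoms
  na <- nrow(atoms)
  nf <- n_frames(trajectory)
  if (na == 0L) stop("refusing to write an empty trajectory", call. = FALSE)
  # one vectorised sprintf pass over all frames
  big <- atoms[rep(seq_len(na), nf), , drop = FALSE]
  xyz_all <- matrix(t(trajectory$xyz), ncol = 3L, byrow = TRUE)
  atom_lines <- .format_atom_lines(big, xyz_all, serial_overflow)
  blocks <- split(atom_lines, rep(seq_len(nf), each = na))
  out <- vector("list", nf)
  for (i in seq_len(nf))
    out[[i]] <- c(sprintf("MODEL     %4d", i), blocks[[i]], "ENDMDL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(unlist(out), "END"), con)
  invisible(path)
}
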