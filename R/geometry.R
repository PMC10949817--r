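#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two ordered point sets of equal size. Reflections are excluded by
#' sign-correcting the smallest singular value, so the returned rotation
#' always has determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, in
#'   one-to-one correspondence by row order.
#' @return An object of class \code{"gj_superposition"}: list with
#'   \code{rotation} (3 x 3), \code{translation} (length 3), \code{rmsd}
#'   (Angstrom, after superposition) and \code{n_atoms_used}. The mapping
#'   applied to a row vector x is \code{x \%*\% t(rotation) + translation}.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate sets must be n x 3 matrices", call. = FALSE)
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(reference),
         call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for a superposition", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  # degenerate (collinear or coincident) sets leave the rotation underdetermined
  if (svd(P, nu = 0, nv = 0)$d[2] < 1e-8 * max(svd(P, nu = 0, nv = 0)$d[1], 1e-12) ||
      svd(Q, nu = 0, nv = 0)$d[2] < 1e-8 * max(svd(Q, nu = 0, nv = 0)$d[1], 1e-12))
    stop("degenerate (collinear) point set; superposition is undetermined",
         call. = FALSE)
  A <- crossprod(P, Q)           # 3x3 covariance
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  trans <- as.numeric(cr - cm %*% t(R))
  structure(list(rotation = R, translation = trans, rmsd = rmsd,
                 n_atoms_used = n),
            class = "gj_superposition")
}

#' @export
print.gj_superposition <- function(x, ...) {
  cat("<gj_superposition> rmsd =", format(x$rmsd, digits = 4), "A over",
      x$n_atoms_used, "atoms\n")
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup a \code{\link{kabsch_superpose}} result.
#' @param xyz n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, "+")
}

.rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Extracellular RMSD time series
#'
#' Reproduces the standard membrane-protein convention for measuring
#' conformational change of the extracellular part: every frame is first
#' aligned to the first frame on the heavy atoms of the transmembrane
#' alignment ranges (default 21-46, 74-93, 156-176, 204-229), then the
#' RMSD of the heavy atoms of the extracellular loops (47-73 and 177-203)
#' is computed against the first frame. Frame 1 is therefore 0 by
#' construction, and any whole-frame rigid motion contributes nothing.
#'
#' @param trajectory a \code{\link{gj_trajectory}}.
#' @param annotation a \code{\link{connexin_annotation}} supplying
#'   \code{align_ranges_rmsd} and the EL1/EL2 ranges.
#' @param chains chains to include (default: all chains in the topology).
#' @return data.frame with columns \code{frame}, \code{time_ps},
#'   \code{rmsd} (Angstrom).
#' @export
extracellular_rmsd_series <- function(trajectory,
                                      annotation = connexin_annotation(),
                                      chains = NULL) {
  topo <- trajectory$topology
  if (is.null(chains)) chains <- sort(unique(topo$atoms$chain_id))
  align_res <- expand_ranges(annotation$align_ranges_rmsd)
  ec_res <- extracellular_residues(annotation)
  present <- unique(topo$atoms$res_num[topo$atoms$chain_id %in% chains])
  missing <- setdiff(c(align_res, ec_res), present)
  if (length(missing))
    stop("residues required for alignment/RMSD are missing: ",
         paste(utils::head(missing, 20), collapse = ", "),
         if (length(missing) > 20) " ..." else "", call. = FALSE)
  align_idx <- select_atoms(topo, chain = chains, resno = align_res,
                            heavy = TRUE, value = "indices")
  ec_idx <- select_atoms(topo, chain = chains, resno = ec_res,
                         heavy = TRUE, value = "indices")
  ref <- frame_coords(trajectory, 1L)
  ref_align <- ref[align_idx, , drop = FALSE]
  ref_ec <- ref[ec_idx, , drop = FALSE]
  nf <- n_frames(trajectory)
  rmsd <- numeric(nf)
  for (i in seq_len(nf)) {
    fc <- frame_coords(trajectory, i)
    sup <- kabsch_superpose(fc[align_idx, , drop = FALSE], ref_align)
    ec <- apply_superposition(sup, fc[ec_idx, , drop = FALSE])
    rmsd[i] <- .rmsd_between(ec, ref_ec)
  }
  data.frame(frame = seq_len(nf), time_ps = frame_times(trajectory),
             rmsd = rmsd)
}

#' Translate whole chains along z
#'
#' Rigidly shifts every atom of the named chains by \code{offset_z}
#' Angstrom along the membrane normal (+z); all other atoms are
#' untouched. This is the "move one hemichannel away" operation used to
#' stage docking at 1, 3 and 5 Angstrom separations.
#'
#' @param structure a \code{\link{gj_structure}}.
#' @param chains chain letters to move (must exist).
#' @param offset_z signed offset in Angstrom.
#' @return The shifted structure.
#' @export
translate_chains <- function(structure, chains, offset_z) {
  have <- unique(structure$atoms$chain_id)
  missing <- setdiff(chains, have)
  if (length(missing))
    stop("chain(s) not in structure: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sel <- structure$atoms$chain_id %in% chains
  structure$atoms$z[sel] <- structure$atoms$z[sel] + offset_z
  structure
}

#' Steric clashes between two chain groups
#'
#' All heavy-atom pairs across the two (disjoint) chain groups closer
#' than \code{cutoff} (strict \code{<}), sorted by increasing distance.
#'
#' @param structure a \code{\link{gj_structure}}.
#' @param group_a,group_b disjoint chain letter vectors.
#' @param cutoff clash distance in Angstrom (default 2.0).
#' @return data.frame with the two atom identities and the distance;
#'   zero rows when there are no clashes.
#' @export
clash_report <- function(structure, group_a, group_b, cutoff = 2.0) {
  if (length(intersect(group_a, group_b)))
    stop("chain groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "), call. = FALSE)
  a <- select_atoms(structure, chain = group_a, heavy = TRUE)$atoms
  b <- select_atoms(structure, chain = group_b, heavy = TRUE)$atoms
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  hits_i <- integer(0); hits_j <- integer(0); hits_d <- numeric(0)
  if (nrow(a) && nrow(b)) {
    chunk <- max(1L, floor(2e6 / max(nrow(b), 1L)))
    for (s in seq(1L, nrow(a), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(a))
      d2 <- outer(rowSums(xa[s:e, , drop = FALSE]^2), rowSums(xb^2), "+") -
        2 * xa[s:e, , drop = FALSE] %*% t(xb)
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        hits_i <- c(hits_i, hit[, 1] + s - 1L)
        hits_j <- c(hits_j, hit[, 2])
        hits_d <- c(hits_d, sqrt(pmax(d2[hit], 0)))
      }
    }
  }
  ord <- order(hits_d)
  data.frame(
    chain_a = a$chain_id[hits_i][ord], res_a = a$res_num[hits_i][ord],
    name_a = a$name[hits_i][ord],
    chain_b = b$chain_id[hits_j][ord], res_b = b$res_num[hits_j][ord],
    name_b = b$name[hits_j][ord],
    distance = hits_d[ord], stringsAsFactors = FALSE)
}

#' Assemble a head-to-head hemichannel pair on a gap-junction template
#'
#' Takes one hexameric hemichannel and a dodecameric gap-junction
#' template (chains A-L) and produces a 12-chain model: one rigid copy of
#' the hemichannel superposed onto template chains A-F, a second rigid
#' copy superposed onto chains G-L. Correspondence is alphabetical (the
#' hemichannel's 1st chain onto A and onto G, and so on), resolved on
#' shared C-alpha atoms; each chain pair must share at least 3. The
#' second copy's chains are relabelled G-L and atom serials continue
#' after the first copy. Clashes across the two copies (< 2 Angstrom)
#' are reported in the build log, not resolved.
#'
#' @param hc a 6-chain \code{\link{gj_structure}}.
#' @param template_gjc a 12-chain template with chains A-L.
#' @param params \code{\link{analysis_parameters}} (clash cutoff, chain sets).
#' @return A 12-chain \code{\link{gj_structure}} with attribute
#'   \code{"build_log"}: list with per-copy alignment RMSDs and the clash
#'   report.
#' @export
build_hc_hc <- function(hc, template_gjc, params = analysis_parameters()) {
  hc_chains <- sort(unique(hc$atoms$chain_id))
  tpl_chains <- sort(unique(template_gjc$atoms$chain_id))
  if (length(hc_chains) != 6L)
    stop("hemichannel must have 6 chains, found ", length(hc_chains),
         call. = FALSE)
  if (length(tpl_chains) != 12L || !setequal(tpl_chains, LETTERS[1:12]))
    stop("template must have 12 chains A-L, found ",
         paste(tpl_chains, collapse = ""), call. = FALSE)

  fit_copy <- function(target_chains) {
    mob <- NULL; ref <- NULL
    for (k in seq_along(hc_chains)) {
      hca <- select_atoms(hc, chain = hc_chains[k], elety = "CA")$atoms
      tca <- select_atoms(template_gjc, chain = target_chains[k],
                          elety = "CA")$atoms
      shared <- intersect(hca$res_num, tca$res_num)
      if (length(shared) < 3L)
        stop("fewer than 3 shared C-alpha atoms between hemichannel chain ",
             hc_chains[k], " and template chain ", target_chains[k],
             call. = FALSE)
      hca <- hca[match(shared, hca$res_num), ]
      tca <- tca[match(shared, tca$res_num), ]
      mob <- rbind(mob, as.matrix(hca[, c("x", "y", "z")]))
      ref <- rbind(ref, as.matrix(tca[, c("x", "y", "z")]))
    }
    kabsch_superpose(mob, ref)
  }
  sup1 <- fit_copy(params$hc1_chains)
  sup2 <- fit_copy(params$hc2_chains)

  copy1 <- set_coords(hc, apply_superposition(sup1, coords(hc)))
  copy2 <- set_coords(hc, apply_superposition(sup2, coords(hc)))
  copy1$atoms$chain_id <- params$hc1_chains[match(copy1$atoms$chain_id, hc_chains)]
  copy2$atoms$chain_id <- params$hc2_chains[match(copy2$atoms$chain_id, hc_chains)]
  atoms <- rbind(copy1$atoms, copy2$atoms)
  atoms$serial <- seq_len(nrow(atoms))  # copy 2 continues after copy 1
  out <- gj_structure(atoms, title = "assembled HC-HC model")
  clashes <- clash_report(out, params$hc1_chains, params$hc2_chains,
                          cutoff = params$clash_cutoff)
  attr(out, "build_log") <- list(
    rmsd_copy1 = sup1$rmsd, rmsd_copy2 = sup2$rmsd,
    n_ca_copy1 = sup1$n_atoms_used, n_ca_copy2 = sup2$n_atoms_used,
    clashes = clashes)
  out
}
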