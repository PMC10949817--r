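# Donor and acceptor atom vocabulary of the docking-interface residues
# (55-58): backbone N plus Asn OD1, Thr OG1, Gln NE2 donate; backbone O
# plus Asn OD1, Thr OG1, Gln OE1 accept. Asn OD1 appears on both lists
# exactly as specified for the analysis, even though an oxygen donor is
# chemically unusual; a note is emitted once per session.
.iface_donor_sel <- function(atoms) {
  atoms$name == "N" |
    (atoms$res_name == "ASN" & atoms$name == "OD1") |
    (atoms$res_name == "THR" & atoms$name == "OG1") |
    (atoms$res_name == "GLN" & atoms$name == "NE2")
}

.iface_acceptor_sel <- function(atoms) {
  atoms$name == "O" |
    (atoms$res_name == "ASN" & atoms$name == "OD1") |
    (atoms$res_name == "THR" & atoms$name == "OG1") |
    (atoms$res_name == "GLN" & atoms$name == "OE1")
}

.od1_donor_note <- local({
  done <- FALSE
  function() {
    if (!done) {
      message("note: Asn OD1 is treated as both donor and acceptor, ",
              "as the interface H-bond definition lists it on both sides")
      done <<- TRUE
    }
  }
})

# Map each hydrogen to its donor heavy atom: nearest heavy atom within the
# attachment cutoff (1.25 A; 1.45 A when that heavy atom is sulfur, since
# the S-H bond at 1.34 A is longer than N-H/O-H bonds). Returns a
# data.frame h_idx / heavy_idx of attached hydrogens (atom-table rows).
.hydrogen_attachment <- function(structure, params = analysis_parameters()) {
  a <- structure$atoms
  h <- which(a$is_hydrogen)
  heavy <- which(!a$is_hydrogen)
  if (!length(h) || !length(heavy))
    return(data.frame(h_idx = integer(), heavy_idx = integer()))
  xh <- as.matrix(a[h, c("x", "y", "z")])
  xv <- as.matrix(a[heavy, c("x", "y", "z")])
  out_h <- integer(0); out_v <- integer(0)
  chunk <- max(1L, floor(2e6 / length(heavy)))
  for (s in seq(1L, length(h), by = chunk)) {
    e <- min(s + chunk - 1L, length(h))
    d2 <- outer(rowSums(xh[s:e, , drop = FALSE]^2), rowSums(xv^2), "+") -
      2 * xh[s:e, , drop = FALSE] %*% t(xv)
    nearest <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), nearest)], 0))
    cut <- ifelse(a$element[heavy[nearest]] == "S",
                  params$h_attach_cutoff_s, params$h_attach_cutoff)
    ok <- dmin <= cut
    out_h <- c(out_h, h[(s:e)[ok]])
    out_v <- c(out_v, heavy[nearest[ok]])
  }
  data.frame(h_idx = out_h, heavy_idx = out_v)
}

.require_hydrogens <- function(structure, what) {
  if (!any(structure$atoms$is_hydrogen))
    stop("no hydrogen atoms in the frame; ", what,
         " requires explicit hydrogens on donor atoms ",
         "(re-export the trajectory with hydrogens)", call. = FALSE)
}

.dist_rows <- function(xyz, i, j) {
  sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
}

.empty_hbonds <- function() {
  data.frame(category = character(), chain_d = character(), res_d = integer(),
             resname_d = character(), donor = character(),
             hydrogen = character(), chain_a = character(), res_a = integer(),
             resname_a = character(), acceptor = character(),
             distance = numeric(), s_heavy_distance = numeric(),
             class = character(), subunit_pair = character(),
             stringsAsFactors = FALSE)
}

.hbond_rows <- function(atoms, di, hi, ai, dist, s_heavy = NA_real_,
                        category, params) {
  cls <- classify_trans_gj(atoms$chain_id[di], atoms$chain_id[ai], params)
  data.frame(
    category = category,
    chain_d = atoms$chain_id[di], res_d = atoms$res_num[di],
    resname_d = atoms$res_name[di], donor = atoms$name[di],
    hydrogen = if (length(hi)) atoms$name[hi] else NA_character_,
    chain_a = atoms$chain_id[ai], res_a = atoms$res_num[ai],
    resname_a = atoms$res_name[ai], acceptor = atoms$name[ai],
    distance = dist, s_heavy_distance = s_heavy,
    class = cls$class, subunit_pair = cls$subunit_pair,
    stringsAsFactors = FALSE)
}

#' Detect trans-gap-junction hydrogen bonds in one frame
#'
#' Hydrogen bonds between the docking-interface residues 55-58 of the
#' two opposing hemichannels: a bond is every (donor hydrogen, acceptor
#' heavy atom) pair closer than 2.5 Angstrom (strict), with the donor
#' taken from backbone N, Asn OD1, Thr OG1 or Gln NE2 and the acceptor
#' from backbone O, Asn OD1, Thr OG1 or Gln OE1, donor and acceptor on
#' chains of different hemichannels. Hydrogens are assigned to donors by
#' the nearest-heavy-atom rule. Same-hemichannel 55-58 bonds can be
#' obtained with \code{restrict}.
#'
#' @param frame a \code{\link{gj_structure}} with explicit hydrogens.
#' @param annotation \code{\link{connexin_annotation}} (interface
#'   residues).
#' @param params \code{\link{analysis_parameters}} (2.5 Angstrom cutoff,
#'   pairing).
#' @param restrict \code{"trans"} (default: cross-hemichannel only),
#'   \code{"intra"} (same hemichannel only) or \code{"all"}.
#' @return data.frame of bonds (zero rows when none), columns as in
#'   \code{\link{detect_cys_cys_hbonds}}.
#' @export
detect_trans_gj_hbonds <- function(frame, annotation = connexin_annotation(),
                                   params = analysis_parameters(),
                                   restrict = c("trans", "intra", "all")) {
  restrict <- match.arg(restrict)
  a <- frame$atoms
  iface <- a$res_num %in% annotation$interface_internal
  don <- which(iface & .iface_donor_sel(a) & !a$is_hydrogen)
  acc <- which(iface & .iface_acceptor_sel(a) & !a$is_hydrogen)
  if (!length(don) || !length(acc)) return(.empty_hbonds())
  .od1_donor_note()
  .require_hydrogens(frame, "trans-GJ H-bond detection")
  att <- .hydrogen_attachment(frame, params)
  att <- att[att$heavy_idx %in% don, , drop = FALSE]
  if (!nrow(att)) return(.empty_hbonds())
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xh <- xyz[att$h_idx, , drop = FALSE]
  xa <- xyz[acc, , drop = FALSE]
  d2 <- outer(rowSums(xh^2), rowSums(xa^2), "+") - 2 * xh %*% t(xa)
  hit <- which(d2 < params$hbond_HA_cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(.empty_hbonds())
  di <- att$heavy_idx[hit[, 1]]; hi <- att$h_idx[hit[, 1]]; ai <- acc[hit[, 2]]
  keep <- di != ai
  hc_d <- .hc_of(a$chain_id[di], params); hc_a <- .hc_of(a$chain_id[ai], params)
  keep <- keep & switch(restrict,
                        trans = hc_d != hc_a,
                        intra = hc_d == hc_a & !is.na(hc_d),
                        all = TRUE)
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) return(.empty_hbonds())
  di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]
  dist <- sqrt(pmax(d2[hit][keep], 0))
  out <- .hbond_rows(a, di, hi, ai, dist, category = "trans_gj",
                     params = params)
  out[order(out$chain_d, out$res_d, out$chain_a, out$res_a, out$distance), ]
}

#' Detect Cys-Cys thiol hydrogen bonds in one frame
#'
#' In the reduced (open disulfide) state each cysteine thiol can donate
#' via its HG1 hydrogen or accept on its SG sulfur. A bond is every
#' (SG of one Cys, HG1 of another Cys) pair closer than 4.3 Angstrom.
#' Oxidized cysteines carry no HG1 and contribute nothing. The HG
#' atom-name synonym is accepted.
#'
#' @param frame a \code{\link{gj_structure}}.
#' @param scope optional data.frame (\code{chain_id}, \code{res_num}) of
#'   Cys residues to consider; default all cysteines.
#' @param params \code{\link{analysis_parameters}} (4.3 Angstrom cutoff).
#' @return data.frame of bonds; the donor columns describe the HG1 side.
#' @export
detect_cys_cys_hbonds <- function(frame, scope = NULL,
                                  params = analysis_parameters()) {
  a <- frame$atoms
  cys <- a$res_name == "CYS"
  if (!is.null(scope)) {
    key <- paste(a$chain_id, a$res_num, sep = "/")
    cys <- cys & key %in% paste(scope$chain_id, scope$res_num, sep = "/")
  }
  sg <- which(cys & a$name == "SG")
  hg <- which(cys & a$name %in% c("HG1", "HG"))
  if (!length(sg) || !length(hg)) return(.empty_hbonds())
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xs <- xyz[sg, , drop = FALSE]; xh <- xyz[hg, , drop = FALSE]
  d2 <- outer(rowSums(xh^2), rowSums(xs^2), "+") - 2 * xh %*% t(xs)
  hit <- which(d2 < params$cys_cys_SH_cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(.empty_hbonds())
  hi <- hg[hit[, 1]]; si <- sg[hit[, 2]]
  # exclude a thiol's own hydrogen
  keep <- !(a$chain_id[hi] == a$chain_id[si] & a$res_num[hi] == a$res_num[si])
  if (!any(keep)) return(.empty_hbonds())
  hi <- hi[keep]; si <- si[keep]
  # donor heavy atom = the SG the hydrogen belongs to
  di <- integer(length(hi))
  for (k in seq_along(hi)) {
    own <- which(a$chain_id == a$chain_id[hi[k]] &
                   a$res_num == a$res_num[hi[k]] & a$name == "SG")
    di[k] <- if (length(own)) own[1] else hi[k]
  }
  dist <- sqrt(pmax(d2[hit][keep], 0))
  out <- .hbond_rows(a, di, hi, si, dist, category = "cys_cys",
                     params = params)
  out$distance <- dist  # S...H distance, the criterion distance
  out[order(out$chain_d, out$res_d, out$chain_a, out$res_a, out$distance), ]
}

#' Detect Cys-interface hydrogen bonds in one frame
#'
#' Bonds between cysteine SG (as donor or acceptor) and the
#' donor/acceptor heavy atoms of the interface residues 55-58. Both
#' criteria must hold: sulfur to heavy-atom distance below 4.1 Angstrom
#' AND donor-hydrogen to acceptor (sulfur or other heavy atom) distance
#' below 3.2 Angstrom.
#'
#' @inheritParams detect_trans_gj_hbonds
#' @return data.frame of bonds; \code{s_heavy_distance} carries the
#'   sulfur/heavy-atom distance, \code{distance} the hydrogen distance.
#' @export
detect_cys_interface_hbonds <- function(frame,
                                        annotation = connexin_annotation(),
                                        params = analysis_parameters()) {
  a <- frame$atoms
  iface <- a$res_num %in% annotation$interface_internal
  x_don <- which(iface & .iface_donor_sel(a) & !a$is_hydrogen)
  x_acc <- which(iface & .iface_acceptor_sel(a) & !a$is_hydrogen)
  sg <- which(a$res_name == "CYS" & a$name == "SG")
  if (!length(sg) || (!length(x_don) && !length(x_acc)))
    return(.empty_hbonds())
  .require_hydrogens(frame, "Cys-interface H-bond detection")
  att <- .hydrogen_attachment(frame, params)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  res <- list()
  s_cut <- params$cys_iface_S_heavy_cutoff
  h_cut <- params$cys_iface_H_cutoff
  # SG as donor: SG-H ... X (any interface donor/acceptor heavy atom)
  sg_h <- att[att$heavy_idx %in% sg, , drop = FALSE]
  x_all <- union(x_don, x_acc)
  if (nrow(sg_h) && length(x_all)) {
    for (k in seq_len(nrow(sg_h))) {
      ds <- .dist_rows(xyz, rep(sg_h$heavy_idx[k], length(x_all)), x_all)
      dh <- .dist_rows(xyz, rep(sg_h$h_idx[k], length(x_all)), x_all)
      ok <- ds < s_cut & dh < h_cut
      if (any(ok))
        res[[length(res) + 1L]] <- .hbond_rows(
          a, rep(sg_h$heavy_idx[k], sum(ok)), rep(sg_h$h_idx[k], sum(ok)),
          x_all[ok], dh[ok], s_heavy = ds[ok],
          category = "cys_interface", params = params)
    }
  }
  # SG as acceptor: X-H ... SG with X an interface donor
  don_h <- att[att$heavy_idx %in% x_don, , drop = FALSE]
  if (nrow(don_h) && length(sg)) {
    for (k in seq_len(nrow(don_h))) {
      ds <- .dist_rows(xyz, rep(don_h$heavy_idx[k], length(sg)), sg)
      dh <- .dist_rows(xyz, rep(don_h$h_idx[k], length(sg)), sg)
      ok <- ds < s_cut & dh < h_cut
      if (any(ok))
        res[[length(res) + 1L]] <- .hbond_rows(
          a, rep(don_h$heavy_idx[k], sum(ok)), rep(don_h$h_idx[k], sum(ok)),
          sg[ok], dh[ok], s_heavy = ds[ok],
          category = "cys_interface", params = params)
    }
  }
  if (!length(res)) return(.empty_hbonds())
  out <- do.call(rbind, res)
  out[order(out$chain_d, out$res_d, out$chain_a, out$res_a, out$distance), ]
}

#' Hydrogen-bond dynamics over a trajectory
#'
#' Applies one of the categorized detectors to every frame and returns
#' the per-frame bond count (optionally restricted to a chain subset, as
#' when a hemichannel model is compared to one hemichannel of a larger
#' model) plus, per residue-pair label, the number of subunit pairs on
#' which that bond is present in each frame.
#'
#' @param trajectory a \code{\link{gj_trajectory}}.
#' @param detector \code{"trans_gj"}, \code{"cys_cys"},
#'   \code{"cys_interface"}, or a function mapping a frame structure to a
#'   bond data.frame.
#' @param chains_counted \code{"all"} or a chain-letter vector; a bond is
#'   counted only when all its participating chains are in the set.
#' @param params,annotation passed to the detectors.
#' @param stride analyse every \code{stride}-th frame.
#' @return List with \code{counts} (frame, time_ps, n_bonds) and
#'   \code{presence} (frame, pair_label, n_subunit_pairs, long format).
#' @export
hbond_timeseries <- function(trajectory, detector, chains_counted = "all",
                             params = analysis_parameters(),
                             annotation = connexin_annotation(),
                             stride = 1L) {
  fn <- if (is.function(detector)) detector else switch(
    match.arg(detector, c("trans_gj", "cys_cys", "cys_interface")),
    trans_gj = function(s) detect_trans_gj_hbonds(s, annotation, params),
    cys_cys = function(s) detect_cys_cys_hbonds(s, params = params),
    cys_interface = function(s) detect_cys_interface_hbonds(s, annotation,
                                                            params))
  frames <- seq(1L, n_frames(trajectory), by = stride)
  counts <- integer(length(frames))
  pres <- list()
  one_letter <- function(res3) {
    out <- suppressWarnings(bio3d::aa321(res3))
    out[is.na(out) | out == "X"] <- "X"
    out
  }
  for (fi in seq_along(frames)) {
    b <- fn(frame_structure(trajectory, frames[fi]))
    if (nrow(b) && !identical(chains_counted, "all"))
      b <- b[b$chain_d %in% chains_counted & b$chain_a %in% chains_counted, ,
             drop = FALSE]
    counts[fi] <- nrow(b)
    if (nrow(b)) {
      lab_d <- paste0(b$res_d, one_letter(b$resname_d))
      lab_a <- paste0(b$res_a, one_letter(b$resname_a))
      lab <- ifelse(lab_d <= lab_a, paste(lab_d, lab_a, sep = "-"),
                    paste(lab_a, lab_d, sep = "-"))
      su <- ifelse(is.na(b$subunit_pair),
                   paste(b$chain_d, b$chain_a, sep = "-"), b$subunit_pair)
      tab <- tapply(su, lab, function(x) length(unique(x)))
      pres[[length(pres) + 1L]] <- data.frame(
        frame = frames[fi], pair_label = names(tab),
        n_subunit_pairs = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  presence <- if (length(pres)) do.call(rbind, pres) else
    data.frame(frame = integer(), pair_label = character(),
               n_subunit_pairs = integer(), stringsAsFactors = FALSE)
  rownames(presence) <- NULL
  list(counts = data.frame(frame = frames,
                           time_ps = frames * trajectory$frame_interval_ps,
                           n_bonds = counts),
       presence = presence)
}

.canonical_cys <- function(params) sort(unlist(params$ss_pairs))

#' Assign the canonical extracellular disulfide state
#'
#' In \code{closed} mode the three canonical intra-subunit EL1-EL2
#' disulfides (54-198, 61-192, 65-187) are recorded for every chain and
#' thiol hydrogens (HG1/HG) on those cysteines are removed, mirroring a
#' disulfide patch. In \code{open} mode no bonds are recorded and every
#' canonical cysteine is guaranteed an HG1 hydrogen, placed 1.34 Angstrom
#' from SG along the CB-to-SG direction when absent.
#'
#' @param structure a \code{\link{gj_structure}} whose chains each carry
#'   the six canonical cysteines.
#' @param params \code{\link{analysis_parameters}} (\code{ss_pairs}).
#' @param mode \code{"closed"} or \code{"open"}.
#' @return List with \code{structure} (modified) and \code{bonds}
#'   (data.frame: chain, res_a, res_b, sg_sg_distance, state).
#' @export
assign_disulfides <- function(structure, params = analysis_parameters(),
                              mode = c("closed", "open")) {
  mode <- match.arg(mode)
  a <- structure$atoms
  chains <- sort(unique(a$chain_id))
  canon <- .canonical_cys(params)
  for (ch in chains) for (r in canon) {
    sel <- a$chain_id == ch & a$res_num == r
    if (!any(sel & a$res_name == "CYS" & a$name == "SG"))
      stop("chain ", ch, " lacks canonical Cys ", r, " (with an SG atom)",
           call. = FALSE)
  }
  sg_at <- function(ch, r) {
    i <- which(a$chain_id == ch & a$res_num == r & a$name == "SG")
    as.numeric(a[i, c("x", "y", "z")])
  }
  if (mode == "closed") {
    bonds <- do.call(rbind, lapply(chains, function(ch) {
      do.call(rbind, lapply(params$ss_pairs, function(pr) {
        d <- sqrt(sum((sg_at(ch, pr[1]) - sg_at(ch, pr[2]))^2))
        data.frame(chain = ch, res_a = pr[1], res_b = pr[2],
                   sg_sg_distance = d, state = "closed",
                   stringsAsFactors = FALSE)
      }))
    }))
    drop <- a$res_name == "CYS" & a$res_num %in% canon &
      a$name %in% c("HG1", "HG")
    structure$atoms <- a[!drop, , drop = FALSE]
    rownames(structure$atoms) <- NULL
  } else {
    add <- list()
    for (ch in chains) for (r in canon) {
      has_h <- any(a$chain_id == ch & a$res_num == r &
                     a$name %in% c("HG1", "HG"))
      if (!has_h) {
        sg <- sg_at(ch, r)
        cb_i <- which(a$chain_id == ch & a$res_num == r & a$name == "CB")
        dir <- if (length(cb_i)) {
          v <- sg - as.numeric(a[cb_i[1], c("x", "y", "z")])
          v / sqrt(sum(v^2))
        } else c(0, 0, 1)  # no CB in a minimal residue: default direction
        h <- sg + 1.34 * dir
        add[[length(add) + 1L]] <- data.frame(
          serial = 0L, name = "HG1", element = "H", res_num = r,
          res_name = "CYS", chain_id = ch, x = h[1], y = h[2], z = h[3],
          is_hydrogen = TRUE, stringsAsFactors = FALSE)
      }
    }
    if (length(add)) {
      atoms <- rbind(a, do.call(rbind, add))
      atoms$serial <- seq_len(nrow(atoms))
      structure <- gj_structure(atoms, title = structure$title,
                                source = structure$source)
    }
    bonds <- data.frame(chain = character(), res_a = integer(),
                        res_b = integer(), sg_sg_distance = numeric(),
                        state = character(), stringsAsFactors = FALSE)
  }
  list(structure = structure, bonds = bonds)
}

#' Detect disulfide bonds geometrically
#'
#' All SG-SG pairs (any chains) at or below the cutoff (default
#' 2.3 Angstrom; a bonded S-S sits near 2.05 Angstrom) are reported as
#' closed disulfides; pairs matching a canonical intra-subunit EL1-EL2
#' pairing are flagged.
#'
#' @param structure a \code{\link{gj_structure}}.
#' @param cutoff SG-SG distance cutoff in Angstrom.
#' @param params \code{\link{analysis_parameters}} (\code{ss_pairs}).
#' @return data.frame: chain_a, res_a, chain_b, res_b, sg_sg_distance,
#'   state, canonical.
#' @export
detect_disulfides <- function(structure,
                              cutoff = analysis_parameters()$ss_bond_SG_SG_cutoff,
                              params = analysis_parameters()) {
  a <- structure$atoms
  sg <- which(a$res_name == "CYS" & a$name == "SG")
  if (length(sg) < 2L)
    return(data.frame(chain_a = character(), res_a = integer(),
                      chain_b = character(), res_b = integer(),
                      sg_sg_distance = numeric(), state = character(),
                      canonical = logical(), stringsAsFactors = FALSE))
  xyz <- as.matrix(a[sg, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(chain_a = character(), res_a = integer(),
                      chain_b = character(), res_b = integer(),
                      sg_sg_distance = numeric(), state = character(),
                      canonical = logical(), stringsAsFactors = FALSE))
  i <- sg[hit[, 1]]; j <- sg[hit[, 2]]
  pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  canon_keys <- vapply(params$ss_pairs, function(p) pair_key(p[1], p[2]), "")
  canonical <- a$chain_id[i] == a$chain_id[j] &
    pair_key(a$res_num[i], a$res_num[j]) %in% canon_keys
  out <- data.frame(chain_a = a$chain_id[i], res_a = a$res_num[i],
                    chain_b = a$chain_id[j], res_b = a$res_num[j],
                    sg_sg_distance = d[hit], state = "closed",
                    canonical = canonical, stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$res_a, out$chain_b, out$res_b), ]
  rownames(out) <- NULL
  out
}
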