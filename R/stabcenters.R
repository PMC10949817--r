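# Residue-level index of a structure: identities, heavy-atom coordinate
# blocks, centroids and bounding radii for fast contact prefiltering.
.residue_index <- function(structure) {
  a <- structure$atoms
  a <- a[!a$is_hydrogen, , drop = FALSE]
  key <- paste(a$chain_id, a$res_num, sep = "/")
  ord <- order(a$chain_id, a$res_num)
  a <- a[ord, , drop = FALSE]; key <- key[ord]
  idx <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  chain <- vapply(idx, function(i) a$chain_id[i[1]], "")
  res_num <- vapply(idx, function(i) a$res_num[i[1]], 1L)
  res_name <- vapply(idx, function(i) a$res_name[i[1]], "")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  first <- vapply(idx, `[`, 1L, 1L)
  count <- lengths(idx)
  cent <- t(vapply(idx, function(i) colMeans(xyz[i, , drop = FALSE]),
                   numeric(3)))
  rad <- vapply(seq_along(idx), function(k) {
    d <- sweep(xyz[idx[[k]], , drop = FALSE], 2, cent[k, ])
    sqrt(max(rowSums(d^2)))
  }, 0)
  list(n = length(idx), chain = chain, res_num = res_num,
       res_name = res_name, idx = idx, first = first, count = count,
       xyz = xyz, names = a$name, element = a$element, cent = cent,
       rad = rad, lookup = stats::setNames(seq_along(idx), names(idx)))
}

# exact contact test / detail between residues i, j of a residue index
.pair_geom <- function(ri, rvdw, i, j) {
  ai <- ri$idx[[i]]; aj <- ri$idx[[j]]
  xi <- ri$xyz[ai, , drop = FALSE]; xj <- ri$xyz[aj, , drop = FALSE]
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
  d <- sqrt(pmax(d2, 0))
  gap <- d - outer(rvdw[ai], rvdw[aj], "+")
  best <- arrayInd(which.min(d), dim(d))
  list(min_gap = min(gap), min_distance = min(d),
       atom_a = ri$names[ai[best[1]]], atom_b = ri$names[aj[best[2]]])
}

# 0/1 contact matrix: centroid prefilter, then exact heavy-atom test on
# surviving pairs. `active` restricts the computation to the residues a
# caller can ever query (scope plus flanks); others stay 0.
.contact_matrix <- function(ri, params, active = NULL) {
  rvdw <- vdw_radius(ri$element, params$vdw_radii)
  tol <- params$sc_vdw_tolerance
  n <- ri$n
  C <- matrix(0L, n, n)
  if (n < 2L) return(C)
  if (is.null(active)) active <- rep(TRUE, n)
  cd <- as.matrix(stats::dist(ri$cent))
  reach <- outer(ri$rad, ri$rad, "+") + 2 * max(rvdw) + tol
  keep <- cd <= reach & upper.tri(cd) & outer(active, active, "&")
  cand <- which(keep, arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (.pair_geom(ri, rvdw, i, j)$min_gap < tol) {
      C[i, j] <- 1L; C[j, i] <- 1L
    }
  }
  C
}

# flanking residue indices (same chain) of residue k
.flanks <- function(ri, k, width) {
  ch <- ri$chain[k]; rn <- ri$res_num[k]
  left <- ri$lookup[paste(ch, (rn - width):(rn - 1L), sep = "/")]
  right <- ri$lookup[paste(ch, (rn + 1L):(rn + width), sep = "/")]
  list(left = unname(left[!is.na(left)]), right = unname(right[!is.na(right)]))
}

# criterion 3 on a precomputed contact matrix. The 9 cross-triplet contacts
# decompose as column sums of C over {l_a, a, r_a} for fixed {l_b, b, r_b},
# so the best l_a and r_a can be maximized independently per (l_b, r_b).
.crit3_fast <- function(C, ka, kb, fa, fb, need) {
  if (!length(fa$left) || !length(fa$right) ||
      !length(fb$left) || !length(fb$right)) return(FALSE)
  for (lb in fb$left) for (rb in fb$right) {
    base <- C[ka, lb] + C[ka, kb] + C[ka, rb]
    best_l <- max(C[fa$left, lb] + C[fa$left, kb] + C[fa$left, rb])
    best_r <- max(C[fa$right, lb] + C[fa$right, kb] + C[fa$right, rb])
    if (base + best_l + best_r >= need) return(TRUE)
  }
  FALSE
}

#' Heavy-atom contact between two residues
#'
#' Two residues are in contact when at least one heavy-atom pair lies
#' closer than the sum of the two van der Waals radii plus the tolerance
#' (default 1.0 Angstrom). Also reports the minimum heavy-atom distance
#' and the atom pair achieving it.
#'
#' @param structure a \code{\link{gj_structure}}.
#' @param chain_a,res_a,chain_b,res_b residue addresses.
#' @param params \code{\link{analysis_parameters}} (radius table and
#'   tolerance).
#' @return List with \code{contact} (logical), \code{min_distance}
#'   (Angstrom), \code{atom_a}, \code{atom_b}.
#' @export
residue_contact <- function(structure, chain_a, res_a, chain_b, res_b,
                            params = analysis_parameters()) {
  ri <- .residue_index(structure)
  k1 <- ri$lookup[paste(chain_a, res_a, sep = "/")]
  k2 <- ri$lookup[paste(chain_b, res_b, sep = "/")]
  if (is.na(k1) || is.na(k2))
    stop("residue not found (or has no heavy atoms)", call. = FALSE)
  rvdw <- vdw_radius(ri$element, params$vdw_radii)
  g <- .pair_geom(ri, rvdw, k1, k2)
  list(contact = g$min_gap < params$sc_vdw_tolerance,
       min_distance = g$min_distance, atom_a = g$atom_a, atom_b = g$atom_b)
}

#' Is a residue pair a stabilization center?
#'
#' Applies the three criteria: (1) at least 10 residues of sequence
#' separation for same-chain pairs (pairs on different chains pass, as
#' sequence separation is undefined across chains); (2) a heavy-atom
#' contact closer than the van der Waals sum plus 1.0 Angstrom; (3) a
#' choice of one residue from each flanking tetrapeptide of each partner
#' whose two triplets realize at least 7 of the 9 cross-triplet
#' contacts. A residue lacking flank residues on one side fails
#' criterion 3.
#'
#' @inheritParams residue_contact
#' @return Logical.
#' @export
is_stabilization_center <- function(structure, chain_a, res_a, chain_b, res_b,
                                    params = analysis_parameters()) {
  ri <- .residue_index(structure)
  ka <- ri$lookup[paste(chain_a, res_a, sep = "/")]
  kb <- ri$lookup[paste(chain_b, res_b, sep = "/")]
  if (is.na(ka) || is.na(kb))
    stop("residue not found (or has no heavy atoms)", call. = FALSE)
  if (ri$chain[ka] == ri$chain[kb] &&
      abs(ri$res_num[ka] - ri$res_num[kb]) < params$sc_min_seq_separation)
    return(FALSE)
  rvdw <- vdw_radius(ri$element, params$vdw_radii)
  tol <- params$sc_vdw_tolerance
  if (.pair_geom(ri, rvdw, ka, kb)$min_gap >= tol) return(FALSE)
  fa <- .flanks(ri, ka, params$sc_flank_width)
  fb <- .flanks(ri, kb, params$sc_flank_width)
  if (!length(fa$left) || !length(fa$right) ||
      !length(fb$left) || !length(fb$right)) return(FALSE)
  # local contact matrix over the two neighbourhoods only
  ta <- c(fa$left, ka, fa$right); tb <- c(fb$left, kb, fb$right)
  nn <- ri$n
  C <- matrix(0L, nn, nn)
  for (u in ta) for (v in tb)
    if (u != v && .pair_geom(ri, rvdw, u, v)$min_gap < tol) {
      C[u, v] <- 1L; C[v, u] <- 1L
    }
  .crit3_fast(C, ka, kb, fa, fb, params$sc_triplet_min_contacts)
}

#' Detect all stabilization centers in one structure (frame)
#'
#' Evaluates the stabilization-center criteria over all unordered
#' residue pairs in scope, annotating each hit with its minimum
#' heavy-atom distance, the atom pair achieving it, and its
#' trans-gap-junction classification.
#'
#' @param structure a \code{\link{gj_structure}}.
#' @param scope residues to pair: \code{NULL} for all, the keyword
#'   \code{"extracellular"} (EL1/EL2 residues of \code{annotation}), or a
#'   data.frame with columns \code{chain_id}, \code{res_num}. Flank
#'   residues outside the scope still participate in criterion 3.
#' @param params \code{\link{analysis_parameters}}.
#' @param annotation \code{\link{connexin_annotation}} (for the
#'   extracellular scope keyword and nothing else).
#' @return data.frame, one row per detected pair: \code{chain_a},
#'   \code{res_a}, \code{name_a}, \code{chain_b}, \code{res_b},
#'   \code{name_b}, \code{min_distance}, \code{atom_a}, \code{atom_b},
#'   \code{class}, \code{subunit_pair}, \code{is_trans_gj}. Pairs are
#'   ordered with \code{(chain_a, res_a) < (chain_b, res_b)}.
#' @export
detect_scs_frame <- function(structure, scope = NULL,
                             params = analysis_parameters(),
                             annotation = connexin_annotation()) {
  ri <- .residue_index(structure)
  rvdw <- vdw_radius(ri$element, params$vdw_radii)
  ks <- .scope_keys(ri, scope, annotation)
  in_scope <- logical(ri$n); in_scope[ks] <- TRUE
  # criterion 3 reaches at most sc_flank_width residues beyond the scope
  active <- in_scope
  if (!all(active)) {
    w <- params$sc_flank_width
    for (k in ks) {
      near <- which(ri$chain == ri$chain[k] &
                      abs(ri$res_num - ri$res_num[k]) <= w)
      active[near] <- TRUE
    }
  }
  C <- .contact_matrix(ri, params, active)
  flank_cache <- vector("list", ri$n)
  get_flanks <- function(k) {
    f <- flank_cache[[k]]
    if (is.null(f)) {
      f <- .flanks(ri, k, params$sc_flank_width)
      flank_cache[[k]] <<- f
    }
    f
  }
  hits <- which(C == 1L & upper.tri(C), arr.ind = TRUE)
  out <- list()
  for (h in seq_len(nrow(hits))) {
    kp <- hits[h, 1L]; kq <- hits[h, 2L]
    if (!in_scope[kp] || !in_scope[kq]) next
    if (ri$chain[kp] == ri$chain[kq] &&
        abs(ri$res_num[kp] - ri$res_num[kq]) < params$sc_min_seq_separation)
      next
    if (!.crit3_fast(C, kp, kq, get_flanks(kp), get_flanks(kq),
                     params$sc_triplet_min_contacts)) next
    g <- .pair_geom(ri, rvdw, kp, kq)
    out[[length(out) + 1L]] <- data.frame(
      chain_a = ri$chain[kp], res_a = ri$res_num[kp],
      name_a = ri$res_name[kp],
      chain_b = ri$chain[kq], res_b = ri$res_num[kq],
      name_b = ri$res_name[kq],
      min_distance = g$min_distance, atom_a = g$atom_a, atom_b = g$atom_b,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    res <- data.frame(chain_a = character(), res_a = integer(),
                      name_a = character(), chain_b = character(),
                      res_b = integer(), name_b = character(),
                      min_distance = numeric(), atom_a = character(),
                      atom_b = character(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    # canonical ordering of the pair members
    swap <- res$chain_a > res$chain_b |
      (res$chain_a == res$chain_b & res$res_a > res$res_b)
    if (any(swap)) {
      tmp <- res[swap, c("chain_a", "res_a", "name_a", "atom_a")]
      res[swap, c("chain_a", "res_a", "name_a", "atom_a")] <-
        res[swap, c("chain_b", "res_b", "name_b", "atom_b")]
      res[swap, c("chain_b", "res_b", "name_b", "atom_b")] <- tmp
    }
    res <- res[order(res$chain_a, res$res_a, res$chain_b, res$res_b), ]
    rownames(res) <- NULL
  }
  cls <- classify_trans_gj(res$chain_a, res$chain_b, params)
  res$class <- cls$class
  res$subunit_pair <- cls$subunit_pair
  res$is_trans_gj <- cls$class == "trans-GJ"
  res
}

.scope_keys <- function(ri, scope, annotation) {
  if (is.null(scope)) return(seq_len(ri$n))
  if (is.character(scope) && length(scope) == 1L) {
    if (scope != "extracellular")
      stop("unknown scope keyword '", scope, "'", call. = FALSE)
    return(which(ri$res_num %in% extracellular_residues(annotation)))
  }
  if (is.data.frame(scope)) {
    keys <- ri$lookup[paste(scope$chain_id, scope$res_num, sep = "/")]
    return(sort(unname(keys[!is.na(keys)])))
  }
  stop("scope must be NULL, \"extracellular\" or a chain_id/res_num data.frame",
       call. = FALSE)
}

#' Classify a residue pair by its chain relationship
#'
#' \code{intra-subunit} when both residues share a chain,
#' \code{inter-subunit-intra-HC} when the chains differ but lie in the
#' same hemichannel, and \code{trans-GJ} when the chains belong to the
#' two opposing hemichannels. Trans-GJ pairs on a canonical docking
#' register (A-J, B-I, C-H, D-G, E-L, F-K) are labelled with that pair;
#' other cross-hemichannel pairs keep their literal chain pair.
#'
#' @param chain_a,chain_b chain letter vectors (recycled to equal length).
#' @param params \code{\link{analysis_parameters}}.
#' @return List of two vectors: \code{class} and \code{subunit_pair}
#'   (NA for non-trans pairs).
#' @export
classify_trans_gj <- function(chain_a, chain_b, params = analysis_parameters()) {
  n <- max(length(chain_a), length(chain_b))
  chain_a <- rep_len(chain_a, n); chain_b <- rep_len(chain_b, n)
  valid <- c(params$hc1_chains, params$hc2_chains)
  bad <- setdiff(unique(c(chain_a, chain_b)), valid)
  if (length(bad))
    stop("unknown chain(s): ", paste(bad, collapse = ", "),
         "; valid chains: ", paste(valid, collapse = ", "), call. = FALSE)
  ha <- .hc_of(chain_a, params); hb <- .hc_of(chain_b, params)
  class <- ifelse(chain_a == chain_b, "intra-subunit",
                  ifelse(ha == hb, "inter-subunit-intra-HC", "trans-GJ"))
  label <- rep(NA_character_, n)
  tr <- which(class == "trans-GJ")
  for (i in tr) {
    c1 <- if (ha[i] == "HC1") chain_a[i] else chain_b[i]
    c2 <- if (ha[i] == "HC1") chain_b[i] else chain_a[i]
    label[i] <- paste(c1, c2, sep = "-")  # HC1 chain first
  }
  list(class = class, subunit_pair = label)
}

#' Stabilization-center dynamics over a trajectory
#'
#' Runs \code{\link{detect_scs_frame}} on every frame and aggregates each
#' residue pair's presence into a stability table: the number of frames
#' in which the pair is a stabilization center, the fraction of the run,
#' and the minimum / maximum / mean (over frames present) of the per-frame
#' minimum heavy-atom distance.
#'
#' @inheritParams detect_scs_frame
#' @param trajectory a \code{\link{gj_trajectory}}.
#' @param stride analyse every \code{stride}-th frame (default 1: all
#'   frames).
#' @return List with \code{stability} (one row per residue-pair instance)
#'   and \code{per_frame} (all per-frame detections with a \code{frame}
#'   column).
#' @export
sc_timeseries <- function(trajectory, scope = NULL,
                          params = analysis_parameters(),
                          annotation = connexin_annotation(), stride = 1L) {
  frames <- seq(1L, n_frames(trajectory), by = stride)
  per <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    s <- frame_structure(trajectory, frames[fi])
    d <- detect_scs_frame(s, scope = scope, params = params,
                          annotation = annotation)
    if (nrow(d)) d$frame <- frames[fi]
    per[[fi]] <- d
  }
  per <- per[vapply(per, nrow, 1L) > 0]
  nf <- length(frames)
  if (!length(per)) {
    stability <- data.frame(chain_a = character(), res_a = integer(),
                            name_a = character(), chain_b = character(),
                            res_b = integer(), name_b = character(),
                            class = character(), subunit_pair = character(),
                            n_frames_present = integer(), fraction = numeric(),
                            d_min = numeric(), d_max = numeric(),
                            d_mean = numeric(), stringsAsFactors = FALSE)
    return(list(stability = stability,
                per_frame = data.frame(), n_frames = nf))
  }
  all <- do.call(rbind, per)
  key <- paste(all$chain_a, all$res_a, all$chain_b, all$res_b, sep = "/")
  sp <- split(all, factor(key, levels = unique(key)))
  stability <- do.call(rbind, lapply(sp, function(d) {
    data.frame(chain_a = d$chain_a[1], res_a = d$res_a[1], name_a = d$name_a[1],
               chain_b = d$chain_b[1], res_b = d$res_b[1], name_b = d$name_b[1],
               class = d$class[1], subunit_pair = d$subunit_pair[1],
               n_frames_present = nrow(d), fraction = nrow(d) / nf,
               d_min = min(d$min_distance), d_max = max(d$min_distance),
               d_mean = mean(d$min_distance), stringsAsFactors = FALSE)
  }))
  stability <- stability[order(stability$chain_a, stability$res_a,
                               stability$chain_b, stability$res_b), ]
  rownames(stability) <- NULL
  list(stability = stability, per_frame = all, n_frames = nf)
}

#' Filter a stability table to reportable extracellular pairs
#'
#' Keeps rows in which at least one residue lies in EL1 (47-73) or EL2
#' (177-203) and whose stability fraction reaches the threshold
#' (default 2\% of the run).
#'
#' @param stability stability table from \code{\link{sc_timeseries}}.
#' @param annotation \code{\link{connexin_annotation}}.
#' @param min_fraction minimum stability fraction (default 0.02).
#' @return The filtered table.
#' @export
filter_extracellular <- function(stability,
                                 annotation = connexin_annotation(),
                                 min_fraction = 0.02) {
  if (!nrow(stability)) return(stability)
  ec <- extracellular_residues(annotation)
  keep <- (stability$res_a %in% ec | stability$res_b %in% ec) &
    stability$fraction >= min_fraction
  out <- stability[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
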