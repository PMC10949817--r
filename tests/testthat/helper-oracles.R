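# Independent brute-force reference implementations used to cross-check the
# package detectors. These share no code with the package internals: plain
# loops over the atom table.

oracle_heavy <- function(s) {
  a <- s$atoms
  a[a$element != "H", , drop = FALSE]
}

oracle_vdw <- function(el) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  r <- tab[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

# residue list of a structure as a data.frame (chain, res)
oracle_residues <- function(s) {
  a <- oracle_heavy(s)
  unique(data.frame(chain = a$chain_id, res = a$res_num,
                    stringsAsFactors = FALSE))
}

# minimum heavy-atom distance and vdW-gap contact between two residues
oracle_pair <- function(s, ca, ra, cb, rb, tol = 1.0) {
  a <- oracle_heavy(s)
  A <- a[a$chain_id == ca & a$res_num == ra, , drop = FALSE]
  B <- a[a$chain_id == cb & a$res_num == rb, , drop = FALSE]
  best_d <- Inf; contact <- FALSE
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
    if (d < best_d) best_d <- d
    if (d < oracle_vdw(A$element[i]) + oracle_vdw(B$element[j]) + tol)
      contact <- TRUE
  }
  list(contact = contact, min_distance = best_d)
}

# full contact matrix over all residues (row/col order of oracle_residues)
oracle_contact_matrix <- function(s, tol = 1.0) {
  rs <- oracle_residues(s)
  n <- nrow(rs)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ct <- oracle_pair(s, rs$chain[i], rs$res[i], rs$chain[j], rs$res[j],
                      tol)$contact
    m[i, j] <- ct; m[j, i] <- ct
  }
  list(residues = rs, m = m)
}

# exhaustive stabilization-center detection: all residue pairs, all 4x4x4x4
# flank-triplet selections, 9 cross-contacts counted per selection
oracle_detect_scs <- function(s, tol = 1.0, min_sep = 10, need = 7) {
  cm <- oracle_contact_matrix(s, tol)
  rs <- cm$residues; m <- cm$m
  idx_of <- function(ch, r) which(rs$chain == ch & rs$res == r)
  flank <- function(i, side) {
    ch <- rs$chain[i]; r <- rs$res[i]
    cand <- if (side == "left") (r - 4):(r - 1) else (r + 1):(r + 4)
    out <- integer(0)
    for (x in cand) { k <- idx_of(ch, x); if (length(k)) out <- c(out, k) }
    out
  }
  best_count <- function(i, j) {
    li <- flank(i, "left"); ri <- flank(i, "right")
    lj <- flank(j, "left"); rj <- flank(j, "right")
    if (!length(li) || !length(ri) || !length(lj) || !length(rj)) return(0L)
    best <- 0L
    for (a in li) for (b in ri) for (cc in lj) for (dd in rj) {
      ta <- c(a, i, b); tb <- c(cc, j, dd)
      cnt <- 0L
      for (u in ta) for (v in tb) if (m[u, v]) cnt <- cnt + 1L
      if (cnt > best) best <- cnt
    }
    best
  }
  hits <- NULL
  n <- nrow(rs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- rs$chain[i] == rs$chain[j]
    if (same && abs(rs$res[i] - rs$res[j]) < min_sep) next
    if (!m[i, j]) next
    if (best_count(i, j) < need) next
    hits <- rbind(hits, data.frame(chain_a = rs$chain[i], res_a = rs$res[i],
                                   chain_b = rs$chain[j], res_b = rs$res[j],
                                   stringsAsFactors = FALSE))
  }
  hits
}

# brute-force cross-group clash enumeration
oracle_clashes <- function(s, ga, gb, cutoff = 2.0) {
  a <- oracle_heavy(s)
  A <- a[a$chain_id %in% ga, , drop = FALSE]
  B <- a[a$chain_id %in% gb, , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
    if (d < cutoff) n <- n + 1L
  }
  n
}

# tiny builder for hand-placed atoms
atom_row <- function(name, el, res, rn, ch, x, y, z) {
  data.frame(serial = 0L, name = name, element = el, res_num = as.integer(res),
             res_name = rn, chain_id = ch, x = x, y = y, z = z,
             is_hydrogen = el == "H", stringsAsFactors = FALSE)
}

mini_structure <- function(...) {
  atoms <- do.call(rbind, list(...))
  atoms$serial <- seq_len(nrow(atoms))
  gj_structure(atoms)
}

sc_pair_key <- function(d) {
  if (is.null(d) || nrow(d) == 0) return(character(0))
  sort(paste(d$chain_a, d$res_a, d$chain_b, d$res_b, sep = "/"))
}
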