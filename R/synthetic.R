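# ---- shared helpers ---------------------------------------------------------

.atom_df <- function(name, element, res_num, res_name, chain_id, xyz) {
  data.frame(serial = 0L, name = name, element = element,
             res_num = as.integer(res_num), res_name = res_name,
             chain_id = chain_id, x = xyz[1], y = xyz[2], z = xyz[3],
             is_hydrogen = element == "H", stringsAsFactors = FALSE)
}

.finish_structure <- function(rows, title) {
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  gj_structure(atoms, title = title)
}

# ---- stabilization-center fixture ------------------------------------------

#' Two-strand fixture with one planted stabilization center
#'
#' Builds a single-chain structure of C-alpha-only glycine strands whose
#' geometry plants exactly one stabilization-center pair and one contact
#' pair that fails the 7-of-9 triplet criterion. Two X-shaped strand
#' crossings are used: in the first the strands cross at an angle tight
#' enough that a triplet around each central residue realizes exactly 7
#' of 9 cross-contacts; in the second the strands cross at 90 degrees,
#' where only 5 of 9 contacts are achievable. With \code{sep < 9} the
#' crossing arms are truncated so the two central residues can sit
#' closer than 9 apart in sequence; the central pair then fails the
#' 10-residue separation criterion.
#'
#' The generator self-verifies its manifest with the package detector
#' before returning.
#'
#' @param sep sequence separation of the planted central pair
#'   (default 12).
#' @param seed retained for interface symmetry; the fixture is fully
#'   deterministic.
#' @param strand_gap closest approach of the two strands in Angstrom.
#' @param spacing intra-strand C-alpha spacing in Angstrom.
#' @param cos_cross cosine of the crossing angle of the SC crossing
#'   (default 0.6, inside the window that yields exactly 7 contacts).
#' @return List with \code{structure} (a \code{\link{gj_structure}}) and
#'   \code{manifest} (planted SC pair, planted non-SC contact pair,
#'   whether the central pair passes the separation criterion).
#' @export
make_sc_fixture <- function(sep = 12L, seed = 1L, strand_gap = 1.5,
                            spacing = 3.4, cos_cross = 0.6) {
  if (cos_cross <= 0.47 || cos_cross >= 1)
    stop("cos_cross outside the feasible window (0.47, 1) for a ",
         "7-of-9 crossing", call. = FALSE)
  rows <- list()
  strand <- function(res_nums, us, origin, dir, zoff) {
    for (k in seq_along(res_nums)) {
      p <- origin + us[k] * spacing * dir + c(0, 0, zoff)
      rows[[length(rows) + 1L]] <<- .atom_df("CA", "C", res_nums[k], "GLY",
                                             "A", p)
    }
  }
  half <- acos(cos_cross) / 2
  e1 <- c(cos(half), sin(half), 0); e2 <- c(cos(half), -sin(half), 0)
  truncated <- sep < 9L
  if (truncated) {
    strand(1:5, -4:0, c(0, 0, 0), e1, 0)
    strand((5L + sep):(9L + sep), 0:4, c(0, 0, 0), e2, strand_gap)
    sc_pair <- c(5L, 5L + sep)
    non_sc <- NULL
  } else {
    strand(1:9, -4:4, c(0, 0, 0), e1, 0)
    strand((sep + 1L):(sep + 9L), -4:4, c(0, 0, 0), e2, strand_gap)
    sc_pair <- c(5L, 5L + sep)
    # 90-degree crossing far away: contact holds, triplet criterion fails
    f1 <- c(cos(pi / 4), sin(pi / 4), 0); f2 <- c(cos(pi / 4), -sin(pi / 4), 0)
    strand(31:39, -4:4, c(60, 0, 0), f1, 0)
    strand(43:51, -4:4, c(60, 0, 0), f2, strand_gap)
    non_sc <- c(35L, 47L)
  }
  s <- .finish_structure(rows, title = "planted SC fixture")
  expect_sc <- sep >= 10L  # criterion 1 needs >= 10 residues of separation
  ok_sc <- is_stabilization_center(s, "A", sc_pair[1], "A", sc_pair[2])
  if (ok_sc != expect_sc)
    stop("generator self-check failed on the planted central pair",
         call. = FALSE)
  if (!is.null(non_sc) &&
      is_stabilization_center(s, "A", non_sc[1], "A", non_sc[2]))
    stop("generator self-check failed: planted non-SC pair detected as SC",
         call. = FALSE)
  manifest <- list(
    planted_sc = if (expect_sc)
      data.frame(chain_a = "A", res_a = sc_pair[1], chain_b = "A",
                 res_b = sc_pair[2], stringsAsFactors = FALSE)
    else NULL,
    central_pair = sc_pair,
    passes_separation = expect_sc,
    planted_non_sc = if (!is.null(non_sc))
      data.frame(chain_a = "A", res_a = non_sc[1], chain_b = "A",
                 res_b = non_sc[2], stringsAsFactors = FALSE)
    else NULL,
    sc_strand_residues = if (truncated) (5L + sep):(9L + sep) else
      (sep + 1L):(sep + 9L),
    seed = seed)
  list(structure = s, manifest = manifest)
}

#' Random compact chain(s) for detector cross-checks
#'
#' C-alpha-only random self-avoiding-ish walks, useful as unstructured
#' input when comparing the stabilization-center detector against an
#' exhaustive reference implementation.
#'
#' @param n_res residues per chain.
#' @param n_chains number of chains (letters from A).
#' @param seed RNG seed.
#' @param step C-alpha step length in Angstrom.
#' @param confine side of the cubic box the walk is folded back into;
#'   smaller boxes produce more long-range contacts.
#' @return A \code{\link{gj_structure}}.
#' @export
make_random_structure <- function(n_res = 25L, n_chains = 1L, seed = 1L,
                                  step = 3.8, confine = 18) {
  .with_seed(seed, function() {
    rows <- list()
    for (ci in seq_len(n_chains)) {
      p <- stats::runif(3, 0, confine)
      for (i in seq_len(n_res)) {
        v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
        p2 <- p + step * v
        # fold back into the box to keep the walk compact
        p2 <- pmin(pmax(p2, 0), confine) +
          (p2 < 0 | p2 > confine) * (p - p2) * 0.5
        p <- p2
        rows[[length(rows) + 1L]] <- .atom_df("CA", "C", i, "GLY",
                                              LETTERS[ci], p)
      }
    }
    .finish_structure(rows, title = "random walk fixture")
  })
}

# ---- toy connexon -----------------------------------------------------------

.toy_res_name <- function(i) {
  switch(as.character(i),
         "54" = , "61" = , "65" = , "187" = , "192" = , "198" = "CYS",
         "55" = "ASN", "56" = "THR", "57" = , "58" = , "195" = "GLN",
         "194" = "HIS", "196" = "VAL", "GLY")
}

.cyl <- function(r, phi_deg, z) {
  phi <- phi_deg * pi / 180
  c(r * cos(phi), r * sin(phi), z)
}

#' Ring-symmetric toy connexon with planted interaction geometry
#'
#' Generates a hexamer (one hemichannel, chains A-F) or a dodecamer (two
#' apposed hemichannels, second ring chains G-L arranged so the docking
#' register is the canonical A-J, B-I, C-H, D-G, E-L, F-K) with
#' connexin-style residue numbering 20-230, minimal residues (backbone
#' N/CA/C/O plus the side-chain atoms the detectors read), and the six
#' conserved cysteines per chain. In the \code{closed} state each
#' canonical EL1-EL2 pair sits at 2.05 Angstrom SG-SG; in the
#' \code{open} state the pairs are separated to 3.5 Angstrom and every
#' cysteine carries an HG1 thiol hydrogen.
#'
#' Optional plants add interaction geometry across the two rings:
#' \describe{
#'   \item{\code{"cys_cys"}}{(open only) one thiol-donor and one
#'     thiol-acceptor geometry per subunit, i.e. two SG/HG1 bonds per
#'     docking pair — a dozen bonds on a dodecamer.}
#'   \item{\code{"trans_gj"}}{one opposing Gln58 NE2-H...OE1 bond at
#'     2.4 Angstrom per docking pair.}
#'   \item{\code{"cys_interface"}}{(open only) per chain, the Cys61
#'     thiol repositioned to 4.0 Angstrom (S-heavy) / 2.66 Angstrom
#'     (H-acceptor) from the backbone O of its own Gln58.}
#'   \item{\code{"trans_sc"}}{per docking pair, residues 55-57 of the
#'     first ring and 194-196 of the second are moved into a tight
#'     X-crossing at the interface so that (56, 195) forms a planted
#'     trans-GJ stabilization center (self-verified at generation).}
#' }
#'
#' @param n_subunits 6 or 12.
#' @param disulfide_state \code{"closed"} or \code{"open"}.
#' @param plants character vector among \code{"cys_cys"},
#'   \code{"trans_gj"}, \code{"cys_interface"}.
#' @param seed retained for interface symmetry; geometry is
#'   deterministic.
#' @param params \code{\link{analysis_parameters}} (pairing and cutoffs
#'   used by the generator's self-checks).
#' @return List with \code{structure} and \code{manifest} (expected
#'   disulfide and bond counts, verified against the package detectors
#'   before returning).
#' @export
make_toy_connexon <- function(n_subunits = 12L,
                              disulfide_state = c("closed", "open"),
                              plants = character(), seed = 1L,
                              params = analysis_parameters()) {
  disulfide_state <- match.arg(disulfide_state)
  if (!n_subunits %in% c(6L, 12L))
    stop("n_subunits must be 6 or 12", call. = FALSE)
  if (length(plants))
    plants <- match.arg(plants,
                        c("cys_cys", "trans_gj", "cys_interface", "trans_sc"),
                        several.ok = TRUE)
  open <- disulfide_state == "open"
  if (!open && any(plants %in% c("cys_cys", "cys_interface")))
    stop("cys_cys and cys_interface plants require the open disulfide state",
         call. = FALSE)
  if (n_subunits == 6L &&
      any(plants %in% c("cys_cys", "trans_gj", "trans_sc")))
    stop("cross-ring plants require a dodecamer (n_subunits = 12)",
         call. = FALSE)

  ann <- connexin_annotation()
  el <- extracellular_residues(ann)
  ring2_chains <- unname(params$subunit_pairing[params$hc1_chains])
  chains1 <- params$hc1_chains
  sectors <- stats::setNames((seq_len(6L) - 1L) * 60, chains1)

  dist_to_el <- function(i) {
    if (i %in% el) return(0)
    min(abs(i - c(ann$el1_range, ann$el2_range)))
  }
  res_z <- function(i, sign) {
    d <- dist_to_el(i)
    if (d == 0) sign * (6 + 0.8 * sin(i)) else sign * (8 + 0.25 * d)
  }
  res_phi <- function(i, phi0) phi0 + 5 + 40 * (i - 20) / 210

  rows <- list()
  add <- function(name, element, res, resname, chain, xyz)
    rows[[length(rows) + 1L]] <<- .atom_df(name, element, res, resname,
                                           chain, xyz)

  build_chain <- function(chain, phi0, sign) {
    for (i in 20:230) {
      rn <- .toy_res_name(i)
      phi <- res_phi(i, phi0)
      r <- 23 + 0.3 * cos(i * 2.3)
      p <- .cyl(r, phi, res_z(i, sign))
      rad <- pi / 180 * phi
      tang <- c(-sin(rad), cos(rad), 0); radial <- c(cos(rad), sin(rad), 0)
      add("N", "N", i, rn, chain, p - 1.2 * tang)
      add("CA", "C", i, rn, chain, p)
      add("C", "C", i, rn, chain, p + 1.2 * tang)
      add("O", "O", i, rn, chain, p + 1.2 * tang + 1.23 * radial)
      if (rn == "ASN") add("OD1", "O", i, rn, chain, p + 1.5 * radial)
      if (rn == "THR") add("OG1", "O", i, rn, chain, p + 1.5 * radial)
      if (rn == "GLN") {
        add("NE2", "N", i, rn, chain, p + 1.5 * radial + 0.5 * tang)
        add("OE1", "O", i, rn, chain, p + 1.5 * radial - 0.5 * tang)
      }
    }
    # cysteine side chains: canonical pairs on radial axes at dedicated slots
    d_ss <- if (open) 3.5 else 2.05
    for (k in 1:3) {
      pr <- params$ss_pairs[[k]]
      phi_k <- phi0 + 24 + (k - 1) * 14
      rad <- pi / 180 * phi_k
      radial <- c(cos(rad), sin(rad), 0)
      m <- .cyl(28, phi_k, sign * 6)
      sg_a <- m - (d_ss / 2) * radial   # EL1 cysteine, inner
      sg_b <- m + (d_ss / 2) * radial   # EL2 cysteine, outer
      add("CB", "C", pr[1], "CYS", chain, sg_a + 1.81 * radial)
      add("SG", "S", pr[1], "CYS", chain, sg_a)
      add("CB", "C", pr[2], "CYS", chain, sg_b - 1.81 * radial)
      add("SG", "S", pr[2], "CYS", chain, sg_b)
      if (open) {
        add("HG1", "H", pr[1], "CYS", chain, sg_a - 1.34 * radial)
        add("HG1", "H", pr[2], "CYS", chain, sg_b + 1.34 * radial)
      }
    }
  }

  for (ch in chains1) build_chain(ch, sectors[[ch]], -1)
  if (n_subunits == 12L)
    for (ch in chains1) build_chain(params$subunit_pairing[[ch]],
                                    sectors[[ch]], +1)

  s <- .finish_structure(rows, title = sprintf(
    "toy connexon (%d subunits, %s disulfides)", n_subunits, disulfide_state))

  move_atom <- function(s, chain, res, name, xyz) {
    i <- which(s$atoms$chain_id == chain & s$atoms$res_num == res &
                 s$atoms$name == name)
    if (length(i) != 1L) stop("internal: atom ", chain, "/", res, "/", name)
    s$atoms[i, c("x", "y", "z")] <- as.list(xyz)
    s
  }
  add_atom <- function(s, chain, res, resname, name, element, xyz) {
    row <- .atom_df(name, element, res, resname, chain, xyz)
    row$serial <- nrow(s$atoms) + 1L
    s$atoms <- rbind(s$atoms, row)
    s
  }

  n_pairs <- if (n_subunits == 12L) 6L else 0L
  if (length(plants)) {
    for (ch in chains1) {
      phi0 <- sectors[[ch]]
      ch2 <- if (n_subunits == 12L) params$subunit_pairing[[ch]] else NULL
      if ("cys_cys" %in% plants) {
        # donor geometry on ring 1 (Cys65), acceptor on its Cys65 partner;
        # mirrored donor/acceptor via the Cys187 pair
        p65 <- .cyl(28, phi0 + 45, -2); p65b <- .cyl(28, phi0 + 45, +2)
        p187 <- .cyl(28, phi0 + 55, -2); p187b <- .cyl(28, phi0 + 55, +2)
        rad <- pi / 180 * (phi0 + 45); radial45 <- c(cos(rad), sin(rad), 0)
        rad <- pi / 180 * (phi0 + 55); radial55 <- c(cos(rad), sin(rad), 0)
        s <- move_atom(s, ch, 65L, "SG", p65)
        s <- move_atom(s, ch, 65L, "CB", p65 + 1.81 * radial45)
        s <- move_atom(s, ch, 65L, "HG1", p65 + c(0, 0, 1.34))
        s <- move_atom(s, ch2, 65L, "SG", p65b)
        s <- move_atom(s, ch2, 65L, "CB", p65b + 1.81 * radial45)
        s <- move_atom(s, ch2, 65L, "HG1", p65b + c(0, 0, 1.34))
        s <- move_atom(s, ch, 187L, "SG", p187)
        s <- move_atom(s, ch, 187L, "CB", p187 + 1.81 * radial55)
        s <- move_atom(s, ch, 187L, "HG1", p187 - c(0, 0, 1.34))
        s <- move_atom(s, ch2, 187L, "SG", p187b)
        s <- move_atom(s, ch2, 187L, "CB", p187b + 1.81 * radial55)
        s <- move_atom(s, ch2, 187L, "HG1", p187b - c(0, 0, 1.34))
      }
      if ("trans_gj" %in% plants) {
        q <- .cyl(24.5, phi0 + 30, 0)
        s <- move_atom(s, ch, 58L, "NE2", q + c(0, 0, -1.5))
        s <- add_atom(s, ch, 58L, "GLN", "HE21", "H", q + c(0, 0, -0.5))
        s <- move_atom(s, ch2, 58L, "OE1", q + c(0, 0, 1.9))
      }
      if ("trans_sc" %in% plants) {
        # X-crossing of the interface triplets, same geometry that makes the
        # two-strand fixture realize exactly 7 of 9 cross-contacts
        half <- acos(0.6) / 2
        rr <- pi / 180 * (phi0 + 18)
        tang <- c(-sin(rr), cos(rr), 0); radial <- c(cos(rr), sin(rr), 0)
        e1 <- cos(half) * tang + sin(half) * radial
        e2 <- cos(half) * tang - sin(half) * radial
        cen <- .cyl(26, phi0 + 18, 0)
        move_res <- function(s, chn, res, target_ca) {
          i <- which(s$atoms$chain_id == chn & s$atoms$res_num == res)
          ca <- which(s$atoms$chain_id == chn & s$atoms$res_num == res &
                        s$atoms$name == "CA")
          delta <- target_ca - as.numeric(s$atoms[ca, c("x", "y", "z")])
          s$atoms[i, c("x", "y", "z")] <-
            sweep(as.matrix(s$atoms[i, c("x", "y", "z")]), 2, delta, "+")
          s
        }
        for (k in -1:1)
          s <- move_res(s, ch, 56L + k, cen + k * 3.8 * e1 + c(0, 0, -1))
        for (k in -1:1)
          s <- move_res(s, ch2, 195L + k, cen + k * 3.8 * e2 + c(0, 0, 1))
      }
      if ("cys_interface" %in% plants) {
        plant_chain <- function(s, chn) {
          o_i <- which(s$atoms$chain_id == chn & s$atoms$res_num == 58L &
                         s$atoms$name == "O")
          o <- as.numeric(s$atoms[o_i, c("x", "y", "z")])
          rad <- atan2(o[2], o[1])
          sgn <- if (o[3] < 0) -1 else 1
          # tilt outward and away from the interface plane, clear of the
          # canonical SG slots
          u <- c(cos(rad), sin(rad), 0.8 * sgn)
          u <- u / sqrt(sum(u^2))
          sg <- o + 4.0 * u
          s <- move_atom(s, chn, 61L, "SG", sg)
          s <- move_atom(s, chn, 61L, "CB", sg + 1.81 * u)
          move_atom(s, chn, 61L, "HG1", sg - 1.34 * u)
        }
        s <- plant_chain(s, ch)
        if (!is.null(ch2)) s <- plant_chain(s, ch2)
      }
    }
  }

  expected <- list(
    n_disulfides = if (open) 0L else 3L * n_subunits,
    n_cys_cys_hbonds = if ("cys_cys" %in% plants) 2L * n_pairs else 0L,
    n_trans_gj_hbonds = if ("trans_gj" %in% plants) n_pairs else NA_integer_,
    n_trans_sc = if ("trans_sc" %in% plants) n_pairs else 0L)
  planted_trans_sc <- if ("trans_sc" %in% plants)
    data.frame(chain_a = chains1, res_a = 56L,
               chain_b = unname(params$subunit_pairing[chains1]),
               res_b = 195L, stringsAsFactors = FALSE)
  else NULL

  # self-checks against the package detectors
  found_ss <- detect_disulfides(s, params = params)
  if (nrow(found_ss) != expected$n_disulfides ||
      (nrow(found_ss) && !all(found_ss$canonical)))
    stop("generator self-check failed: expected ", expected$n_disulfides,
         " canonical disulfides, found ", nrow(found_ss), call. = FALSE)
  if (open || "cys_cys" %in% plants) {
    ncc <- nrow(detect_cys_cys_hbonds(s, params = params))
    if (ncc != expected$n_cys_cys_hbonds)
      stop("generator self-check failed: expected ",
           expected$n_cys_cys_hbonds, " Cys-Cys H-bonds, found ", ncc,
           call. = FALSE)
  }
  if ("trans_gj" %in% plants) {
    ntg <- nrow(detect_trans_gj_hbonds(s, ann, params))
    if (ntg != expected$n_trans_gj_hbonds)
      stop("generator self-check failed: expected ",
           expected$n_trans_gj_hbonds, " trans-GJ H-bonds, found ", ntg,
           call. = FALSE)
  }
  if (!is.null(planted_trans_sc)) {
    for (r in seq_len(nrow(planted_trans_sc)))
      if (!is_stabilization_center(s, planted_trans_sc$chain_a[r], 56L,
                                   planted_trans_sc$chain_b[r], 195L, params))
        stop("generator self-check failed: planted trans-GJ SC not detected ",
             "on pair ", planted_trans_sc$chain_a[r], "-",
             planted_trans_sc$chain_b[r], call. = FALSE)
  }

  manifest <- list(n_subunits = n_subunits, disulfide_state = disulfide_state,
                   plants = plants, expected = expected,
                   planted_trans_sc = planted_trans_sc, seed = seed)
  list(structure = s, manifest = manifest)
}

# ---- cylinder channel -------------------------------------------------------

#' Cylindrical channel with an analytically known pore profile
#'
#' Stacks rings of atoms along +z. At a slice through ring k the largest
#' in-plane inscribed sphere has radius \code{ring_radii[k] - r_vdw}
#' exactly, which makes the fixture an oracle for the pore profiler.
#'
#' @param ring_radii numeric vector, one ring radius (Angstrom) per
#'   slice, from low to high z.
#' @param spacing axial ring spacing in Angstrom.
#' @param n_per_ring atoms per ring.
#' @param element ring atom element (default carbon).
#' @param z0 z of the first ring.
#' @param params radius table.
#' @return List with \code{structure} and \code{manifest} (ring z
#'   positions and the analytic inscribed radius per ring).
#' @export
make_cylinder_channel <- function(ring_radii, spacing = 2.0,
                                  n_per_ring = 24L, element = "C", z0 = 0,
                                  params = analysis_parameters()) {
  rv <- vdw_radius(element, params$vdw_radii)
  if (any(ring_radii <= rv))
    stop("ring radii must exceed the atom vdW radius (", rv, " A)",
         call. = FALSE)
  rows <- list()
  zs <- z0 + (seq_along(ring_radii) - 1L) * spacing
  for (k in seq_along(ring_radii)) {
    for (j in seq_len(n_per_ring)) {
      ang <- 2 * pi * (j - 1) / n_per_ring
      rows[[length(rows) + 1L]] <- .atom_df(
        paste0(element, j), element, k, "UNK", "A",
        c(ring_radii[k] * cos(ang), ring_radii[k] * sin(ang), zs[k]))
    }
  }
  s <- .finish_structure(rows, title = "cylinder channel fixture")
  list(structure = s,
       manifest = list(z = zs, ring_radius = ring_radii,
                       analytic_radius = ring_radii - rv))
}

# ---- trajectories with scheduled events ------------------------------------

#' Deterministic or Bernoulli on/off schedule
#'
#' @param n_frames number of frames.
#' @param p target on-fraction.
#' @param kind \code{"deterministic"} (the first \code{round(p * n)}
#'   frames are on, so the realized fraction equals \code{p} exactly
#'   when \code{p * n} is integral) or \code{"bernoulli"} (iid draws).
#' @param seed RNG seed for the Bernoulli draw.
#' @return Logical vector of length \code{n_frames}.
#' @export
schedule_onoff <- function(n_frames, p, kind = c("deterministic", "bernoulli"),
                           seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "deterministic") {
    k <- round(p * n_frames)
    c(rep(TRUE, k), rep(FALSE, n_frames - k))
  } else {
    .with_seed(seed, function() stats::runif(n_frames) < p)
  }
}

#' Make/break event for the planted stabilization center of a fixture
#'
#' In "off" frames the partner strand of the planted crossing is rigidly
#' displaced, removing every contact of the planted pair; in "on" frames
#' it sits at its fixture position.
#'
#' @param fixture result of \code{\link{make_sc_fixture}}.
#' @param on logical per-frame vector (see \code{\link{schedule_onoff}}).
#' @param shift displacement applied in off frames (default 25 Angstrom
#'   along z).
#' @return An event list consumable by \code{\link{make_trajectory}}.
#' @export
sc_onoff_event <- function(fixture, on, shift = c(0, 0, 25)) {
  s <- fixture$structure
  idx <- which(s$atoms$res_num %in% fixture$manifest$sc_strand_residues)
  base <- as.matrix(s$atoms[idx, c("x", "y", "z")])
  list(name = "planted_sc", atoms = idx, on = on,
       xyz_on = base, xyz_off = sweep(base, 2, shift, "+"))
}

#' Synthetic trajectory: positional jitter plus scheduled events
#'
#' Emulates an MD recording statistically: every frame is the base
#' structure plus iid isotropic Gaussian jitter, except atoms governed
#' by an event schedule, which are placed exactly at their on- or
#' off-geometry in each frame (no jitter), so the per-frame ground truth
#' in the manifest is exact. This is controlled noise, not physical
#' dynamics.
#'
#' @param base a \code{\link{gj_structure}}.
#' @param n_frames number of frames.
#' @param jitter_sigma Gaussian jitter s.d. per coordinate (Angstrom).
#' @param schedule list of events (see \code{\link{sc_onoff_event}});
#'   each event has \code{atoms}, logical \code{on}, \code{xyz_on},
#'   \code{xyz_off}.
#' @param interval_ps frame spacing in ps (default 10).
#' @param seed RNG seed for the jitter.
#' @return List with \code{trajectory} (a \code{\link{gj_trajectory}})
#'   and \code{manifest} (per-event on-vectors and realized fractions).
#' @export
make_trajectory <- function(base, n_frames, jitter_sigma = 0,
                            schedule = list(), interval_ps = 10, seed = 1L) {
  for (ev in schedule) {
    if (length(ev$on) != n_frames)
      stop("event '", ev$name, "' schedule length ", length(ev$on),
           " != n_frames ", n_frames, call. = FALSE)
    if (max(ev$atoms) > n_atoms(base))
      stop("event '", ev$name, "' references atoms beyond the base structure",
         call. = FALSE)
  }
  na <- n_atoms(base)
  base_vec <- as.numeric(t(coords(base)))
  xyz <- .with_seed(seed, function() {
    m <- matrix(rep(base_vec, each = n_frames), nrow = n_frames)
    if (jitter_sigma > 0)
      m <- m + stats::rnorm(length(m), sd = jitter_sigma)
    m
  })
  for (ev in schedule) {
    cols <- as.vector(rbind(3L * ev$atoms - 2L, 3L * ev$atoms - 1L,
                            3L * ev$atoms))
    on_vec <- as.numeric(t(ev$xyz_on))
    off_vec <- as.numeric(t(ev$xyz_off))
    xyz[ev$on, cols] <- matrix(rep(on_vec, each = sum(ev$on)),
                               nrow = sum(ev$on))
    xyz[!ev$on, cols] <- matrix(rep(off_vec, each = sum(!ev$on)),
                                nrow = sum(!ev$on))
  }
  traj <- gj_trajectory(base, xyz, frame_interval_ps = interval_ps)
  manifest <- list(events = lapply(schedule, function(ev)
    list(name = ev$name, on = ev$on, fraction = mean(ev$on))),
    jitter_sigma = jitter_sigma, seed = seed)
  list(trajectory = traj, manifest = manifest)
}
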