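#' Connexin residue annotation
#'
#' Residue-range bookkeeping for a Cx43-style connexin subunit: the two
#' extracellular loops (EL1, EL2), the transmembrane helix ranges, the
#' alignment ranges used for trajectory superposition, the internal and
#' external docking-interface residues, and the positions of the six
#' conserved extracellular cysteines. All ranges are inclusive, 1-based
#' PDB residue numbers.
#'
#' Two transmembrane sets are kept deliberately: \code{tm_ranges_model} is
#' the membrane-prediction set (20-46, 74-94, 154-176, 205-226) used when
#' describing the model topology, while \code{align_ranges_rmsd}
#' (21-46, 74-93, 156-176, 204-229) is the set used as the alignment base
#' when computing extracellular RMSD series.
#'
#' @param el1_range,el2_range integer length-2 inclusive residue intervals.
#' @param tm_ranges_model,align_ranges_rmsd lists of length-2 intervals.
#' @param interface_internal,interface_external integer residue vectors.
#' @param cys_el1,cys_el2 cysteine residue numbers on EL1 and EL2.
#' @return An object of class \code{"gj_annotation"} (a named list).
#' @export
#' @examples
#' ann <- connexin_annotation()
#' ann$el1_range
connexin_annotation <- function(el1_range = c(47L, 73L),
                                el2_range = c(177L, 203L),
                                tm_ranges_model = list(c(20L, 46L), c(74L, 94L),
                                                       c(154L, 176L), c(205L, 226L)),
                                align_ranges_rmsd = list(c(21L, 46L), c(74L, 93L),
                                                         c(156L, 176L), c(204L, 229L)),
                                interface_internal = 55:58,
                                interface_external = 194:196,
                                cys_el1 = c(54L, 61L, 65L),
                                cys_el2 = c(187L, 192L, 198L)) {
  chk_interval <- function(x, nm) {
    if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
      stop("annotation interval '", nm, "' must be a length-2 increasing interval",
           call. = FALSE)
    as.integer(x)
  }
  ann <- list(
    el1_range = chk_interval(el1_range, "el1_range"),
    el2_range = chk_interval(el2_range, "el2_range"),
    tm_ranges_model = lapply(tm_ranges_model, chk_interval, nm = "tm_ranges_model"),
    align_ranges_rmsd = lapply(align_ranges_rmsd, chk_interval, nm = "align_ranges_rmsd"),
    interface_internal = as.integer(interface_internal),
    interface_external = as.integer(interface_external),
    cys_el1 = as.integer(cys_el1),
    cys_el2 = as.integer(cys_el2)
  )
  class(ann) <- "gj_annotation"
  ann
}

#' Residue numbers of a set of annotation ranges
#'
#' @param ranges a list of inclusive length-2 intervals.
#' @return Integer vector of all residue numbers covered.
#' @keywords internal
expand_ranges <- function(ranges) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  unique(unlist(lapply(ranges, function(r) seq.int(r[1], r[2]))))
}

#' Extracellular residue numbers (EL1 plus EL2)
#'
#' @param annotation a \code{\link{connexin_annotation}} object.
#' @return Integer vector of residue numbers.
#' @export
extracellular_residues <- function(annotation = connexin_annotation()) {
  expand_ranges(list(annotation$el1_range, annotation$el2_range))
}

#' Analysis parameters
#'
#' Single authoritative home of all numeric constants used by the
#' detectors: the stabilization-center criteria (minimum sequence
#' separation, van der Waals tolerance, 7-of-9 triplet contact rule,
#' flank width, 2\% stability threshold), the three hydrogen-bond cutoffs
#' (2.5 Angstrom donor-H/acceptor, 4.3 Angstrom Cys SG/HG1,
#' 4.1 + 3.2 Angstrom Cys-interface pair of criteria), the 2.0 Angstrom
#' clash cutoff, the disulfide SG-SG detection cutoff, the van der Waals
#' radius table, the hexamer-to-hexamer subunit pairing and the three
#' canonical EL1-EL2 cysteine disulfide pairs.
#'
#' Hydrogen-to-donor assignment uses \code{h_attach_cutoff} for N/O
#' donors and \code{h_attach_cutoff_s} for sulfur (the S-H bond at
#' 1.34 Angstrom is longer than an N-H or O-H bond).
#'
#' @param ... named overrides of any default listed below.
#' @return An object of class \code{"gj_params"} (a named list).
#' @export
#' @examples
#' p <- analysis_parameters()
#' p$hbond_HA_cutoff
#' p2 <- analysis_parameters(sc_vdw_tolerance = 1.2)
analysis_parameters <- function(...) {
  p <- list(
    sc_min_seq_separation = 10L,
    sc_vdw_tolerance = 1.0,
    sc_triplet_min_contacts = 7L,
    sc_flank_width = 4L,
    sc_min_stability_fraction = 0.02,
    hbond_HA_cutoff = 2.5,
    cys_cys_SH_cutoff = 4.3,
    cys_iface_S_heavy_cutoff = 4.1,
    cys_iface_H_cutoff = 3.2,
    clash_cutoff = 2.0,
    ss_bond_SG_SG_cutoff = 2.3,
    h_attach_cutoff = 1.25,
    h_attach_cutoff_s = 1.45,
    vdw_radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                  default = 1.70),
    hc1_chains = LETTERS[1:6],
    hc2_chains = LETTERS[7:12],
    subunit_pairing = c(A = "J", B = "I", C = "H", D = "G", E = "L", F = "K"),
    ss_pairs = list(c(54L, 198L), c(61L, 192L), c(65L, 187L)),
    hc_offsets = c(1, 3, 5)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p[names(over)] <- over
  }
  cutoffs <- c("sc_vdw_tolerance", "hbond_HA_cutoff", "cys_cys_SH_cutoff",
               "cys_iface_S_heavy_cutoff", "cys_iface_H_cutoff", "clash_cutoff",
               "ss_bond_SG_SG_cutoff", "h_attach_cutoff", "h_attach_cutoff_s")
  for (nm in cutoffs)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive number", call. = FALSE)
  .check_pairing(p$subunit_pairing, p$hc1_chains, p$hc2_chains)
  class(p) <- "gj_params"
  p
}

.check_pairing <- function(pairing, hc1, hc2) {
  if (!setequal(names(pairing), hc1) || !setequal(unname(pairing), hc2))
    stop("subunit_pairing must map the HC1 chains onto the HC2 chains bijectively",
         call. = FALSE)
  invisible(TRUE)
}

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @param radii named radius table with a \code{default} entry
#'   (see \code{\link{analysis_parameters}}).
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, radii = analysis_parameters()$vdw_radii) {
  r <- radii[toupper(element)]
  r[is.na(r)] <- radii[["default"]]
  unname(r)
}

#' Hemichannel membership and docking partner of a chain
#'
#' Chains A-F form the first hemichannel (HC1), chains G-L the second
#' (HC2); the docking register pairs A-J, B-I, C-H, D-G, E-L and F-K.
#'
#' @param chain_id single chain letter in A-L.
#' @param params \code{\link{analysis_parameters}} carrying the chain sets
#'   and pairing map.
#' @return List with elements \code{hc} ("HC1" or "HC2") and
#'   \code{partner} (the paired chain letter).
#' @export
#' @examples
#' hc_membership("A")  # HC1, partner J
#' hc_membership("K")  # HC2, partner F
hc_membership <- function(chain_id, params = analysis_parameters()) {
  if (length(chain_id) != 1L || !is.character(chain_id))
    stop("chain_id must be a single chain letter", call. = FALSE)
  pairing <- params$subunit_pairing
  if (chain_id %in% params$hc1_chains) {
    list(hc = "HC1", partner = unname(pairing[[chain_id]]))
  } else if (chain_id %in% params$hc2_chains) {
    inv <- names(pairing)[match(chain_id, unname(pairing))]
    list(hc = "HC2", partner = inv)
  } else {
    stop("unknown chain '", chain_id, "'; valid chains: ",
         paste(c(params$hc1_chains, params$hc2_chains), collapse = ", "),
         call. = FALSE)
  }
}

#' Which hemichannel does each chain belong to
#'
#' Vectorised companion of \code{\link{hc_membership}}.
#'
#' @inheritParams hc_membership
#' @return Character vector of "HC1"/"HC2".
#' @keywords internal
.hc_of <- function(chain_id, params) {
  out <- rep(NA_character_, length(chain_id))
  out[chain_id %in% params$hc1_chains] <- "HC1"
  out[chain_id %in% params$hc2_chains] <- "HC2"
  out
}

#' Write analysis parameters to a YAML file
#'
#' @param params a \code{\link{analysis_parameters}} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  p <- unclass(params)
  p$ss_pairs <- lapply(p$ss_pairs, as.integer)
  # named vectors must become YAML maps, not bare sequences
  p$vdw_radii <- as.list(p$vdw_radii)
  p$subunit_pairing <- as.list(p$subunit_pairing)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' Read analysis parameters from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file written by \code{\link{write_parameters}} or
#'   hand-authored with the same field names.
#' @return A \code{\link{analysis_parameters}} object.
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$vdw_radii)) raw$vdw_radii <- unlist(raw$vdw_radii)
  if (!is.null(raw$subunit_pairing)) raw$subunit_pairing <- unlist(raw$subunit_pairing)
  do.call(analysis_parameters, raw)
}
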