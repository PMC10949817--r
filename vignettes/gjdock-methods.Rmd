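---
title: "Geometric analysis of connexin hemichannel docking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric analysis of connexin hemichannel docking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjdock)
```

## The scientific setting

Connexin hemichannels (HCs) are hexamers embedded in one cell's
membrane; two HCs on adjacent cells dock head-to-head to form a
dodecameric gap-junction channel (GJC). The extracellular docking
interface of Cx43 is organized around six conserved cysteines per
subunit (54, 61, 65 on extracellular loop EL1; 187, 192, 198 on EL2)
that form three intra-subunit EL1-EL2 disulfides per subunit — 36 in a
full GJC — and around two short interface motifs, the internal
55N-56T-57Q-58Q stretch and the external 194H-195Q-196V stretch.
Whether those disulfides are closed (oxidized) or open (reduced thiols)
reorganizes the interface: it decides whether residue pairs across the
gap can form stabilization centers and hydrogen bonds, and it correlates
with the channel being functionally open or closed.

`gjdock` post-processes molecular-dynamics trajectories of such
assemblies. It does not run MD; it consumes multi-MODEL PDB exports
(the format MD packages emit frame by frame) and quantifies the docking
interface geometrically.

## The quantities computed

### Stabilization centers

A stabilization center (SC) is a residue pair held by long-range
packing. Two residues form an SC when

1. they are at least 10 residues apart in sequence (pairs on different
   chains pass automatically: sequence separation is undefined across
   chains, and the cross-gap pairs of interest are inter-chain);
2. some heavy-atom pair is closer than the sum of the two van der Waals
   radii plus 1.0 Å;
3. picking one residue from each flanking tetrapeptide of each partner
   (positions $-4..-1$ and $+1..+4$) yields two triplets
   $\{l_a, a, r_a\}$ and $\{l_b, b, r_b\}$ whose $3 \times 3 = 9$
   cross-pairs realize at least 7 contacts, for some choice of flanks.

Criterion 3 deserves a note: the verbal definition ("seven contacts out
of the possible nine ... with the other residue and its four neighbours
in both directions") is ambiguous, because a residue plus four
neighbours on both sides is nine residues, not a source of nine
contacts. Only the triplet reading — one residue chosen from each
flanking tetrapeptide, forming 3x3 cross-pairs — makes "nine possible
contacts" exact, so that is what `is_stabilization_center()` implements.
A residue whose flank on either side is empty (chain terminus) fails
criterion 3; flanks with one to three residues select among what is
present.

Per-frame detections (`detect_scs_frame()`) aggregate over a run into a
stability table (`sc_timeseries()`): the fraction of frames in which a
pair is present, plus the minimum/maximum/mean of its per-frame minimum
heavy-atom distance. Reportable extracellular SCs are those touching
EL1 (47-73) or EL2 (177-203) and present in at least 2% of the run
(`filter_extracellular()`). Pairs are classified intra-subunit,
inter-subunit-intra-HC, or trans-GJ (chains in opposite hemichannels),
with the canonical docking register A-J, B-I, C-H, D-G, E-L, F-K.

### Categorized hydrogen bonds

Three geometric detectors, all distance-based (no angular terms):

* **trans-GJ** (`detect_trans_gj_hbonds()`): between interface residues
  55-58 of opposite hemichannels; donors are backbone N, Asn OD1, Thr
  OG1 and Gln NE2, acceptors backbone O, Asn OD1, Thr OG1 and Gln OE1;
  a bond is a donor-hydrogen/acceptor pair below 2.5 Å (strict).
  Asn OD1 sits on both lists deliberately, matching the analysis
  definition verbatim even though an oxygen donor is chemically
  unusual; a session note flags it.
* **Cys-Cys** (`detect_cys_cys_hbonds()`): thiol-thiol precursors of
  disulfide exchange in the reduced state; every SG/HG1 pair of two
  different cysteines below 4.3 Å. On a docked pair of hexamers each
  subunit can donate once and accept once — a dozen bonds in total —
  which is what the planted-fixture test reproduces.
* **Cys-interface** (`detect_cys_interface_hbonds()`): cysteine SG as
  donor or acceptor against the 55-58 donor/acceptor heavy atoms; both
  the 4.1 Å sulfur/heavy-atom and the 3.2 Å hydrogen criteria must
  hold (the definition joins them with "and").

PDB files carry no bond table, so hydrogens are assigned to donors by
proximity: a hydrogen belongs to its nearest heavy atom within 1.25 Å.
Sulfur is the one exception — an S-H bond is 1.34 Å long, so the
attachment cutoff for sulfur is 1.45 Å; with a uniform 1.25 Å cutoff a
thiol hydrogen placed at the standard bond length would be orphaned.
Detectors that need donor hydrogens raise an error on a frame with no
hydrogens at all, rather than silently reporting zero bonds.

### Disulfide state

`assign_disulfides()` imposes a state the way a structure-preparation
disulfide patch does: closed mode records the three canonical
intra-subunit pairs (54-198, 61-192, 65-187) per chain and strips thiol
hydrogens; open mode records none and guarantees an HG1 on every
canonical cysteine (placed at 1.34 Å from SG opposite CB when absent).
`detect_disulfides()` is the geometric read-out: SG-SG pairs within
2.3 Å. That cutoff is a package choice: a bonded S-S sits near 2.05 Å,
and 2.3 Å gives slack for thermal distortion without reaching
non-bonded sulfur contacts (the open-state fixtures keep unbonded SG
pairs above 3 Å).

### Extracellular RMSD

`extracellular_rmsd_series()` aligns every frame to the first on the
heavy atoms of the transmembrane ranges 21-46, 74-93, 156-176, 204-229
(Kabsch superposition, reflections excluded) and then measures RMSD
over the heavy atoms of EL1+EL2. Alignment on the membrane-anchored
part makes the series blind to rigid-body drift — a whole-frame rotation
reads exactly zero — while extracellular rearrangement reads in Å: an
artificial 1.0 Å shift of every extracellular atom with the TM fixed
yields exactly 1.0. Two transmembrane-range conventions circulate for
this protein family (a membrane-prediction set 20-46/74-94/154-176/
205-226 and the alignment set above); the annotation object carries
both, and only the alignment set drives superposition. Heavy atoms
(not C-alpha only) are used for both alignment and measurement, the
stabler convention when hydrogens may be absent.

### Pore profile

`pore_profile()` computes, for each position $z$ along the channel
axis, the radius of the largest sphere centred in that plane that
touches no heavy-atom van der Waals surface:
$r(z) = \max_{c \in \mathbb{R}^2} \min_a (\lVert (c, z) - x_a \rVert - r_a)$.
This is the quantity a sphere-chain pore profiler plots (diameter vs
position), computed here by per-slice 2D maximization: Nelder-Mead from
the previous slice's optimum plus eight jittered restarts, which tracks
the pore centre line through the channel. Design choices: step 0.5 Å
and radius clamp 15 Å by default (both configurable); slices whose
optimum reaches the clamp are flagged unbounded and excluded from the
minimum-diameter summary; hydrogens are ignored (hard-sphere heavy-atom
model, no probe solvation); the jitter is seeded, so a fixed seed gives
bit-identical profiles. The "extracellular region" window of
`min_diameter_series()` defaults to the axial span of the EL1/EL2
residues, recomputed per frame, since no fixed boundary exists for it.
On analytic cylinder fixtures the profile recovers ring radius minus
vdW radius to within max(0.1 Å, step/2), which is the accuracy bound
the test suite enforces.

### SC connectivity graph

`build_sc_graph()` collapses a stability table across all chains to
residue level: nodes are residue labels (e.g. "65C"), node weight is
the number of SC instances the residue participates in, edge weight is
the stability fraction averaged over subunit instances (mean, not max —
a choice, recorded here, as either could summarize the figure-style
single-graph view), and cysteines are flagged. The handshake identity
(node weights summing to twice the edge instances) holds by
construction and is asserted on randomized tables. Connected modules
are exposed as plain connected components above a node-weight threshold
(`sc_graph_components()`) rather than through community detection,
which would overfit a visually-defined concept.

## Numeric constants

All constants live in one place, `analysis_parameters()`:

| parameter | default | meaning |
|---|---|---|
| `sc_min_seq_separation` | 10 | SC criterion 1 |
| `sc_vdw_tolerance` | 1.0 Å | SC contact slack |
| `sc_triplet_min_contacts` | 7 of 9 | SC criterion 3 |
| `sc_min_stability_fraction` | 0.02 | reportable-SC threshold |
| `hbond_HA_cutoff` | 2.5 Å | trans-GJ H...acceptor |
| `cys_cys_SH_cutoff` | 4.3 Å | Cys SG...HG1 |
| `cys_iface_S_heavy_cutoff` | 4.1 Å | Cys-interface S...X |
| `cys_iface_H_cutoff` | 3.2 Å | Cys-interface H distance |
| `clash_cutoff` | 2.0 Å | assembly clash report |
| `ss_bond_SG_SG_cutoff` | 2.3 Å | disulfide detection |
| `h_attach_cutoff(_s)` | 1.25 / 1.45 Å | H-to-donor assignment |

The van der Waals table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
default 1.70 Å) is a standard Bondi-style set, exposed in the
configuration because the SC definition inherits any radius convention;
radii are configurable to allow calibration against other SC
implementations. All distance cutoffs are strict (`<`) where the
defining phrase says "below", and the disulfide read-out uses `<=`.

## The synthetic-data generator

Every test runs on structures generated in-package with planted ground
truth; each generator verifies its manifest with the package detectors
before returning, so a fixture that drifts out of spec fails loudly at
generation, not silently in a test.

* `make_sc_fixture()` plants exactly one SC: two C-alpha strands
  crossing in an X at cos θ = 0.6, the window in which the optimal
  flank triplets realize exactly 7 of 9 contacts; a second 90° crossing
  plants a contact that peaks at 5 of 9 and must be rejected. With
  `sep < 9` the arms are truncated so the central pair sits closer than
  the separation criterion allows.
* `make_toy_connexon()` builds ring-symmetric hexamers/dodecamers with
  residues 20-230, minimal residues (backbone plus the side-chain atoms
  the detectors read), canonical cysteines at 2.05 Å (closed) or 3.5 Å
  (open) SG-SG, and optional planted interactions: a dozen Cys-Cys
  bonds (one donor and one acceptor geometry per subunit), one trans-GJ
  H-bond per docking pair at 2.4 Å, a Cys61-Gln58 intra-subunit
  geometry at 4.0/2.66 Å, and one trans-GJ SC per docking pair (56-195)
  via the same X-crossing geometry as the strand fixture.
* `make_cylinder_channel()` stacks atom rings whose inscribed radius is
  known in closed form — the pore-profiler oracle.
* `make_trajectory()` emulates an MD recording statistically: iid
  Gaussian positional jitter around a base structure plus scheduled
  make/break events whose atoms sit exactly on their on/off geometry
  each frame. Deterministic schedules are recovered exactly by
  `sc_timeseries()`; Bernoulli(p) schedules are recovered to the
  realized fraction, which lies within $3\sqrt{p(1-p)/n}$ of p.

What the toys do not emulate — and hence what passing tests do not
show about real data: physical dynamics (the jitter is uncorrelated
between frames), realistic backbone geometry (the toy connexon's loops
are compact arcs, so intra-chain SC detections on it are geometry
artifacts; tests therefore assert planted pairs and trans-GJ counts,
not total counts), solvent, lipids, and any energetics. Conclusions
about real trajectories rest on the detectors' correctness on exact
geometry, which is what the fixtures certify.

## Problem sizes and determinism

The suite runs at deliberately small scale: toy connexons of ~10,000
atoms, trajectory fixtures of 200-2,000 frames (one 10,000-frame
trajectory exercises the full-scale I/O accounting), 50 random folds of
up to ~50 residues for the exhaustive SC cross-check, and cylinder
profiles of a few dozen slices. These sizes make every expected value
computable by brute force or closed form. All randomness flows through
explicit seeds: generators take a `seed` argument, the pore profiler
seeds its restarts, and `scripts/acceptance.R` derives every stream
from its `--seed` flag, so repeated runs are bit-identical.

## Known limitations

* H-bond detection is purely distance-based; no donor-H-acceptor angle
  term, matching the definitions reproduced, not best practice.
* The dodecamer assembly (`build_hc_hc()`) maps hemichannel chains to
  template chains alphabetically; the rotational register of a real
  docking pair must be supplied by the template, and clashes are
  reported, never minimized (no force field is present).
* The pore profiler's per-slice maximization is local; for severely
  non-convex cross-sections more restarts (`n_starts`) may be needed.
* Trajectories are multi-MODEL PDB only; binary MD formats are out of
  scope by design.
* Reference minimum distances reported for deposited MD runs of the
  real Cx43 assemblies (e.g. the 65C-189R and 187C-68K SC contacts)
  require those trajectories as input; the machinery
  (`sc_timeseries()` distance bookkeeping) is exercised here on
  synthetic schedules instead.
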