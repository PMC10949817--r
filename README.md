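# gjdock

Geometric post-processing of molecular-dynamics trajectories of
connexin hemichannels (HCs) and gap-junction channels (GJCs), for
structural biologists studying how two hemichannels dock head-to-head
across the extracellular gap and how the redox state of the conserved
extracellular cysteines governs that docking.

Two hexameric hemichannels on adjacent cells dock into a dodecameric
gap-junction channel. The Cx43 docking interface is organized by six
conserved cysteines per subunit (EL1: 54, 61, 65; EL2: 187, 192, 198)
forming three intra-subunit disulfides per subunit — 36 per channel —
and by the interface motifs 55N-56T-57Q-58Q (internal) and
194H-195Q-196V (external). `gjdock` quantifies that interface along a
trajectory:

* **Stabilization centers (SCs).** A residue pair (a, b) is an SC when
  (1) |res(a) − res(b)| ≥ 10 on the same chain (inter-chain pairs pass),
  (2) some heavy-atom pair satisfies d < r_vdW(a) + r_vdW(b) + 1.0 Å,
  and (3) triplets {l_a, a, r_a}, {l_b, b, r_b} built by choosing one
  residue from each flanking tetrapeptide realize ≥ 7 of the 9
  cross-triplet contacts. Detected per frame, aggregated into
  stability fractions, filtered to extracellular pairs present ≥ 2% of
  the run, and classified intra-subunit / inter-subunit /
  trans-gap-junction (docking register A-J, B-I, C-H, D-G, E-L, F-K).
* **Categorized H-bonds.** Trans-GJ bonds between residues 55-58 of
  opposite hemichannels (donor-H to acceptor < 2.5 Å); Cys-Cys
  thiol bonds (SG to HG1 < 4.3 Å); Cys-interface bonds (SG to heavy
  atom < 4.1 Å **and** donor-H distance < 3.2 Å).
* **Disulfide state.** Closed/open assignment (disulfide-patch style)
  and geometric SG-SG detection (≤ 2.3 Å).
* **Extracellular RMSD.** Frames aligned on the transmembrane heavy
  atoms (residues 21-46, 74-93, 156-176, 204-229), RMSD over EL1+EL2
  (47-73, 177-203).
* **Pore profile.** HOLE-style largest-inscribed-sphere radius per
  axial slice, r(z) = max_c min_a (|(c, z) − x_a| − r_a), with overall
  and extracellular-window minimum diameters per frame.
* **HC-HC assembly.** Two rigid copies of a hemichannel superposed on a
  dodecameric template (chains A-F and G-L), serials continued,
  sub-2 Å cross-copy clashes reported.
* **SC graph.** Chain-aggregated residue connectivity graph (nodes
  sized by SC participation, edges weighted by mean stability),
  exported as GraphML or TSV.

A synthetic-structure module generates every fixture class with planted
ground truth (self-verified at generation), so the full pipeline is
testable without any external data.

## Worked example

```r
library(gjdock)

# a docked dodecamer with closed disulfides and one planted trans-GJ SC
# per docking pair, plus a 2-frame "trajectory" around it
tc <- make_toy_connexon(12, "closed", plants = "trans_sc")
tr <- make_trajectory(tc$structure, n_frames = 2, seed = 8)$trajectory

detect_disulfides(frame_structure(tr, 1))
#> 36 rows: one per canonical pair per chain, e.g.
#>   chain_a res_a chain_b res_b sg_sg_distance  state canonical
#> 1       A    54       A   198           2.05 closed      TRUE
#> ...

ts <- sc_timeseries(tr, scope = "extracellular")
subset(ts$stability, class == "trans-GJ",
       c(chain_a, res_a, chain_b, res_b, subunit_pair, fraction))
#>      chain_a res_a chain_b res_b subunit_pair fraction
#> 108        A    56       J   195          A-J        1
#> 390        B    56       I   195          B-I        1
#> 672        C    56       H   195          C-H        1
#> 954        D    56       G   195          D-G        1
#> 1236       E    56       L   195          E-L        1
#> 1518       F    56       K   195          F-K        1
```

The 36 disulfides are the three canonical EL1-EL2 pairs on each of 12
subunits; the six trans-GJ SCs are the planted 56T-195Q pairs, one per
docking interface, present in 100% of the (rigid) toy run.

Pore profiling on an analytic cylinder (carbon rings of radius 6.7 Å,
one constricted to 3.7 Å):

```r
cy <- make_cylinder_channel(c(rep(6.7, 5), 3.7, rep(6.7, 5)), spacing = 2)
pr <- pore_profile(cy$structure, z_range = c(0, 20), step = 2, seed = 1)
pr$min_diameter   # 4.0  (= 2 x (3.7 - 1.7) A)
pr$z_at_min       # 10   (the constricted ring)
```

A full run — SC dynamics, H-bonds, disulfides, RMSD, pore, graph — is
orchestrated from one YAML config by `run_pipeline()`, or from the
shell via the thin `exec/gjdock` script:

```sh
gjdock run --config analysis.yaml
gjdock sc --trajectory traj.pdb --out sc.tsv
```

Atom selection uses named clauses, e.g.
`select_atoms(s, chain = "A", resno = 47:73, heavy = TRUE)` for the EL1
heavy atoms of chain A.

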