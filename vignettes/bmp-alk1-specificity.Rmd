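---
title: "Methods: interface analysis, conservation classes and kinetic fitting for BMP9/BMP10–ALK1 specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface analysis, conservation classes and kinetic fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bmpspec)
```

This vignette is the package's account of its methods: the models and
geometric criteria, the parameters that matter and why they default as
they do, what the synthetic generators emulate (and what they do not),
and the numerical and design choices that were genuinely open.

## The scientific setting

BMP9 and BMP10 are the only bone morphogenetic proteins that signal
through the endothelial type I receptor ALK1, and they do so with
picomolar affinity — orders of magnitude tighter than other BMPs bind
their cognate type I receptors. The structural explanation is tripartite:
the ligand–receptor interface combines (i) a hydrophobic core conserved
across the whole BMP family, (ii) a ring of residues conserved only
within the BMP9/BMP10 subfamily that carry the ALK1 specificity, and
(iii) variable residues that differ even between BMP9 and BMP10. A
one-residue insertion unique to the subfamily kinks the top strand of
finger 1, creating the surface read out by endoglin and the prodomain via
β-augmentation and, conversely, breaking the backbone ladder by which the
antagonist CV2 traps BMP2 — predicting (correctly) that CV2 cannot
inhibit BMP9. This package implements every computational step of that
argument as composable, tested functions.

## Structures, numbering and selections

Coordinates are read from PDB or mmCIF via bio3d into a flat atom tibble.
Three policies apply at parse time and everywhere downstream:

* **Hydrogens are ignored.** The relevant crystal structures are at
  2.3–3.3 Å and have none; all geometric criteria are heavy-atom based.
* **Alternate locations** keep only the highest-occupancy conformer
  (ties: first altloc tag alphabetically), making all counts
  deterministic.
* **Waters are discarded; other heteroatoms are kept but flagged**
  non-polymer, so they participate in surface areas but never in
  sequence-derived analyses.

All reports use **open-reading-frame (ORF) numbering** — residue 1 is the
initiator methionine of the signal peptide — as the canonical coordinate
system, with author numbering retained for traceability. `map_numbering()`
aligns a chain's observed sequence to a full-length reference
(Needleman–Wunsch, identity scoring with a strong mismatch penalty and
affine gaps, so true indels gap rather than mismatch) and fails loudly
below 95% identity over aligned positions. Nonstandard residues map to
`X`: excluded from conservation, included in surface areas.

## Buried-interface analysis

`compute_sasa()` is a Shrake–Rupley implementation with a deterministic
golden-spiral (Fibonacci) sphere sampling — no randomness, so areas are
bit-reproducible. Per-atom area is `exposed/n_points × 4π(r + probe)²`.

* `probe_radius = 1.4` Å — the water probe.
* `n_points = 960` — at this density a 20-atom cluster's total area is
  within 2% of a 4000-point evaluation (tested), and a lone atom's area
  is within 1% of the analytic sphere.
* Radii: C 1.70, N 1.55, O 1.52, S 1.80 Å (standard protein vdW values);
  unknown elements are an error naming the atom, never a silent default.

`interface_report()` computes SASA three times (each group isolated, then
the complex); per-residue buried area is clamped at ≥ 0 (it is
non-negative by construction up to float noise). The headline buried
surface area is the two-side average, the convention of interface-analysis
servers; both one-sided sums are also reported. `min_delta = 0.1` Å²
decides interface membership: conceptually "any buried area counts", with
a small epsilon guarding quadrature noise. Because published interface
residue counts depend on the exact threshold inside the server used, the
threshold is exposed and the deposited-structure counts are treated as
calibration benchmarks in the acceptance tests rather than hard-wired.

An independent Monte-Carlo SASA (seeded random directions, brute-force
burial test) serves as the oracle in tests and certifies the planted
truth of synthetic complexes; the two implementations share no sampling
code. The same random point set must be used for the isolated and
complexed evaluations when differencing — otherwise sampling noise
masquerades as buried area.

## Contact detection

Hydrogen bonds (no hydrogens available): donor and acceptor are N/O atoms
from a residue-chemistry table (Pro backbone N is never a donor;
Ser/Thr/Tyr hydroxyls are both donor and acceptor — the serine-to-backbone
bond at the heart of the ALK1 site II requires the donor role), with

* `max_dist = 3.5` Å donor–acceptor distance, and
* `min_angle = 90`° at the donor, measured antecedent–donor–acceptor,
  where the antecedent is the donor's bonded heavy atom (found as the
  nearest same-residue heavy atom within bonding distance, which covers
  backbone and all sidechain donors without a topology table).

Both are standard mid-resolution criteria and both are arguments. Salt
bridges pair Asp/Glu carboxylate oxygens (and OXT) with Lys/Arg/His
nitrogens at ≤ 4.0 Å, one record per residue pair at the minimum atom
distance; His is reported but flagged `ambiguous` since its protonation
is unknown at crystallisation pH.

`group_sheet_ladders()` clusters backbone–backbone bonds into β-sheet
ladders by register progression: antiparallel ladders advance `(+2, −2)`
(narrow pairs carry two bonds each), parallel ladders alternate their two
registers, `(+2, +2)`, `(0, +2)`, `(+2, 0)`. A ladder needs ≥ 2 backbone
bonds; sidechain bonds and unclusterable backbone bonds are returned
separately, never silently dropped.

## Superposition

`kabsch()` is the closed-form least-squares rigid superposition: SVD of
the cross-covariance with the determinant-sign correction so the result
is always a proper rotation. Degenerate (collinear) inputs are an error.
`build_correspondence()` pairs atoms positionally for identical sequences
and through a free-end-gap global alignment otherwise, using aligned
non-gap columns only and all four mainchain atoms (N, CA, C, O) per
paired residue; a CA-only mode is provided because published RMSDs do not
always state their atom set, and both modes are reported by
`compare_complexes()` workflows where it matters. Partially modelled
residues are dropped, not imputed, and there is no outlier trimming —
published plain RMSDs are plain RMSDs. For symmetric assemblies the copy
assignment (which receptor copy corresponds to which) is resolved by
taking the minimum RMSD over the copy orderings.

Tests bound the implementation three ways: rigid motions must be removed
to < 10⁻⁶ Å; the result must never exceed a brute-force rotation-grid
search; and it must agree with an independent least-squares fit from
bio3d.

## Conservation classes and the tripartite partition

`classify_positions()` assigns each alignment column exactly one class:

1. a gap in any subfamily row → `gap_in_subfamily`;
2. else modal residue count over all rows ≥ `family_min` →
   `family_conserved` (gaps never count as matches);
3. else all subfamily cells identical → `subfamily_conserved`;
4. else `variable`.

`family_min = 6` encodes "conserved in at least 6 of the 7 aligned family
members". Conservation is strict identity — the convention of
asterisk-marked alignments — with an optional similarity-group mode that
is off by default. The classifier is invariant to row order and naming,
and raising `family_min` can only shrink the family-conserved set (both
tested properties).

`tripartite_partition()` projects classes onto an interface residue set
and splits it into conserved core / subfamily-specific / variable. The
**override channel** exists because sequence and structure can disagree:
a residue that varies in sequence may still make the same interaction in
every complex (an aspartate-to-glutamate style substitution preserving a
salt bridge). Such residues are promoted into the subfamily-specific set
only explicitly, with a justification tag carried in the output — never
silently. Because of this ambiguity the headline "16 subfamily-conserved
positions" benchmark is checked as a band (±2) covering both the bare and
the override-inclusive counts. Swap-mutant design (`design_swap_mutants()`)
excludes overridden residues: they are conserved in function if not in
identity, so swapping them is not a specificity experiment.

Region assignment follows the interfaces: subfamily-conserved residues in
the type I interface form region 1, those in the type II interface region
2, and the remainder cluster at the dimer core (region 3) — the package
derives regions from interface reports rather than a geometric
dimer-axis rule, since the interface sets are the operational definition.

## Insertion detection and β-augmentation compatibility

`detect_insertion()` finds alignment columns occupied in every subfamily
row and gapped in every other row inside a strand interval, and
quantifies the resulting kink: superpose member and reference strands on
the flanking paired residues (2 per end by default), then take the
maximum mainchain deviation across the interval. The metric is invariant
under rigid motion of either structure (tested) and is computed even when
no insertion exists (then it is a plain strand-conformation difference).

`predict_beta_augmentation()` operationalises the CV2 argument. The
candidate ligand is superposed onto the template ligand over whole-domain
mainchain atoms — not strand-locally, because the antagonist engages the
strand in the context of the folded finger. Each template ladder bond is
preserved if the corresponding candidate backbone atom sits within
`max_disp = 2.0` Å of the template atom's position *and* the implied bond
to the antagonist atom still satisfies the 3.5 Å criterion; the verdict is
`compatible` iff at least `min_required = 3` of the (typically 4) bonds
survive. The thresholds are exposed; their anchors are the two ends of
the scale: a template tested against itself preserves every bond, and a
strand with a planted 3 Å bulge at the ladder site preserves none (both
are tests).

## SPR kinetics

The 1:1 mass-transport model is the standard quasi-steady two-compartment
form

$$\frac{dR}{dt} = \frac{k_a C (R_{max} - R) - k_d R}{1 + k_a (R_{max} - R)/k_t},$$

with association at analyte concentration $C$ until $t_{assoc}$ and
dissociation ($C = 0$) after; $k_t$ (RU·M⁻¹s⁻¹, Biacore convention) is
the transport coefficient and $k_t = \infty$ reduces to closed-form
Langmuir kinetics (used directly in that case; the reduction is verified
to 10⁻¹⁰ RU and the finite-$k_t$ integrator against an independent
fixed-step method to 10⁻⁴ RU). Evaluation-software rate equations are
proprietary, so this documented standard form is the model.

`fit_sensorgrams()` fits $(k_a, k_d, R_{max}[, k_t])$ globally across all
curves by Levenberg–Marquardt in log-parameter space from `n_starts`
seeded log-uniform starts (one heuristic start from the data's maximum
response), returning the best start; $K_D = k_d/k_a$ by definition.
Duplicate injections are distinct curves sharing a concentration.

Two study conditions are used in tests and the acceptance script:

* **Well-conditioned kinetics** ($k_a = 10^5$, $k_d = 10^{-2}$,
  $R_{max} = 100$ RU, $k_t = 10^8$; five concentrations spanning
  0.1–10 × $K_D$; 300 s per phase): noiseless recovery is exact to
  < 10⁻³ relative, and the median $K_D$ error at 1% noise over ten
  seeded replicates is < 5%.
* **Picomolar-affinity fixtures** parameterised from the reported
  equilibrium constants (48.1 pM and 34.3 pM with $k_a = 10^6$, the
  regime of BMP9/BMP10 binding ALK1): duplicate injections of a
  0.25–2 nM series, 600 s association, 3000 s dissociation, 0.1 RU
  instrument noise. With a dissociation rate of ~5×10⁻⁵ s⁻¹ only a
  ~13% decay is observed even in 3000 s, so $K_D$ carries an intrinsic
  ~5% uncertainty at this noise level; the recovery tolerance (10%)
  reflects that identifiability limit, not implementation error. The
  published constants themselves are not recoverable: the raw
  sensorgrams are not deposited, so they serve only to parameterise
  these fixtures.

## What the synthetic generators emulate — and what they do not

* `make_strand_pair()` builds strands in ideal β geometry (φ = −119°,
  ψ = 113°, standard bond lengths/angles, NeRF chain construction) and
  docks them by a deterministic optimisation so that a chosen register of
  backbone N···O pairs sits at 2.9 Å with physical donor angles while all
  other cross-strand N/O pairs stay out of range — a planted ladder that
  the detector must recover exactly. The optional insertion parks one
  extra residue between its neighbours and displaces the bulged segment
  away from the partner strand without re-registering the rest of the
  strand, emulating how a β-bulge distorts a sheet locally while the
  surrounding fold is unchanged. A short partner strand against a long
  host (`n_res_b`, `register_offset`) gives the localised pairing site
  with flanking anchor that the compatibility predictor needs.
* `make_toy_complex()` uses spaced four-atom residue clusters so that
  burial is unambiguous per residue; its truth is certified by the
  Monte-Carlo oracle and construction *fails* if any residue's burial is
  ambiguous, rather than planting a fuzzy set.
* `make_msa()` draws columns that satisfy the requested classes exactly,
  including subfamily-specific insertion columns and within-subfamily
  gaps.
* `make_sensorgrams()` adds seeded Gaussian noise to model curves —
  white noise only; no drift, no regeneration artefacts, no reference-cell
  mismatch (inputs are assumed reference-subtracted).

Passing on these fixtures therefore demonstrates algorithmic correctness
— recovery of known ground truth under controlled geometry and noise —
not performance on real data, where partial occupancy, alternate
conformations, missing loops, alignment errors and correlated instrument
noise all intrude. The deposited-structure benchmarks in the acceptance
tests are the bridge to real data; they require the coordinate files
(fetched once with `fetch_structures()`) and a locally built seven-member
growth-factor alignment, and they state so when the files are absent.

## Pipeline reproducibility and problem sizes

`run_pipeline()` validates its configuration exhaustively before any
computation (every error reported at once), runs stages in dependency
order, isolates failures per stage, and seeds every stochastic step from
the single configured seed, so an unchanged configuration reproduces its
report exactly. Reports render to a TSV bundle, JSON, or markdown with
threshold provenance.

The shipped tests and acceptance script run at deliberately small problem
sizes — strands of 4–12 residues, toy complexes of 8 + 8 residues,
alignments of ~110 columns, sensorgram series of 4–5 concentrations at
120–180 time points, 10-replicate Monte-Carlo loops — chosen so each
quantity is measurable with margin while the whole suite completes in a
few minutes on one core.

## Known limitations

* SASA neighbour search builds a full distance matrix: fine to ~10⁴
  atoms, not for very large assemblies.
* No symmetry-mate generation: deposited asymmetric units are analysed
  as-is (a contact across a crystallographic axis would be missed).
* Contact chemistry covers H-bonds and salt bridges only — no cation–π,
  halogen bonds or water-mediated contacts.
* The antagonist-compatibility predictor is rigid: it cannot credit
  backbone plasticity that might rescue a marginally displaced ladder.
* The kinetic model is strictly 1:1; avidity on dimeric surfaces (Fc
  fusions) is not modelled, matching common practice but a real
  simplification.
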