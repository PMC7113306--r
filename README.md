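# bmpspec

Structural-informatics toolkit for the question of why BMP9 and BMP10 —
alone among the bone morphogenetic proteins — bind the endothelial type I
receptor ALK1 with picomolar affinity. It is written for structural
biologists and computational biologists working on TGF-β family
ligand–receptor recognition who want the complete analysis chain behind
that question as reusable, tested R functions: buried-interface mapping,
contact inventories, rigid-body overlays, a tripartite conservation
classifier, antagonist-compatibility prediction, interface swap-mutant
design, and global fitting of surface plasmon resonance (SPR) kinetics.

## What the package computes

**Buried interfaces.** Solvent-accessible surface area (SASA) by the
Shrake–Rupley method: each atom's sphere of radius *r* + 1.4 Å is sampled
at a deterministic golden-spiral point set and the accessible fraction
counted; the per-residue buried area on complex formation is
ΔSASA = SASA(isolated) − SASA(complex), and an interface's buried surface
area is the two-side average ½(ΣΔSASA_A + ΣΔSASA_B). Any residue with
ΔSASA ≥ 0.1 Å² counts as an interface residue (threshold adjustable).

**Contacts.** Heavy-atom criteria suited to crystal structures without
hydrogens: a hydrogen bond is a donor–acceptor N/O pair within 3.5 Å whose
antecedent–donor–acceptor angle is ≥ 90°; a salt bridge is a carboxylate
oxygen within 4.0 Å of a Lys/Arg (or His, flagged ambiguous) nitrogen.
Backbone bonds are grouped into β-sheet ladders with parallel/antiparallel
orientation from the residue-register progression — the geometry behind
β-augmentation, the binding mode that the BMP9/BMP10 prodomain, endoglin
and the antagonist crossveinless-2 (CV2) all use on finger 1 of the
growth-factor domain.

**Superposition.** Kabsch least-squares rigid alignment (SVD with
reflection correction) over an atom correspondence built positionally for
identical sequences or from a global alignment for homologues, reporting
mainchain RMSD.

**Tripartite conservation.** Given a family alignment (e.g. seven BMP
growth-factor domains) and a subfamily (BMP9 + BMP10), every column is
classified as family-conserved (modal residue in ≥ 6 of 7 rows),
subfamily-conserved (identical within the subfamily only), or variable —
the three-way split that explains receptor specificity: a conserved
hydrophobic core provides affinity, subfamily-conserved residues provide
ALK1 specificity, and variable residues individualise each ligand.
Swap-mutant design emits the substitutions converting one subfamily
member's variable interface residues into the other's.

**β-augmentation compatibility.** Superpose a candidate ligand onto the
ligand of an antagonist complex and test whether each backbone H-bond of
the antagonist's ladder remains geometrically satisfiable; a
subfamily-specific one-residue insertion that kinks the host strand breaks
the ladder and predicts escape from the antagonist.

**SPR kinetics.** 1:1 interaction model with optional mass-transport
limitation, dR/dt = [k_a·C·(R_max − R) − k_d·R] / [1 + k_a·(R_max − R)/k_t],
globally fitted across a concentration series in log-parameter space by
multi-start Levenberg–Marquardt; K_D = k_d/k_a.

Seeded generators (`make_strand_pair()`, `make_toy_complex()`,
`make_msa()`, `make_sensorgrams()`, `perturb_copy()`) produce every input
class with machine-readable planted truth, so the full pipeline is
testable offline.

## Worked example

```r
library(bmpspec)

# an ideal antiparallel strand pair with a planted H-bond ladder
pair <- make_strand_pair(6, seed = 2)
hb <- find_hbonds(pair$model, "A", "B")
group_sheet_ladders(hb)[[1]]
#> <sheet_ladder> antiparallel: A1-5 | B2-6 (6 backbone H-bonds)

# picomolar-affinity sensorgrams and a global 1:1 mass-transport fit
kp <- kinetic_params(ka = 1e6, kd = 4.81e-5, Rmax = 100, kt = 1e8)
sg <- make_sensorgrams(kp, rep(c(0.25, 0.5, 1, 2) * 1e-9, 2), noise_sd = 0.1,
                       seed = 12, times = seq(0, 3600, 20), t_assoc = 600)
fit <- fit_sensorgrams(sg$data, t_assoc = 600, model = "mass_transport",
                       n_starts = 3, seed = 13)
fit
#> <kinetic_fit> 1:1 mass_transport model
#>   ka = 9.35e+05 /M/s, kd = 4.68e-05 /s, Rmax = 102 RU, kt = 1.05e+08 RU/M/s
#>   KD = 5e-11 M (50 pM); SSE = 13.75
```

The fitted K_D of 50 pM recovers the planted 48.1 pM (k_d/k_a =
4.81×10⁻⁵ / 10⁶) to within the uncertainty that 0.1 RU of instrument
noise leaves on a dissociation rate this slow. `tidy(fit)`, `glance(fit)`
and `autoplot(fit)` give the broom-style parameter table, one-row summary
and overlay plot.

For real structures: `read_structure("6sf3.cif")` →
`interface_report(model, group_a, group_b)` /
`find_salt_bridges(model, ...)` / `compare_complexes(a, b, role_map)`,
and `run_pipeline(config)` orchestrates a whole configured analysis into
a report renderable as TSV, JSON or markdown.

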