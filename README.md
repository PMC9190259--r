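# abflex

Post-simulation analysis of antibody–antigen conformational ensembles:
interface interaction profiling with explicit bridging waters, CDR
conformational-state quantification in dihedral and Cartesian space, and
affinity-correlation statistics — with a synthetic-ensemble generator that
plants exactly known ground truth so the whole pipeline is testable without
trajectory data.

## The problem

Explicit-solvent simulations of an antibody Fv, free (apo) and bound to its
antigen (holo), produce conformational ensembles that static crystal
structures cannot: water-mediated contacts at the paratope and the spectrum
of conformations each CDR loop visits. Turning those ensembles into numbers
requires three analyses that `abflex` implements for users of such
simulations:

1. **Interface interactions.** Per frame, detect hydrogen bonds
   (donor–acceptor ≤ 3.5 Å, D–H–A angle 120–180°), salt bridges (side-chain
   N/O pairs ≤ 4.5 Å), cation–π and π-stacking (ring centroid rules at
   6 Å), hydrophobic contacts (≤ 4.5 Å, counted by residue pair), ion
   contacts, and — the class implicit solvent cannot see — **bridging
   waters**: a water hydrogen-bonded to both antibody and antigen in the
   same frame. Each antibody–water bond is classified exactly once as
   direct-replacement, bridging, or bulk-solvent. The headline summary is
   the percentage of intermolecular interactions *not* made with bulk
   solvent,
   `100 × (total − solvent) / total`, bridging waters counting as
   intermolecular.
2. **CDR sampling, dihedral.** Each loop's backbone φ/ψ series is
   histogrammed (10° circular bins); bins holding ≥ 1.5 % of frames form
   peaks, joint peak labels form states, states under 1 % are discarded as
   rare. States are compared by circular similarity
   `s = mean(1 − Δ/180)` (1 = identical, 0 = opposed by 180°); scores
   ≥ 0.8 mark the same conformation across apo and holo.
3. **CDR sampling, Cartesian.** After superposition on the V_H/V_L
   interface backbone, a √mass-weighted PCA over combined apo+holo frames
   yields a shared 3-PC space; average-linkage clustering at linkage
   distance 11 counts conformations, and the DRES score — Jensen–Shannon
   divergence between kernel density estimates of the two projections, from
   0 (identical) to ln 2 (disjoint) — measures apo/holo overlap.
4. **Affinity statistics.** Per-antibody means over the six CDRs are
   correlated with ln(K_d in nM) (and ln k_off) by R², always accompanied
   by a leave-one-out influence scan that flags the panel member whose
   omission changes R² most.

## Worked example

Build a toy complex with planted interactions, count them, and compare
dihedral state sets:

```r
library(abflex)

ens <- build_toy_complex(complex_spec(hbond = 3, salt_bridge = 1, bridge = 2,
                                      hydrophobic = 2, solvent = 4))
summarize_trajectory(ens)
#> interaction summary (fluctuating_interface, 1 frames)
#>                  kind mean sd
#> 1        hbond_direct    3  0
#> 2        hbond_bridge    2  0
#> 3       hbond_solvent    4  0
#> 4         salt_bridge    1  0
#> 5           cation_pi    0  0
#> 6            pi_stack    0  0
#> 7 hydrophobic_residue    2  0
#> 8         ion_contact    0  0

round(nonsolvent_fraction(summarize_trajectory(ens)), 1)
#>                nonsolvent_pct nonsolvent_nonhydrophobic_pct
#>                          66.7                          50.0
#>               hydrophobic_pct                    total_mean
#>                          16.7                          12.0
```

Twelve intermolecular interactions, four of them to bulk water: 66.7 % are
non-solvent (direct bonds, the salt bridge, the two bridging waters and the
hydrophobic contacts), 50 % once hydrophobic contacts are also excluded.
The generator audits itself: if the detectors did not recover exactly the
planted counts, construction would fail.

```r
g_apo  <- generate_dihedral_ensemble(n_dihedrals = 4, populations = c(0.6, 0.3, 0.1),
                                     n_frames = 5000, spread = 3, seed = 1)
g_holo <- generate_dihedral_ensemble(n_dihedrals = 4, populations = c(0.7, 0.3),
                                     n_frames = 5000, spread = 3, seed = 2)
apo  <- build_states(g_apo$series)
holo <- build_states(g_holo$series)
apo
#> state set for CDR - 3 state(s), rare fraction 0.0028
#>   state 1: pop 0.608, means (-150, -140, -130, -120)
#>   state 2: pop 0.282, means (-30, -20, -10.1, 0.1)
#>   state 3: pop 0.107, means (90, 99.8, 110.1, 120.1)

m <- match_states(apo, holo)
compare_sampling(apo, holo)
#> [1] "more_apo"
```

The three planted apo states are recovered with their populations and mean
torsions; matching against the two-state holo set finds the one shared
conformation and classifies the loop as sampling more in the apo form.

## The analysis workflow

The `analysis/` scripts run the whole study on a seeded synthetic panel of
8 antibodies whose planted truth is a linear ln(K_d) vs non-solvent
percentage relationship:

```sh
Rscript analysis/01_build_panel.R    # panel PDBs + affinities + config -> results/panel/
Rscript analysis/02_interactions.R   # per-antibody interaction summary -> results/interactions.csv
Rscript analysis/03_cdr_sampling.R   # dihedral states + PCA/DRES per CDR -> results/per_cdr.csv
Rscript analysis/04_correlations.R   # metrics, R^2 + leave-one-out, classes -> results/*.csv, report.json
```

Stage 4 prints, among others, the recovered planted relationship
(`ln_kd vs nonsolvent_pct: R^2 = 0.988` on the default seed) and the
sampling-class percentages table. `run_pipeline()` performs the same stages
from one config in a single call.

## Layout

```
R/                 implementation: containers & PDB I/O, interaction detectors,
                   dihedral states, PCA/clustering/DRES, affinity statistics,
                   synthetic generators, pipeline stages
analysis/          numbered workflow drivers (thin, narrative)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests with independent
                   brute-force oracles
vignettes/         methods vignette: models, parameters, design decisions
```
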