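---
title: "Interface interactions and CDR flexibility: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface interactions and CDR flexibility: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abflex)
```

`abflex` analyses conformational ensembles of antibody variable fragments
(Fv), alone (apo) and in complex with antigen (holo), the way such ensembles
come out of explicit-solvent molecular dynamics: multi-model PDB files with
explicit hydrogens and waters. Three questions drive the package: which
interactions hold the paratope together (including the ones mediated by
individual bridging waters), how many discrete conformations each CDR loop
visits in dihedral and in Cartesian space, and whether any of those
quantities track binding affinity across a panel of antibodies. This
vignette records the models behind each stage, the tunable parameters, and
the design decisions that were genuinely open.

## Interaction model

All detection is geometric, against explicit criteria collected in
`interaction_criteria()` so that every run records what it actually used:

| class | rule (defaults) |
|---|---|
| interface membership | heavy-atom pair across molecules ≤ 4.5 Å |
| hydrogen bond | donor–acceptor (heavy) ≤ 3.5 Å and donor–H–acceptor angle in [120°, 180°] |
| salt bridge | side-chain N/O of oppositely charged residues ≤ 4.5 Å |
| cation–π | ring centroid to cation ≤ 6 Å, centroid→cation vs ring normal in [0°, 60°] ∪ [120°, 180°] |
| π-stacking | ring centroid to ring centroid ≤ 6 Å (distance only) |
| hydrophobic | hydrophobic atom pair ≤ 4.5 Å, counted once per residue pair |
| ion contact | ion to Fv N/O ≤ the salt-bridge cutoff |

Every threshold is inclusive; a pair at exactly the cutoff is detected (a
10⁻⁹-degree slack keeps the closed angle windows inclusive under floating
point). π-stacking deliberately carries no angle filter — the criteria table
this implements lists none — so perpendicular rings at 5 Å count; this is
flagged here because many other tools do filter by ring angle.

Where the underlying conventions are not fixed by the criteria themselves,
the package decides and documents:

* **Donor–hydrogen association.** A hydrogen belongs to the nearest N/O/S
  within 1.25 Å in its own residue. This avoids any reliance on CONECT
  records or bond perception. Donors are N/O/S atoms with at least one such
  hydrogen; acceptors are N/O (S excluded as acceptor, the common
  biomolecular convention).
* **Charged groups.** Arg (NE, NH1, NH2), Lys (NZ) and doubly protonated His
  (residue name HIP) are positive; Asp (OD1/OD2), Glu (OE1/OE2) and the
  C-terminal carboxylate are negative — the pH 7.4 states. His cations are
  excluded from cation–π by default (`include_his_cation` turns them on).
* **Rings.** Phe/Tyr six-rings, the Trp five- and six-ring as separate
  rings, and the neutral-His five-ring; the normal comes from an SVD
  best-fit plane. An incompletely present ring template is a structure
  error rather than a silently skipped ring.
* **Hydrophobic atoms.** Template carbons/sulfurs whose bonded neighbours
  include no N or O (Leu CD1, Met SD, the Phe ring carbons, …). Contacts
  collapse to residue pairs: three atom pairs between the same two residues
  are one contact.

**Water classes partition exactly.** For each frame, every antibody–water
hydrogen bond is classified once: if the water also hydrogen-bonds the
antigen in that frame it is a bridging water and the antibody-side bond
counts as `hbond_bridge`; otherwise the bond is `hbond_solvent`. Only
first-order bridges count — a water reaching the antigen through a second
water does not bridge. Direct antibody–antigen bonds are a third, disjoint
class. This partition is what makes the non-solvent percentage well defined:

$$\text{nonsolvent\%} = 100\,\frac{\text{total} - \text{solvent}}{\text{total}},$$

with bridging-water bonds counted as intermolecular (they form an indirect
antibody–antigen contact) and `total` the sum of per-kind trajectory means
over all intermolecular classes including solvent.

Two counting modes mirror two uses. `fixed_interface` applies a reference
residue selection (e.g. from a crystal structure) to every frame, for fair
simulation-vs-crystal comparisons; `fluctuating_interface` (default) scans
the full cross-molecule atom sets every frame, capturing all interactions as
the system fluctuates — the mode used for affinity correlations. Distances
are direct Euclidean: frames must be pre-imaged and whole, which is the
normal state of aligned, extracted trajectories; the package performs no
periodic-boundary imaging. Neighbour search is vectorised all-pairs rather
than a cell grid: at the atom counts this package targets (10²–10³ per
molecule) a grid buys nothing, and the detectors are tested for exact
agreement with an independent scalar double-loop implementation on hundreds
of random geometries.

## Dihedral-state model

Each CDR's backbone φ/ψ time series (ω is excluded) is histogrammed per
dihedral on a circular grid, default `bin_width` 10° — fine enough to
separate rotamer-scale modes, coarse enough that the 1.5% bin threshold is
meaningful at typical trajectory lengths. A *peak* is a maximal circularly
contiguous run of bins each holding at least `peak_bin_fraction` (default
0.015) of the frames; circular contiguity means a mode sitting on the ±180°
seam is one peak, not two. A frame's *state* is the joint vector of its
per-dihedral peak labels; frames falling in any sub-threshold bin are
off-peak noise. States below `rare_state_fraction` (default 0.01) and all
noise frames accumulate into the rare fraction, so kept populations plus
the rare fraction always sum to one — a tested invariant.

Two states are compared by circular similarity: per dihedral,
$s_d = 1 - \Delta_d/180$ with $\Delta_d$ the absolute circular difference of
the mean torsions in [0°, 180°]; the state score is the arithmetic mean of
the $s_d$ (the minimum is available by option where a single opposed
dihedral should veto a match). Scores of 0.8 and above mark the same
conformation; apo/holo state sets are matched greedily in descending
similarity, one-to-one. Greedy matching is a deliberate, recorded choice —
the matched-percentage summaries this supports do not name an assignment
algorithm, and greedy is reproducible and order-independent given distinct
similarities.

Because off-peak frames are counted as rare rather than attached to the
nearest peak, kept-state populations systematically undershoot planted
populations by the off-peak mass. With wrapped-Gaussian wells of spread σ
and 10° bins, that mass is roughly the per-dihedral tail beyond the peak
bins compounded across dihedrals: negligible for σ ≈ 3°, a few percent at
σ ≈ 8°. The parameter-recovery tests therefore plant σ = 3° wells (well
inside the > 3σ separation the generator enforces) where the ±0.02
population tolerance is attainable; at σ = 8°, realistic for flexible
loops, state *counts* and circular means are still recovered exactly but
populations carry that known bias — a property of the histogram-peak method
itself, not of this implementation.

## Cartesian model

Apo and holo ensembles are first superposed on the V\_H/V\_L interface
backbone (selected by proximity in a reference frame, or given explicitly)
using a proper-rotation Kabsch fit — reflections are rejected by the
determinant correction. A single PCA basis is fit on the concatenated
apo+holo frames: CDR backbone coordinates are weighted by √mass, the
covariance matrix diagonalised, and frames projected on the first three
components. Per-ensemble cluster counts then come from each ensemble's own
projection, so apo and holo are counted in a common, comparable space.

Clustering is average-linkage agglomeration on Euclidean distances in 3-PC
space, cut where the merge distance exceeds 11. Because of the mass
weighting, that threshold is in mass-weighted Ångström units (≈ √(12 Da) ×
plain Å for carbon-dominated backbones); this is stated prominently since a
threshold in plain Å would differ by ~3.5×. The implementation is
`stats::hclust`/`cutree`; it is tested for exact partition agreement with a
naive O(T³) agglomeration oracle up to T = 200.

Ensemble overlap (DRES) is the Jensen–Shannon divergence, natural log,
between Gaussian kernel density estimates of the two projected ensembles:
0 for identical ensembles, ln 2 ≈ 0.693 for disjoint ones. Bandwidths follow
Silverman's rule per dimension on the *pooled* frames — sharing the
bandwidth between both densities is what makes DRES of an ensemble with
itself exactly zero rather than zero-in-expectation. The divergence is
estimated by Monte Carlo with 10,000 samples by default, half drawn from
each KDE, with a fixed seed recorded in the result; estimates match a grid
quadrature oracle within ±0.02 on planted Gaussian pairs. Estimator
settings travel with every score, since the underlying method leaves them
to the implementation.

## Affinity statistics

ln(K_d in nM) is the affinity proxy (monotone in the binding free energy);
antibodies without a K_d stay in the metric table but drop out of every
correlation, and ln(k_off) correlations use pairwise-complete values.
Per-antibody metrics are means over the six CDRs. Correlations report R²
(squared Pearson r) with slope, intercept and n — no p-values, matching the
exploratory character of a nine-antibody panel — plus a leave-one-out scan
that recomputes R² with each point removed and flags the most influential
point. That diagnostic generalises the common practice of quoting a
correlation with one anomalous panel member omitted: both the full and the
omitted R² are always reported, never only the better one. Sampling-class
percentages (more apo / equal / more holo, by kept-state or cluster counts)
use strict count equality by default; a tolerance argument exists because
"equal" could defensibly absorb off-by-one counts.

## What the synthetic generator emulates — and what it does not

No trajectory data accompany the analyses this package implements, so the
generator plants known truth in exactly the structures the pipeline
consumes:

* **Toy complexes** realise requested interaction counts by construction,
  each site strictly inside its threshold (donor–acceptor 2.9 Å at 180°,
  salt pair 4.4 Å, centroid–cation 5.0 Å on the normal, stacked centroids
  at 5.0 Å, hydrophobic pair 4.0 Å, bridging water bonded 2.9/2.8 Å to both
  sides), with sites spaced 14 Å so nothing else comes near any 6 Å cutoff.
  Residues carry a full N/H/CA/C/O backbone plus the minimal side-chain
  motif each class needs (Lys NZ, Asp OD1/OD2, Phe rings, Leu CD1/CD2,
  3-site waters, Na⁺). Every build is audited: the package's own detectors
  must recover the planted counts exactly or construction fails.
* **Dihedral ensembles** draw frame states i.i.d. from planted populations
  and add wrapped-Gaussian noise; **Cartesian ensembles** displace CDR
  atoms along fixed orthonormal modes around per-cluster amplitudes with
  non-CDR atoms frozen, so superposition is exact by construction.
* **Panels** place per-antibody non-solvent percentages on a line
  ln(K_d) = slope·f + intercept (defaults: slope −0.35 per percentage
  point, intercept 25, f spanning 60–95%, giving K_d from sub-pM to tens of
  nM — the span real high-affinity panels cover), with Gaussian noise and an
  optional planted outlier. Fifty interactions per complex give the 2%
  granularity within which the measured percentage matches the planted one.

Passing on these fixtures demonstrates that the *analysis machinery* is
correct: detectors equal brute force, state and cluster recovery works,
the correlation arithmetic recovers planted relationships. It does not
demonstrate anything about real antibodies: toy complexes have no
conformational coupling between sites, no competition between interaction
classes, i.i.d. rather than autocorrelated frames, and cleanly separated
wells. Conclusions about real systems still require real ensembles.

## Numerical choices and degenerate inputs

* Coordinates are Å throughout; residue ids come verbatim from the PDB.
* Multi-model PDBs with inconsistent atom counts fail naming the offending
  model; structures without hydrogens are rejected by hydrogen-bond
  analysis rather than silently returning zero.
* Torsions follow the standard sign convention (verified against two
  independent implementations); collinear quadruples are an error, not an
  NaN. Reversing a quadruple's atom order leaves the torsion unchanged —
  it is mirror reflection that flips the sign.
* `build_states` requires ≥ 100 frames (percent-scale thresholds are
  meaningless below) and a bin width dividing 360.
* PCA needs ≥ 4 combined frames; eigenvalues are clipped at zero;
  variance-explained sums to 1 within 10⁻⁹.
* DRES requires ≥ 10 frames per ensemble and clips to [0, ln 2].
* Correlations refuse n < 3 or zero variance.
* Empty atom selections warn and return empty rather than erroring, so
  set algebra on selections stays total.

## Problem sizes

The shipped analysis (`analysis/01` … `04`) runs an 8-antibody panel with
~50 planted interactions per complex, 2,000-frame dihedral series over 4
dihedrals, 120-frame Cartesian ensembles per CDR and form, and 2,000-sample
DRES estimates — a few minutes end to end on one core, while leaving every
threshold at the values used throughout this vignette. The test suite uses
10,000-frame series and 10,000-sample estimators where tolerances demand
them. All sizes are config knobs; nothing in the method depends on these
particular values.

## Known limitations

* Hydrophobic typing is template-based for the 20 standard residues;
  nonstandard residues contribute no hydrophobic atoms unless templates are
  extended.
* Bridging analysis is first-order only; second-shell water networks are
  out of scope.
* The exploratory correlation grid is reported without multiple-testing
  correction; with n ≤ 9 panels these R² values rank hypotheses, they do
  not test them.
* No kinetics: states and clusters are occupancy summaries, not a Markov
  model; transition information in the frame order is ignored.
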