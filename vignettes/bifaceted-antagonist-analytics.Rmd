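---
title: "Methods: bifaceted cytokine-receptor antagonist analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bifaceted cytokine-receptor antagonist analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifacet)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the defaults and why, what the synthetic
generators emulate, and where the design was genuinely open.

## The problem

Homodimerizing type I cytokine receptors (the motivating case is G-CSFR)
signal when a ligand juxtaposes two receptor ectodomains in a productive
geometry. An antagonist built from a receptor-binding scaffold must
out-compete the natural ligand at its binding epitope *without* itself
assembling a signaling-competent dimer. The bifaceted-ligand strategy
grafts a second copy of the receptor-binding site onto the opposite face
of a small four-helix bundle, so that any ternary complex it nucleates is
too strained (very large spacing between the receptors' membrane-proximal
ends) to signal. Evaluating such designs requires structural comparison,
binding kinetics, cell-based potency, and single-molecule dimerization
measurements; this package implements that analysis stack end to end on
desk-scale synthetic data with known ground truth.

## Pseudosymmetric grafting

An up-down-up-down four-helix bundle carries two internal two-fold
pseudosymmetries that relate the H2/H3 face to the H1/H4 face:

* a rotation about the **bundle axis**, which pairs H2→H4 and H3→H1 and
  preserves the axial sense of a grafted site — we call grafts using it
  **parallel**;
* a two-fold rotation about an **in-plane axis**, which pairs H2→H1 and
  H3→H4 and inverts the axial sense — **antiparallel**.

A third conceivable convention (same helix pairing as the first but with
reversed sequence traversal) is *not* realizable by any rigid transform
on this topology: we verified numerically on the ideal bundle that no
such correspondence brings matched C-alphas within the 3.5 Å acceptance
cutoff. The two conventions above are therefore the package's definition
of orientation, validated by construction against the ideal generator
(both are exact symmetries of `make_ideal_bundle()` output, by choice of
helix phases).

`map_pseudosymmetric_positions()` superposes the source helix-pair
C-alpha trace onto the destination pair under the selected pairing
(Kabsch, proper rotations only), then assigns each transformed source
C-alpha its nearest destination C-alpha greedily by distance, enforcing
bijectivity, with a 3.5 Å cutoff; unmatched positions are an error, not a
silent drop. `optimize_register()` scans integer offsets in ±4 (the
window is a package default; ties break toward smaller |offset|, then
negative) and minimizes the local best-fit C-alpha RMSD between the
candidate destination patch and a **reference site geometry**. The
reference defaults to the site's own backbone on the source face; in a
real design campaign it should be the native receptor-binding site the
graft must reproduce, and passing it externally (`reference_xyz`) is what
makes the register search meaningful — with a moving reference a shifted
site definition would simply carry its destination along and every offset
would score alike on an ideal scaffold.

Binding-site quality is reported as backbone RMSD over paired residues,
with both the C-alpha-only and full-backbone (N, CA, C, O) atom sets and
both local best-fit and fixed-frame modes computable, because published
site RMSDs do not always state which convention was used. The default is
C-alpha with local best fit (isolated-site comparison).

**Inter-TMD spacing.** For ternary-complex models the package measures
the distance between the two receptor chains' anchor atoms, defaulting to
the C-alpha of each chain's most C-terminal resolved residue (the
membrane-proximal end of a modeled ectodomain). This is a proxy — real
constructs have linkers and transmembrane helices — but it is the
quantity that discriminates strained from native-like assemblies (native
complexes measure ~84 Å, bifaceted-design models 214–251 Å in published
ensemble predictions; those ensemble values derive from structure
predictors and are documented anchors, not quantities this package
recomputes).

## Combinatorial library accounting

The affinity-maturation library splits every designed sequence at a fixed
fragment boundary (position 55/56 in the motivating campaign, a
configurable `boundary` here); fragment uniqueness is counted at the
amino-acid level — whether published oligo counts were DNA- or
protein-level unique is unstated, so the package documents protein-level
as its convention. Degeneracy is `|pool1| × |pool2|`; with the published
pool sizes 298 × 330 this is 98,340 ≈ 9.8 × 10⁴. Screening math: the
FACS gate keeps the top `ceil(N × fraction)` events (default fraction
0.001; threshold ties included), and coverage requires at least 20× more
events screened than the library complexity. Plate screens are ranked by
Z-scores of OD600-normalized luminescence, standardized per condition
with the sample (n−1) SD; conditions with zero variance are flagged
degenerate rather than producing NaNs.

## SPR kinetics

Sensograms follow the closed-form 1:1 Langmuir model (association
`R_eq(1 − e^{−(k_aC+k_d)t})`, `R_eq = R_max C/(C+K_D)`; exponential
dissociation), with defaults of 180 s association and 600 s dissociation
matching standard multi-cycle protocols. Double referencing subtracts the
reference-surface and zero-concentration channels; it is exactly linear,
so common drift cancels.

Fitting is global — one (k_a, k_d, R_max) shared across the
concentration series — because a multi-cycle titration measures one
analyte on one surface; per-curve fits are available for diagnostics.
The objective is plain least squares on log-parameters, minimized with
Nelder–Mead from 8 log-spaced starts on k_a (k_d is anchored by a
log-linear fit to the dissociation tails, R_max by the largest observed
plateau), relative SSE tolerance 1e-12. Uncertainty is reported as
leave-one-concentration-out mean ± sample SD, which yields n = 4
estimates for a standard 4-concentration series. Mass-transport
limitation is not modeled; for the rate regimes simulated here
(k_a ~ 3×10⁵ M⁻¹s⁻¹) that is a documented simplification.

## Dose-response potency

Proliferation and competitive-inhibition readouts are min-max normalized
to plate controls (`100·(x − neg)/(pos − neg)`); normalization is affine
invariant, so raw fluorescence units never matter. The four-parameter
logistic is fit by least squares with Nelder–Mead (the simplex choice
mirrors common practice in this assay literature), initialized from the
data (bottom = min, top = max, EC50 = geometric mid of the nonzero
doses), with both hill signs tried plus seeded jittered restarts.
Zero-dose wells enter through the analytic c→0 limit rather than a
pseudo-concentration. The hill sign is free: activation and inhibition
use one parameterization, and IC50 is the midpoint of a decreasing
curve. Replicate statistics: plain mean ± sample SD of per-replicate
fits when replicate designs are equal; leave-one-replicate-out refits on
pooled data when they are not (the situation that arises with biological
replicates of unequal size). Bell-shaped self-competition curves are out
of scope; users fit the ascending limb they select.

## Single-molecule co-tracking

Inputs are localizations (frame, x, y, channel) — spot detection from
raw movies is upstream of this package. Linking is greedy
nearest-neighbor frame-to-frame under a step bound (default guidance:
5·√(4DΔt)), with optional gap bridging; it deliberately replaces
multi-hypothesis trackers, which are a cited-tool contract rather than
the analysis contribution. Immobile emitters (adsorbed dyes, stuck
receptors) are removed when a track's radial positional SD falls below
2× the localization precision — a simplified stand-in for
spatiotemporal cluster analysis.

Co-tracking pairs A and B localizations within 0.1 µm each frame
(greedy by distance, one-to-one) and calls runs of ≥10 consecutive
co-paired frames co-trajectories. The **co-tracked fraction** is
frame-based: qualifying pairings per frame over the per-frame mean of
the two channels' particle counts, averaged over the stack. We chose the
frame-based form over counting distinct track pairs because greedy
linkers occasionally swap identities where tracks cross; a swap splits
one co-trajectory into two runs, which inflates a pair-count numerator
but leaves the frame count intact (we observed exactly this bias, ~+10
percentage points at 0.25 µm⁻² density, when prototyping the pair-count
definition).

Diffusion coefficients come from the pooled MSD of all trajectories
longer than 10 frames, linear regression over the first 4 lags,
`D = slope/4`; the intercept absorbs the localization-noise floor
(≈ 4σ², and the estimator reproduces this on simulated data). Group
comparisons use a two-sample Kolmogorov–Smirnov test; for
min(n, m) ≤ 8 without ties the p-value is exact via an integer
lattice-path count (verified against full enumeration in the tests),
small tied samples fall back to enumeration, and larger samples use the
asymptotic Kolmogorov distribution.

## Synthetic data: the stated world

* **Ideal bundle**: textbook helix parameters (1.5 Å rise, 3.6
  residues/turn, 2.3 Å C-alpha radius), four straight helices on a
  square of radius 8 Å, phases chosen so both pseudosymmetries are
  exact. It emulates scaffold topology, not real coiled-coil supercoil,
  loops, or side chains — a green graft test establishes the mapping
  contract, not design quality on a real scaffold.
* **Sensograms**: closed-form curves plus optional white noise and
  linear drift. Defaults for the recovery studies: 4-point 2-fold
  dilution from 20 nM, 1% of R_max noise. No mass transport, no
  regeneration artifacts.
* **Plates**: 4PL truth plus Gaussian noise of 5% of the dynamic span,
  triplicate, with positive/negative control wells. The IC50 anchor used
  in recovery studies is 35.3 nM (the published potency of the best
  first-generation antagonist); the K_D anchor is 4.3 nM.
* **Trajectories**: 2-D Brownian paths, reflecting boundaries, 32 ms
  frames, 150-frame stacks, 20 nm localization precision. Monomer
  D = 0.1 µm²/s and dimer D = 0.05 µm²/s are typical live-cell membrane
  receptor mobilities (reports of this assay give no
  numeric D truth, so these are realism choices made once). Density
  defaults to 100 emitters/channel on a 20 µm field (0.25 µm⁻²) —
  single-molecule experiments require comparable sparsity for tracking
  to be identifiable at all. Dimers carry exactly one emitter per
  channel: no stochastic degree-of-labeling, no blinking or bleaching,
  so estimated fractions are upper bounds relative to real label
  statistics.

All generators are deterministic given their seed.

## Numerical choices and degenerate inputs

* Kabsch superposition rejects < 3 points and (near-)collinear inputs
  (second singular value < 1e-8 of the first); reflections are removed
  by flipping the smallest singular vector's sign.
* Alternate locations in structure files keep the highest-occupancy
  copy; author chain/residue numbering is preserved.
* Flat SPR signals, constant dose-response readouts, equal positive and
  negative control means, empty KS samples, and OD600 ≤ 0 all raise
  informative errors rather than returning numbers.
* Register-scan ties break toward 0, then negative, so results are
  deterministic.
* `K_D = k_d/k_a` is maintained exactly (derived, never refit).

## Known limitations

* The greedy linker degrades above ~0.5 µm⁻² emitter density; the
  co-tracking fraction remains usable (frame-based definition) but
  per-track statistics do not.
* The crystal-vs-native site RMSD anchors (≈0.6 Å primary / 1.2 Å
  secondary) and the published K_D/IC50 refits require deposited
  coordinates and supplementary datasets that cannot be bundled or
  fetched offline; the corresponding acceptance test fails by design
  with an explanatory message rather than being skipped.
* Ensemble inter-TMD spacings (214 ± 18 Å / 251 ± 9 Å vs 84 ± 43 Å)
  come from structure-prediction ensembles; the package measures the
  metric on given models and reproduces the arithmetic on toy
  complexes, but does not regenerate the ensembles.
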