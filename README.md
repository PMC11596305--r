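# bifacet

Analysis toolkit for the design and characterization of **bifaceted
antagonists of homodimerizing type I cytokine receptors** (the motivating
system is G-CSFR, the granulocyte-colony stimulating factor receptor).

A bifaceted ligand is a small four-helix-bundle domain carrying *two*
receptor-binding faces: the primary site on helices 2/3 and a secondary
site grafted onto helices 1/4 by exploiting the bundle's internal
pseudosymmetry. Such a ligand can engage two receptor subunits in a
geometry too strained to signal, turning a receptor-binding scaffold into
a competitive antagonist. Characterizing this design cycle requires a
heterogeneous stack of quantitative methods, all of which this package
implements as reusable, tested components:

| area | what the package computes |
|---|---|
| structure | PDB/mmCIF parsing, Kabsch superposition, paired-residue backbone RMSD (Cα or N/CA/C/O; local best-fit or fixed frame) |
| grafting | pseudosymmetric H2/H3 → H1/H4 position mapping, register optimization (exhaustive ±4 scan), mutated-sequence emission, binding-site RMSD assessment, inter-TMD spacing of ternary complex models |
| library | two-fragment oligo-pool accounting (`|pool1| × |pool2|` degeneracy), mutational-space size, FACS gate + ≥20× coverage rule, OD-normalized plate Z-scores, consensus logo counts |
| SPR | 1:1 Langmuir sensogram simulation (180 s association / 600 s dissociation), double referencing, global (ka, kd, Rmax) fitting with leave-one-out statistics |
| dose-response | four-parameter logistic fitting (Nelder–Mead), min-max control normalization, EC50/IC50 with replicate or leave-one-out statistics |
| single molecule | trajectory linking, immobile-emitter filtering, dual-color co-tracking (100 nm radius, ≥10 co-diffusing frames), MSD diffusion (D = slope/4), two-sample KS test with exact small-sample p-values |
| synthetic data | seeded generators with known ground truth for every input above |

## Core models

**1:1 Langmuir kinetics.** Association
`R(t) = R_eq (1 − e^{−(k_a C + k_d) t})` with
`R_eq = R_max C / (C + K_D)`, dissociation `R(t) = R_0 e^{−k_d (t−t_0)}`,
`K_D = k_d / k_a`. Fits share (k_a, k_d, R_max) globally across a
multi-concentration series.

**Four-parameter logistic.**
`f(c) = bottom + (top − bottom) / (1 + (EC50/c)^hill)`, with the analytic
`c → 0` limit for zero-dose wells. IC50 is the midpoint of a decreasing
(negative-hill) curve after min-max normalization to plate controls.

**Co-tracking.** Frame-wise A–B co-localization within 0.1 µm, runs of
≥10 frames count as co-trajectories; the co-tracked fraction is the
time-averaged number of qualifying pairings over the per-frame mean
particle count. Diffusion: pooled `MSD(τ) = 4Dτ + b` over the first 4
lags, trajectories longer than 10 frames.

## Worked example

```r
library(bifacet)

## graft a 12-residue site from the H2/H3 face onto H1/H4
bundle <- make_ideal_bundle(n_res = 24)
site <- binding_site(positions = c(30:35, 57:62),
                     aa = strsplit("EWQLRDKFYHNS", "")[[1]])
gr <- graft_site(bundle$structure, bundle$annotation, site,
                 template = strrep("A", 105), orientation = "antiparallel")
gr
#> GraftResult: antiparallel graft, offset +0, site rmsd 0.000 A, 12 mutations

## fit a noisy simulated SPR dilution series (truth: KD = 4.3 nM)
truth <- kinetic_params(ka = 3e5, kd = 1.29e-3, rmax = 100)
sg <- lapply(20e-9 / 2^(0:3), function(c)
  simulate_sensogram(truth, c, dt = 2, noise_sd = 1, seed = 1))
fit_1to1(sg)
#> Global 1:1 kinetic fit
#> ka 3.02e+05 1/(M s), kd 0.00129 1/s, KD 4.28e-09 M, Rmax 99.7 RU
#> leave-one-out statistics:
#>  parameter         mean           sd
#>         ka 3.030902e+05 1.919628e+03
#>         kd 1.291221e-03 3.413732e-07
#>         KD 4.260311e-09 2.578432e-11

## quantify receptor dimerization in a simulated dual-color field
cfg <- trajectory_sim_config(n_per_channel = 100, dimer_fraction = 0.3,
                             seed = 1)
loc <- simulate_two_channel_field(cfg)$localizations
ms <- 5 * sqrt(4 * cfg$d_monomer * cfg$dt)
cotrack(link_tracks(loc[loc$channel == "A", ], ms),
        link_tracks(loc[loc$channel == "B", ], ms))
#> Co-tracking: 48 pairs / (100, 100) tracks -> fraction 0.293
```

The grafted site lands at register offset 0 with ~0 Å site RMSD (the
ideal bundle is exactly pseudosymmetric); the kinetic fit recovers the
4.3 nM ground-truth K_D within 1%; the co-tracking analysis estimates a
29.3% dimer fraction against a 30% ground truth.

## Command line

```sh
Rscript -e 'bifacet::bifacet_cli()' pipeline --seed 1 --out runs/demo
Rscript -e 'bifacet::bifacet_cli()' fitspr --in sensograms.csv --out out/
Rscript -e 'bifacet::bifacet_cli()' doseresp --in plate.csv --kind ic50 --out out/
Rscript -e 'bifacet::bifacet_cli()' cotrack --in localizations.csv --out out/
```

See `vignettes/bifaceted-antagonist-analytics.Rmd` for the methods
account: model assumptions, parameter defaults and units, what the
synthetic generators do and do not emulate, and known limitations.
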