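# spinsight

Integrative spin-label analysis for detecting **minor conformational states of
membrane proteins** — built around the kind of evidence used to show that the
POTRA2 domain of the outer-membrane transporter FhaC makes large, spontaneous
excursions toward the extracellular side: DEER/PELDOR distance distributions,
PRE intensity-ratio statistics, R1rho relaxation dispersion, spin-label
rotamer modeling, and disulfide Cys-pair screening.

## Who this is for

Structural biologists and spectroscopists who have (or simulate) site-directed
spin-labeling data on a protein with a known "resting" structure and want to
ask, quantitatively: *do the measurements show states the crystal structure
cannot explain?*

## What it computes

**Label modeling (accessible volume).** An idealized MTSL/R1 template is
attached at the CB of a (possibly in-silico mutated) Cys site; the five linker
dihedrals are sampled uniformly and clashing conformers rejected
(`generate_ensemble()`, n = 200 by default). The paramagnetic center is the
N-O bond midpoint; `label_to_atom_distances()` gives mean-center distances to
chosen nuclei (e.g. Ile Cdelta1), `interlabel_distribution()` the predicted
DEER distribution of a site pair.

**DEER/PELDOR.** Signal model `V(t) = [1 - lambda + lambda K p] B(t)` with the
Fresnel-form powder kernel (`omega = 2 pi 52.04 / r^3` MHz nm^3). Pipeline:
tail background fit (`fit_background()`), optional multispin power scaling
(`power_scale()`), Tikhonov inversion with non-negativity, an exact unit-mass
moment constraint, L-curve alpha selection and joint refinement of the
modulation depth (`tikhonov_invert()`), plus the
`r_max = 5 (t_max/2)^(1/3)` advisory (`max_reliable_distance()`).

**PRE NMR.** Para/dia peak-intensity ratios with noise-propagated errors
(`compute_ratios()`), normalization to the maximum ratio
(`normalize_to_max()`), one-sided z tests for attenuation against reference
residues (`compare_attenuation()`), and classification against
structure-predicted distances (`classify_against_structure()`); discordant
residues are the minor-conformer candidates.

**R1rho dispersion.** Monoexponential decay fits per spin-lock field
(`fit_r1rho()`), R2,eff extraction with a measured R1 (`r2eff_from_r1rho()`),
and a weighted F test of flat vs fast-exchange Lorentzian dispersion
(`fit_dispersion()`, `analyze_dispersion()`).

**Screens.** CB-CB disulfide feasibility of engineered Cys pairs
(`assess_cys_pair()`) and native-MS peptide bound-fraction arithmetic with
decoy correction (`bound_fraction()`).

**Synthetic data.** Seeded generators for every stage — toy structures with
known geometry, DEER traces from known P(r), paired PRE tables from an r^-6
attenuation model, spin-lock series with and without exchange — each carrying
its truth table (`make_toy_structure()`, `make_deer_dataset()`,
`make_pre_dataset()`, `make_dispersion_dataset()`).

## Worked example

```r
library(spinsight)

# Predicted inter-label distribution on a synthetic two-site scaffold
sc <- make_toy_structure("two-site-scaffold", separation_A = 45)
e1 <- generate_ensemble(sc, "A:5",   n = 200, seed = 1)
e2 <- generate_ensemble(sc, "B:105", n = 200, seed = 2)
find_modes(interlabel_distribution(e1, e2))
#> [1] 4.5

# DEER round trip: Gaussian P(r) (4.5 nm, sigma 0.3), lambda 0.3, k 0.2/us, SNR 50
ds <- make_deer_dataset(noise_sd = 0.02, seed = 1)
bf <- fit_background(ds$trace)
round(c(lambda = bf$background$lambda, k = bf$background$k), 3)
#> lambda      k
#>  0.301  0.193
pr <- tikhonov_invert(bf$form_factor, lambda_mod = bf$background$lambda)
round(c(modes = find_modes(pr), mean = distribution_mean(pr)), 2)
#> modes1 modes2   mean
#>   3.62   4.44   4.59

# PRE: unequal para/dia scales, zero noise -> classification matches truth
pre <- make_pre_dataset(c(I8 = 8, I16 = 16, I24 = 24, I35 = 35, I45 = 45),
                        scale_para = 1.3, scale_dia = 0.9, seed = 1)
ratios <- normalize_to_max(compute_ratios(pre$para, pre$dia))
cls <- classify_against_structure(ratios,
         setNames(pre$truth$distance_A, pre$truth$residue_id))
all(cls$concordant)
#> [1] TRUE

# Dispersion: flat vs exchange
analyze_dispersion(make_dispersion_dataset(exchange = FALSE, seed = 1))$fit$model
#> [1] "flat"
analyze_dispersion(make_dispersion_dataset(exchange = TRUE, seed = 1))$fit$model
#> [1] "exchange"
```

The numbers shown are actual output (seed 1). A single trace at SNR 50
scatters: here the dominant mode sits at 4.44 nm next to a low side lobe, and
the distribution mean lands 0.09 nm above the truth — averaged over 10 seeds
the recovered mean is 4.52 nm (see `scripts/acceptance.R`). That per-trace
scatter is why summary statistics are seed-averaged throughout.

A full synthetic replication — ensembles, DEER inversion, PRE classification,
dispersion model selection, and a discordance table — runs with
`run_replication(list(seed = 1, outdir = "out"))`, or from the shell via the
thin CLI wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "spinsight.R", package = "spinsight"))') \
    replicate --seed 1 -o out/
```

## Methods

See the vignette (`vignettes/spin-label-conformer-analysis.Rmd`) for the
models, their assumptions, all tunable parameters with units and defaults,
the numerical choices in the inverse problem, what the synthetic generators
do and do not emulate, and known limitations.
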