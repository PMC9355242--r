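---
title: "Detecting minor membrane-protein conformers from spin-label data with spinsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting minor membrane-protein conformers from spin-label data with spinsight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinsight)
```

## The scientific problem

Omp85-family transporters such as the two-partner-secretion protein FhaC are
thought to work through large, spontaneous conformational excursions rather
than through an external energy source. Those excursions are *minor states*:
they are invisible to crystallography and to most ensemble-averaged
measurements. Site-directed spin labeling gives several complementary windows
onto them:

* **DEER/PELDOR** measures the distribution `P(r)` of distances between two
  nitroxide labels (roughly 1.8-8 nm), so extra peaks at unexpected distances
  reveal alternative conformers directly.
* **PRE NMR** bleaches the signals of nuclei that come within ~25-30 A of a
  paramagnetic label, even transiently, so residues attenuated "too much" for
  their crystal-structure distance report transient approaches.
* **R1rho relaxation dispersion** bounds the *time scale*: a statistically
  flat dispersion profile excludes chemical-shift-modulating exchange on the
  microsecond scale, pushing the motions to slower times.
* **Engineered Cys pairs** that form disulfides in vivo despite being far
  apart in the resting structure are an independent, in-cell reporter of the
  same motions.

Each of these comparisons needs a structure-based *prediction* of what the
resting conformation alone would give. spinsight implements both sides: the
predictions (rotamer ensembles of the MTSL label on a PDB structure) and the
measurements (DEER inversion, PRE ratio statistics, dispersion model
selection), plus seeded synthetic-data generators so that the entire pipeline
is testable without any experimental input.

## Label modeling (accessible volume)

The MTSL/R1 side chain is attached at the CB of a (possibly in-silico
substituted) cysteine. We use an explicit idealized template of the
cysteine-MTSL adduct — standard bond lengths and angles for the
S-S-CH2-linked 2,2,5,5-tetramethyl-pyrroline-1-oxyl ring, see
`r1_template_geometry()` — and sample its five linker dihedrals uniformly on
[0, 360) degrees. A conformer is kept if none of its heavy atoms comes within
`clash_tol` of a protein heavy atom outside the labeled residue. This is
accessible-volume (mtsslWizard-style) modeling: all sterically allowed
conformers are weighted equally, with no rotamer energies. The paramagnetic
center of each conformer is the N-O bond midpoint; predicted label-to-nucleus
distances use the *mean* center position over the ensemble (not an r^-6
average), matching how such predictions are reported alongside PRE data.

Tunables and defaults:

* `n = 200` conformers — the conventional ensemble size for this kind of
  prediction; distance summaries are stable well below that.
* `clash_tol = 2.5` A — the loose-tolerance regime typical of
  accessible-volume labeling tools. Tighter values bury moderately exposed
  sites; looser values admit physically impossible conformers.
* attempt budget `50 * n`; a site where no conformer survives is reported as
  buried rather than silently returning an empty ensemble.
* Sampling consumes a fixed five draws per attempt from a seeded stream, so
  ensembles are bitwise reproducible and requesting more conformers with the
  same seed only appends (prefix property) — convenient for convergence
  checks.

Inter-label predictions histogram all pairwise midpoint distances of two
ensembles on a 0.02 nm grid and smooth with a sigma = 0.05 nm Gaussian,
comparable to rotamer-library output granularity.

## DEER forward model and inversion

The four-pulse DEER signal is modeled as
`V(t) = [1 - lambda + lambda * (K p)] * B(t)` with the powder-averaged dipolar
kernel `K(t, r) = integral_0^1 cos[(3x^2 - 1) omega(r) t] dx`,
`omega(r) = 2 pi * 52.04 / r^3` (MHz, r in nm), evaluated in closed form with
Fresnel integrals; exchange coupling is neglected, as is universal for
nitroxides beyond ~1.5 nm. The background `B(t) = exp(-k t^(d/3))` defaults to
homogeneous three dimensions (`d = 3`); `d` is exposed because membrane-confined
spin distributions motivate `d < 3`.

Processing follows the standard sequence:

1. **Background fit** (`fit_background()`): log-linear least squares of the
   trace tail (default from 40% of `t_max`), modulation depth from the
   back-extrapolated intercept, form factor `f = (V/B - (1-lambda))/lambda`
   so that `f(0) = 1` exactly.
2. **Power scaling** (`power_scale()`): `f^(1/(n_spins - 1))` on the
   *background-corrected* signal, clipped at a 1e-3 floor, to suppress sum and
   difference combination frequencies in multispin samples. Default
   `n_spins = 2` is the identity.
3. **Tikhonov inversion** (`tikhonov_invert()`): minimize
   `||K p - f||^2 + alpha ||L2 p||^2` under `p >= 0`, with `L2` the second
   difference operator, solved by fast NNLS on the normal equations. Because
   the form factor is normalized, the solution's zeroth moment is known
   exactly (`sum(p dr) = f(0) = 1`); the solver enforces this as a weighted
   moment row. Without it, the non-negativity constraint rectifies noise into
   low-amplitude ghost lobes at short and long distances that barely change
   the fit but visibly bias the distribution's mean.

The regularization parameter comes from the L-curve: maximum curvature of the
(log residual, log seminorm) curve over a 40-point logarithmic ladder spanning
1e-4 to 1e4. Three numerical details matter. The curve is traced with the
plain non-negative Tikhonov solutions and only the final solve at the chosen
alpha carries the moment row — the corner is a property of the
residual-vs-smoothness trade-off, and the extra row deforms it. The two
branches are first projected onto their monotone envelopes (isotonic
regression), because with noisy data and an active-set solver the raw
sequences wiggle at the 1e-4 level and finite-difference curvature amplifies
that into corner misdetection. And the curvature is evaluated on the raw log
scales, not axis-normalized ones. We also evaluated refining the modulation
depth (and background rate) jointly with `P(r)` against the raw trace; the
joint likelihood is nearly degenerate — small background-parameter shifts
trade off against broad low-amplitude mass in `P(r)` — and the refinement
broadened noise-free reconstructions, so it was rejected in favor of the
fixed tail-window background fit plus the exact moment constraint.

An advisory ceiling `r_max = 5 (t_max / 2)^(1/3)` nm marks where the dipolar
evolution window stops defining distances reliably; distributions are flagged
beyond it, never truncated.

**What the round trip does and does not show.** With the synthetic conditions
used throughout (Gaussian `P(r)` mean 4.5 nm, sigma 0.3 nm, lambda 0.3,
k 0.2 per us, t_max 3.2 us, 320 points, trace SNR 50), the
simulate-fit-invert loop recovers the distribution mean to better than 0.1 nm
*averaged over seeds*; single noise realizations scatter by roughly
+/- 0.2 nm, dominated by low-amplitude lobes that the data genuinely cannot
exclude at this SNR. Real data add pump-efficiency variation, orientation
selection and deuterium modulation, none of which the generator emulates, so
agreement here validates the numerics, not spectrometer reality.

## PRE ratio statistics

Ratios `I_para / I_dia` carry arbitrary per-sample scale factors (different
reconstitution and rotor-fill amounts, different inter-scan relaxation), so
they are normalized to the maximum observed ratio — in practice a residue far
outside the ~25-30 A PRE radius, which is therefore PRE-unaffected. Errors
propagate from the spectral noise RMS to the ratio
(`sigma = ratio * sqrt((n_p/I_p)^2 + (n_d/I_d)^2)`) and attenuation is tested
one-sidedly: `z = (ref - ratio) / sqrt(sigma_ref^2 + sigma^2)` against the
error-weighted mean of reference residues, `p = 1 - Phi(z)`. The z statistic
is exactly invariant to the normalization constant, so normalization affects
presentation, not inference. First-order (delta-method) propagation assumes
small relative noise; at intensity SNR below ~20 the ratio distribution grows
visibly skewed and the test becomes mildly anticonservative — the type-I
calibration in the test suite therefore simulates at SNR 100, where the
method's own normality assumption holds.

Classification against structure flags residues as *expected* attenuated
within a detection radius (default 25 A) and *observed* attenuated below a
normalized-ratio threshold (default 0.7, a documented choice — the analysis
uses only relative attenuation and printed distance bounds, never a
quantitative ratio-to-distance inversion). Discordant residues — strongly
attenuated yet predicted far — are the minor-conformer candidates. Overlapped
peaks can be carried as merged ids (`"I252+I420"`) and classify by the
minimum of their component distances.

## R1rho dispersion

Per spin-lock field, decays over the duration ladder are fit
monoexponentially; `R2,eff` is extracted with a separately measured `R1` via
the tilted-frame relation `R2,eff = (R1rho - R1 cos^2 theta) / sin^2 theta`
(`theta = 90` degrees on resonance). Model selection compares the flat model
`R2,eff = R2_0` with the minimal fast-exchange on-resonance Lorentzian
`R2,eff = R2_0 + phi k_ex / (k_ex^2 + (2 pi nu1)^2)` by a weighted F test,
`F = ((RSS_flat - RSS_ex)/2) / (RSS_ex/(n-3))`, exchange selected at
`p < 0.05`. For fixed `k_ex` the exchange model is linear in
`(R2_0, phi/k_ex)`, so the fit profiles `k_ex` over a log grid with a
golden-section refinement — the global weighted optimum without nonlinear
optimizer fragility, and `RSS_ex <= RSS_flat` by construction. Because
`k_ex` is unidentifiable under the null and the amplitude is effectively
boundary-constrained, the F(2, n-3) reference is approximate and the test
runs conservative (empirical false-positive rate ~2-5% at nominal 5%) — the
safe direction for declaring dispersions "statistically flat".

## Synthetic data: what it emulates

* `make_toy_structure()`: ideal poly-Ala helices (phi = -57, psi = -47) — an
  exposed site, a two-site scaffold with an exact CB-CB separation and label
  arms oriented perpendicular to the separation axis (so the inter-label mode
  sits at the designed distance), and a site caged inside pseudo-atom shells
  that rejects every label conformer.
* `make_deer_dataset()`: multi-Gaussian `P(r)` through the module's own
  forward model plus Gaussian trace noise. It shares the kernel with the
  inversion, so round trips validate processing, not kernel theory — the
  kernel itself is validated against brute-force quadrature instead.
* `make_pre_dataset()`: `I_para/I_dia = exp(-tau r^-6)` — the simplest
  Solomon-Bloembergen-consistent attenuation — with tau calibrated so the
  ratio at 25 A is 0.5, distinct global para/dia scales (emulating unequal
  protein amounts, the reason normalization-to-maximum exists), a 1e-3 ratio
  floor standing in for the detection limit on bleached peaks, and additive
  intensity noise. The default true distances {8, 12, 16, 20, 24, 30, 35,
  40, 45} A straddle the detection radius while avoiding the narrow band
  (25-28 A) where a 25 A radius and a 0.7 ratio threshold intrinsically
  disagree.
* `make_dispersion_dataset()`: spin-lock decays from the rotating-frame
  average of `R1` and `R2,eff(nu1)`, with the experimentally typical ladders
  (1.2-10 kHz; 2.5-80 ms) and fractional intensity noise; exchange scenario
  defaults `R2_0 = 20` per s, `phi = 5e5` per s^2, `k_ex = 1e4` per s.

Every generator is a pure function of its arguments and seed (bitwise
reproducible), and every dataset carries its truth table, so downstream
checks are self-contained.

## Design choices made where the design was open

* **Chain selection on real structures**: the first chain containing the
  addressed residue is used; author numbering throughout, no renumbering.
* **Altloc policy**: highest occupancy, first on ties — deterministic parsing.
* **Disulfide feasibility**: CB-CB <= 5.5 A, a standard engineering
  criterion; the screening logic only needs "far apart in the resting
  conformation", so the exact cutoff is uncritical and exposed.
* **Effective spin count** for power scaling defaults to 2 (identity):
  doubly-labeled samples dominate, and scaling is only applied on request.
* **F-test alpha** defaults to 0.05; **PRE detection radius** to 25 A;
  both exposed as arguments.
* **Problem sizes** in tests and the acceptance script — 10-seed DEER round
  trips, 1e4 PRE null draws, 100-seed dispersion batches, 50 x 50 kernel
  oracle grids — were sized to give stable statistics for each check.

## Known limitations

* Accessible-volume ensembles ignore rotamer energetics; sites in partially
  occluded pockets get more uniform arm distributions than a weighted library
  would predict.
* The DEER module does not read vendor binary formats, perform phase
  correction, fit multi-Gaussian models, or compute uncertainty bands for
  `P(r)`; single-trace means at realistic SNR scatter accordingly.
* PRE analysis is deliberately order-level: no distance extraction from
  ratios, no Gamma2 fitting.
* Off-resonance dispersion (general tilted-frame exchange expressions) and
  CPMG experiments are out of scope.

## A worked synthetic replication

```{r replication, eval = FALSE}
report <- run_replication(list(seed = 1))
report$deer$recovered_modes_nm   # modes of the inverted synthetic trace
report$pre$concordance           # 1.0 on the zero-noise scenario
sapply(report$dispersion, `[[`, "selected")  # "flat", "exchange"
```

The same driver accepts a YAML configuration (`load_config()`), writes JSON
and Markdown reports when `outdir` is set, and backs the `spinsight`
command-line wrapper shipped under `inst/cli`.
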