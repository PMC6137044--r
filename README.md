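# sptfrap

Quantitative analysis of live-cell fluorescence microscopy for
surface-immobilized cells and synthetic vesicles. The package is aimed at
microscopists who need to (a) verify that an immobilization protocol actually
keeps cells still at pixel resolution, and (b) measure membrane mobility in
the immobilized samples by single-particle tracking (SPT) and fluorescence
recovery after photobleaching (FRAP).

## What it computes

**Drift quantification.** Residual cell movement between consecutive frames
by FFT cross-correlation: the integer shift at the peak of
F⁻¹[F(B)·conj(F(A))], reported per frame pair in whole pixels.

**Two-population CPD analysis.** Single fluorescent membrane proteins are
detected (discoidal averaging filter, inner radius 1 px / outer radius 3 px),
localized to sub-pixel precision, and linked into trajectories. The cumulative
probability distribution (CPD) of squared step sizes r² at lag t is fitted
with the two-population 2D Brownian mixture

    P(r², t) = 1 − α·exp(−r²/(4·D₁·t)) − (1−α)·exp(−r²/(4·D₂·t)),

yielding the mobile fraction α and the apparent diffusion coefficients
D₁ ≥ D₂ (mobile / immobile), with seeded-bootstrap standard errors.

**Eisosome distance mapping.** Marker blink localizations are condensed into
one centroid per eisosome (single-linkage clustering); each protein
localization is assigned the Euclidean distance to its nearest centroid and
the distances are histogrammed, optionally split by mobility population.

**FRAP.** Recovery traces are normalized to the pre-bleach plateau and fitted
with F(t) = F₀ + (F∞ − F₀)(1 − exp(−ln2·t/t½)); the mobile fraction is
(F∞ − F₀)/(1 − F₀) and the lateral diffusion coefficient follows from
D = γ·w²/(4·t½) for a circular bleach spot of radius w (γ = 0.88 by default).

Because the original raw microscopy data are not deposited, the package
includes a seeded synthetic-data generator (`simulate_*` functions, presets
via `sim_preset()`) that emulates the acquisition settings with known ground
truth; all validation is parameter recovery against that truth.

## Worked example

Simulate 5,000 single-lag steps at the packaged APTES-glutaraldehyde yeast
preset (mobile fraction 0.57, D₁ = 5.1e-4 µm²/s, D₂ = 1e-5 µm²/s, 10 s lag)
and fit the two-population model:

```r
library(sptfrap)
pre  <- sim_preset("aptes_yeast")
sim  <- simulate_trajectories(pre$params, n_particles = 5000, n_steps = 1,
                              dt_s = pre$dt_s, seed = 42)
steps <- step_sizes(sim$trajectories, lag_frames = 1,
                    frame_interval_s = pre$dt_s)
fit <- fit_cpd_two_population(empirical_cpd(steps), n_boot = 200)
fit
#> <cpd_fit> n = 5000 steps, lag 10 s
#>   mobile fraction: 0.566 (SE 0.00846)
#>   D_mobile:   0.0005191 um^2/s (SE 1.12e-05)
#>   D_immobile: 1.048e-05 um^2/s (SE 3.1e-07)
#>   residual norm: 0.1412
```

The fit recovers the generating mobile fraction (0.566 vs 0.57, within one
bootstrap SE) and apparent mobile diffusion coefficient (5.19e-4 vs
5.1e-4 µm²/s, within 2%).

A noisy FRAP trace at the GUV liquid-disordered preset (mobile fraction 0.82,
halftime 196 ms, 2% Gaussian noise):

```r
pre <- sim_preset("frap_guv_ld")
sim <- simulate_frap_trace(pre_level = 1, bleach_depth = pre$bleach_depth,
                           mobile_fraction = pre$mobile_fraction,
                           t_half_s = pre$t_half_s, n_pre = pre$n_pre,
                           n_post = pre$n_post, dt_s = pre$dt_s,
                           noise_sd = 0.02, seed = 7)
fit_recovery(normalize_trace(sim$trace), gamma = pre$gamma)
#> <frap_fit> 120 post-bleach samples
#>   mobile fraction: 0.806   t_half: 206.3 ms   D: 0.267 um^2/s
#>   f0 = 0.417, f_inf = 0.887, residual norm 0.187
```

Single noisy traces scatter around the generating values; averaged over many
seeds the estimates are unbiased (see the test suite and acceptance script).

A command-line wrapper with subcommands `simulate`, `drift`, `track`,
`cpdfit`, `eisodist`, `frap` and `run` lives at `inst/cli/sptfrap`; the
vignette in `vignettes/membrane-mobility-analysis.Rmd` documents the models,
parameter choices and limitations.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from fresh seeded simulations at the packaged presets, the mean
fitted mobile fractions and mobile diffusion coefficient for the two yeast
SPT presets (10 seeds × 5,000 steps each) and the mean fitted FRAP mobile
fraction and recovery halftime for the GUV preset (50 noisy seeds), and
writes them as JSON keyed t1–t5.
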