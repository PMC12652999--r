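# anapquench

Analysis pipeline for detecting serotonin (5-HT) and dopamine (DA) binding
through quenching of the fluorescent non-canonical amino acid ANAP
(l-3-(6-acetylnaphthalen-2-ylamino)-2-aminopropanoic acid). ANAP can be
incorporated co-translationally into a receptor binding site by amber
stop-codon suppression; when 5-HT occupies the site it quenches ANAP by
short-range photoinduced electron transfer, so the fluorescence loss reports
ligand occupancy in real time. The package implements the three quantitative
workflows such an assay rests on, plus seeded synthetic-data generators that
emulate every input, so the whole pipeline is verifiable end to end by
parameter recovery without any instrument data.

## What it computes

**Solution quenching (steady state).** Blank-subtracted emission spectra are
optionally corrected for the inner-filter effect,

    F(λ) = F_obs(λ) · 10^((0.2·OD_ex + OD_em(λ)) / 2),

band-averaged (445–455 nm), and fitted to the Stern–Volmer relation

    F0 / F = F_intercept + K_sv · [Q],

where the slope K_sv (M⁻¹) measures collisional quenching efficiency.

**Time-resolved kinetics.** Fluorescence lifetimes shorter than the 8 ns
excitation pulse are estimated by iterative reconvolution: the trace is fit
to a convolution of the measured instrument response function (IRF) with an
exponential decay (or biexponential / second-order 1/(1+kt) alternatives,
ranked by BIC). Transient-absorption traces are assembled from raw
intensities as

    ΔOD(t) = −log10( (I_pumped(t) − I_fluorescence(t)) / I_unpumped(t) ),

masked over the detector-saturation artifact, and fitted the same way; a
late-time residual plateau distinguishes a fully reversible charge-transfer
product from a permanent photoproduct.

**Cell binding curves.** Per cell: a single-exponential photobleach model is
fitted to five agonist-free PRE exposures and divides it out of all later
spectra; ANAP band intensities per concentration are normalized to span the
applied range; pooled points across cells are fitted with the modified Hill
equation in log10 concentration,

    F_norm(c) = F_min + (F_max − F_min) / (1 + 10^(h·(log10 EC50 − log10 c))),

with the slope factor h negative for quenching, and a seeded bootstrap over
cells giving 95% confidence intervals.

## Worked example

```r
library(anapquench)

cfg <- sim_config(seed = 11)            # ground truth for all generators

# solution quenching: 8-concentration 5-HT titration with noise
sim <- simulate_titration(cfg)
fit <- fit_stern_volmer(sv_ratios(sim$series))
fit
#> Stern-Volmer fit: K_sv = 13.19 per M, intercept = 0.9804, R^2 = 1 (n = 7)

# TRPL lifetime through an 8 ns FWHM IRF on 0.4 ns bins (Poisson noise)
trpl <- simulate_trpl(cfg, "anap")
fit_reconvolution(trpl$trace, trpl$irf, model = "exp1")
#> Reconvolution fit (exp1): tau = 2.775 ns; t0 = -1.57e-07 ns,
#>   reduced chi-sq = 0.007662, AICc = -972.9

# cell binding: 6 noisy cells, bleach-corrected, pooled Hill fit
res <- fit_binding(simulate_cell_series(cfg), bootstrap = 1000, seed = 11)
res$hill
#> Hill fit (cell): EC50 = 5.364e-07 M, slope = -0.4718, fmax = 1.163, fmin = -0.1006
#>   95% CI (bootstrap 1000 over cells): EC50 [3.251e-07, 8.85e-07] M,
#>   slope [-0.5254, -0.4183]
```

The titration was generated with K_sv = 13.3 M⁻¹ and intercept 0.98; the
noisy fit returns 13.19 and 0.980. The TRPL trace was generated with
τ = 2.776 ns and is recovered as 2.775 ns even though the excitation pulse
is three times longer than the lifetime. The cells were generated with
EC50 = 594 nM and h = −0.46; the noisy pooled fit returns 536 nM and −0.47
with the generating values inside the bootstrap intervals. The free
asymptotes (fmax, fmin) absorb the affine residue that range-normalization
leaves on a shallow curve.

A command-line wrapper over the same functions lives at
`inst/cli/anapquench.R` with subcommands `simulate`, `sv`, `trpl`, `tas`
and `bind`.

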