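# hpmrf

MR fingerprinting (MRF) for hyperpolarized [1-¹³C]pyruvate MRI: simulate
metabolite-specific bSSFP/GRE acquisitions from a two-pool Bloch-McConnell
exchange model, build pyruvate-to-lactate conversion-rate (k_PL)
dictionaries, estimate k_PL by complex template matching, and characterize
the estimator by Monte Carlo precision analysis, fixed-parameter
sensitivity sweeps, and voxel-wise mapping on synthetic dynamic images.

## Who this is for

Hyperpolarized ¹³C-pyruvate imaging measures the apparent first-order
conversion rate k_PL (s⁻¹) of pyruvate to lactate — an in vivo marker of
glycolytic metabolism. The magnetization is non-renewable: it decays with
T₁ and is consumed by every excitation, so acquisition design (flip-angle
schedules, balanced SSFP vs. spoiled GRE readouts) and estimator choice
interact strongly with the precision of k_PL. This package is for sequence
developers and kinetic-modeling researchers who want to prototype such
designs and quantify estimator bias and variance before going to the
scanner.

## The model in brief

Two magnetization pools with one-way exchange, per isochromat:

    dP+/dt = (−1/T₂P − k_PL + i·2π f_P) P+
    dL+/dt = (−1/T₂L        + i·2π f_L) L+ + k_PL P+
    dPz/dt = (−1/T₁P − k_PL) Pz + u(t)
    dLz/dt = −Lz/T₁L + k_PL Pz

with a gamma-variate bolus input u(t), instantaneous spectrally selective
RF rotations, and a Lorentzian intravoxel off-resonance distribution. The
propagator is an exact matrix exponential per piecewise-constant interval
(compiled kernel). A dictionary holds one unit-norm fingerprint per k_PL
on a 0–0.1 s⁻¹ grid at 10⁻⁴ s⁻¹ resolution (1001 entries); matching
returns the entry with the largest magnitude complex inner product.

Three interleaved experiment designs are built in: `mrf_sigmoid`
(variable-flip 5°→80° pyruvate bSSFP), `mrf_constant` (30° pyruvate
bSSFP) and `hybridgre` (10° spoiled GRE pyruvate), all with 60° lactate
bSSFP. See the methods vignette (`vignettes/hpmrf-methods.Rmd`) for the
assumptions and design decisions, including the per-block echo
aggregation and excitation-count conventions that set the absolute signal
scale.

## Worked example

```r
library(hpmrf)

sched <- build_schedule("mrf_sigmoid")
sched
#> <sequence_schedule> mrf_sigmoid: 15 pyruvate + 15 lactate blocks,
#>   interleave period 4.1 s, nominal duration 60 s

dict <- generate_dictionary(dictionary_spec(sched))
dict
#> <mrf_dictionary> mrf_sigmoid: 1001 entries, kPL 0..0.1 1/s (step 0.0001), 30 samples

# simulate a noisy acquisition at a true kPL of 0.0237 1/s and match it
sim   <- fingerprint_simulator(sched)
noisy <- add_noise(sim(0.0237), noise_spec(sigma = 0.1, seed = 42), draw_index = 1)
match_fingerprint(noisy, dict)
#> <mrf_match> kPL = 0.0245 1/s (entry 246, score 4.262)

# Monte Carlo precision of the estimator
mc <- run_monte_carlo(dict, sigmas = c(0.1, 0.3), n_iter = 2000, seed = 7,
                      kpl_subset = c(0.01, 0.05))
as.data.frame(mc)[, c("kpl_true", "sigma", "mean_kpl", "bias_pct", "cv_pct")]
#>   kpl_true sigma mean_kpl bias_pct cv_pct
#> 1     0.01   0.1   0.0100   0.2335   6.46
#> 2     0.01   0.3   0.0100   0.4430  19.52
#> 3     0.05   0.1   0.0500   0.0903   3.43
#> 4     0.05   0.3   0.0506   1.2465  11.10

# cost of a wrong fixed parameter: sweep true T1 of pyruvate 20..40 s
sens <- run_sensitivity(sensitivity_spec("T1_pyr"), dict)
attr(sens, "max_abs_error")
#> [1] 0.004
```

Reading the output: at a noise SD of 0.1 (relative to the relaxation-free
total bolus signal) the matched estimates at k_PL = 0.05 s⁻¹ are unbiased
to within 0.1% with a coefficient of variation of about 3.4%; quadrupling
k_PL noise sensitivity at the low end (CV 6.5% at 0.01 s⁻¹) reflects the
smaller lactate signal there. If the dictionary's assumed pyruvate T₁
(30 s) is wrong by up to ±10 s, the resulting k_PL error stays below
0.004 s⁻¹ (20% of the simulated truth).

A thin command-line wrapper over the same functions is installed at
`inst/cli/hpmrf` (subcommands `schedule`, `dictionary`, `match`,
`montecarlo`, `sensitivity`, `phantom`, `fit`, `compare`).

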