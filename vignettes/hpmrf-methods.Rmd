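---
title: "Signal model and estimation methods in hpmrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal model and estimation methods in hpmrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hpmrf` estimates the apparent pyruvate-to-lactate conversion rate
$k_{PL}$ (s$^{-1}$) from hyperpolarized [1-$^{13}$C]pyruvate MRI by MR
fingerprinting (MRF): a forward signal model generates a dictionary of
candidate signal evolutions over a grid of $k_{PL}$ values, and an observed
signal is assigned the $k_{PL}$ of the dictionary entry with the largest
magnitude complex inner product. This vignette records the model, its
assumptions, and the design decisions behind the implementation.

## The two-pool Bloch-McConnell model

Each voxel is described by two magnetization pools, pyruvate and lactate,
with one-way chemical exchange $P \rightarrow L$ at rate $k_{PL}$. Between
RF pulses each isochromat evolves as

$$
\begin{aligned}
\dot P_+ &= \left(-1/T_{2P} - k_{PL} + i\,2\pi f_P\right) P_+ \\
\dot L_+ &= \left(-1/T_{2L} + i\,2\pi f_L\right) L_+ + k_{PL} P_+ \\
\dot P_z &= \left(-1/T_{1P} - k_{PL}\right) P_z + u(t) \\
\dot L_z &= -L_z / T_{1L} + k_{PL} P_z ,
\end{aligned}
$$

where $P_+ = P_x + iP_y$, the exchange term acts on all three components of
the pyruvate pool (balanced acquisitions carry exchanged transverse
coherence), and $u(t)$ is the bolus inflow. Hyperpolarized magnetization is
non-renewable, so there is no recovery term: every RF excitation and every
$T_1$, $T_2$ loss is permanent. Because the system is block-triangular and
piecewise linear, the propagator over any interval has closed-form
matrix-exponential entries; the compiled kernel applies them exactly, and a
fine-step forward-Euler integration is used as an independent oracle in the
test suite.

Units: all signals are expressed relative to a total bolus input of 1 (the
relaxation-free total bolus signal), so noise standard deviations are
directly in that scale.

Default fixed parameters (the dictionary's nuisance values): chemical
shifts $f_P = 0$, $f_L = 392$ Hz; $T_{1P} = 30$ s, $T_{1L} = 25$ s,
$T_{2P} = 0.5$ s, $T_{2L} = 1$ s; bolus arrival $-4$ s (before acquisition
start), duration 12 s; intravoxel linewidth 5 Hz.

### Bolus input

The inflow is a gamma-variate rate
$u(t) \propto (t - t_a)^{\alpha - 1} e^{-(t - t_a)/\beta}$ with shape
$\alpha = 2$ by default; $\beta$ is set so that 99% of the input arrives
within the stated bolus duration. The shape is configurable because only
arrival and duration are well constrained experimentally. During the active
bolus window the inhomogeneous term is integrated by the exact solution for
a piecewise-constant rate on 10 ms sub-steps (the gamma inflow has no
elementary closed form under the full system matrix); the residual
integration error is $O(\Delta t^2) \approx 10^{-6}$ of the total input.

### Off-resonance and field imperfections

Intravoxel $B_0$ inhomogeneity is modeled by `n_isochromats = 101`
frequency offsets placed at equally spaced quantiles of a Lorentzian line
of configurable FWHM, truncated at $\pm 3\times$FWHM (a Gaussian line is
config-selectable; the count is odd so the on-resonance isochromat always
exists). A bulk $B_0$ error adds to both metabolite frequencies; a $B_1$
scale multiplies every flip angle. RF pulses are instantaneous and ideally
spectrally selective: a pulse rotates only its target metabolite, about an
axis that co-rotates with that metabolite's reference frequency, and echo
samples are demodulated at the same reference. Finite pulse durations enter
only through the TR/readout timing.

## Acquisition designs

Three interleaved metabolite-specific designs are built by
`build_schedule()`:

* **MRF-Sigmoid** - pyruvate 3D bSSFP with flip angles following the
  logistic schedule $\alpha(t) = \alpha_{min} + (\alpha_{max} -
  \alpha_{min}) / (1 + e^{t_{mid} - t})$ with defaults
  $5^\circ \rightarrow 80^\circ$ and midpoint 20 s, evaluated at each
  excitation's absolute time; TR 15.6 ms.
* **MRF-Constant** - identical, with constant $30^\circ$ pyruvate flips.
* **HybridGRE** - pyruvate multi-slice spoiled GRE at $10^\circ$ with 1 s
  slice-revisit time and 22 ms readout.

All lactate blocks are bSSFP at $60^\circ$, TR 15.3 ms. Pyruvate and
lactate blocks alternate within each interleave period (4.1 s for the MRF
designs, 4.6 s for HybridGRE; a 60 s window gives 15 + 15 and 13 + 13
samples respectively). bSSFP excitation phase alternates 0/180 degrees, and
each block is book-ended by `n_cat = 10` catalyzation/de-catalyzation
pulses with a $\sin^2$ amplitude profile tied to the first/last imaging
tip; residual transverse magnetization is crushed between blocks so
magnetization is stored longitudinally across the interleave.

Two encoding choices deserve comment because the nominal protocol does not
fully determine them:

* **Excitations per block.** The slab geometry (33.6 cm at 21 mm) implies
  16 through-plane encodes with a single-shot in-plane readout per TR, so
  `n_exc = 16` by default; it is exposed in the schedule configuration and
  any reported statistic should be read alongside it.
* **The block sample.** The recorded complex sample of a block is the
  coherent sum of all acquired imaging echoes (receiver phase following
  the transmit phase cycling), with the center excitation's echo time as
  its time stamp. A reconstructed image voxel aggregates the signal of the
  whole encode train, and a single-echo convention would discard almost
  all of the information the acquisition collects - with 30 samples of
  amplitude $\le 1$ and channel noise 0.1, the Cramer-Rao bound on the
  $k_{PL}$ CV would sit near 50%, an order of magnitude above what these
  acquisitions achieve in practice. Catalyzation pulses are preparation
  only and are not sampled. For the multi-slice GRE block the model drives
  all 16 slice excitations (spaced TR/16) through the same two-pool
  system, as a non-spatially-resolved signal model must; this convention
  makes the GRE pyruvate sample an aggregate as well, and is the main
  caveat when comparing absolute pyruvate amplitudes (e.g. AUC ratios)
  between GRE and bSSFP designs.

## Dictionary and matching

`generate_dictionary()` simulates one fingerprint per grid value
($k_{PL}$ from 0 to 0.1 s$^{-1}$ in steps of $10^{-4}$; 1001 entries) and
stores unit-$L_2$-norm rows plus the raw norms, so matched amplitudes can
be recovered. The fingerprint vector concatenates pyruvate samples then
lactate samples. Matching maximizes $|\langle s, e_k\rangle|$ with the
conjugate-linear inner product; ties break toward the lowest $k_{PL}$
(deterministic and conservative), and an all-zero signal is rejected rather
than matched. Matching is invariant to any nonzero complex scaling of the
signal. Noise-free signals simulated off-grid match to within one grid
step.

`direct_fit()` provides the conventional comparator: bounded nonlinear
least squares over $k_{PL}$ alone, minimizing magnitude residuals
(acquired phase is reference-dependent; a complex-residual flag exists),
multi-started from 0.005, 0.02 and 0.06 s$^{-1}$. Because the objective is
a single bounded scalar, the Monte Carlo comparison driver
(`compare_fit_methods()`) evaluates the same objective exhaustively on the
dictionary grid - the global optimum of the identical problem at the grid
resolution - which makes thousands of fits cheap; agreement between the
two routes is asserted in the tests.

## Monte Carlo and sensitivity analyses

`run_monte_carlo()` adds i.i.d. Gaussian noise of SD $\sigma$ to the real
and imaginary parts of the raw (amplitude-true) fingerprint, re-matches
against the unit-norm dictionary, and summarizes mean, SD, percent bias and
CV per $(k_{PL}, \sigma)$. Noise is added to raw rather than normalized
signals because $\sigma$ is defined on the amplitude scale of the bolus.
Each $(k_{PL}, \sigma)$ combination derives its own RNG stream from the
master seed, so any subset of combinations reproduces identically
regardless of execution order. Estimates at interior grid points are
unbiased to within sampling error; entries near the grid bounds show the
expected truncation bias of the argmax estimator.

`run_sensitivity()` quantifies the cost of fixing nuisance parameters:
noise-free signals at $k_{PL} = 0.02$ s$^{-1}$ are simulated with one
parameter perturbed and matched against the unperturbed dictionary,
reporting signed `fitted - true` errors over 21 equally spaced test values.
Default ranges: $T_{1P}$ 20-40 s, $T_{1L}$ 15-30 s, $T_{2P}$ 0.3-0.7 s,
$T_{2L}$ 0.6-1.4 s, $B_1$ scale 0.8-1.2, $B_0$ offset $\pm 15$ Hz,
linewidth 0.2-9.8 Hz. The bolus-timing ranges are a package choice (no
standard protocol pins them down): arrival $-8$ to $0$ s and duration 8 to
16 s, i.e. $\pm 4$ s about the nominal values, comparable to the relative
spans of the other parameters.

## Synthetic dynamic images

`generate_phantom()` emulates interleaved dynamic metabolite volumes: two
ellipsoidal "kidney" ROIs with distinct conversion rates on a
zero-conversion background, each voxel following the same forward model,
plus complex Gaussian noise added independently per voxel, channel and
frame. It deliberately omits features of real data: partial-volume mixing,
perfusion/flow compartments, spatial $B_0$/$B_1$ gradients, coil
sensitivity profiles, motion, and reconstruction artifacts. Passing
phantom tests therefore demonstrates the correctness of the fitting
pipeline (masking, AUC, TTP alignment, Pearson/Bland-Altman agreement,
voxel-wise matching), not robustness to those confounds. The SNR mask
threshold defaults to peak pyruvate SNR $\ge 5$; time-to-peak is the
argmax of the voxel magnitude curve, and the cross-experiment alignment of
dynamic AUC SNR curves shifts whole frames (nearest) because the two
temporal grids differ.

## Numerical choices and degenerate inputs

* Propagator entries use series-stabilized forms of
  $(e^{a\Delta t} - 1)/a$ and $(e^{a\Delta t} - e^{b\Delta t})/(a - b)$,
  so $T_1, T_2 \rightarrow \infty$, $k_{PL} = 0$ and coincident rates are
  exact rather than 0/0.
* Negative evolution times, overlapping blocks, unknown metabolite
  targets, empty noise-level lists, all-zero signals and degenerate
  $k_{PL}$ grids raise errors at the boundary rather than propagating NaN.
* Dictionary generation is noise-free and bit-reproducible; the on-disk
  cache is keyed by a content hash of the generating specification.
* Sub-seeds derived from the master seed stay below $2^{31}$.

## Problem sizes

The test suite and the acceptance script size the stochastic studies as
follows: point statistics at $n$ = 2,000-10,000 iterations per
$(k_{PL}, \sigma)$; pooled bias fractions on a 101-point grid subsample at
$n$ = 1,000 per point and three noise levels; the direct-fit comparison at
21 grid points $\times$ 100 iterations at $\sigma = 0.2$; phantoms of
$12 \times 12 \times 2$ voxels. These sizes keep every Monte Carlo
standard error well below the tolerances being asserted.

## Known limitations

* Single one-way exchange pair only: no alanine, bicarbonate or
  pyruvate-hydrate pools, and no perfusion compartment.
* Nuisance parameters are fixed at matching time; $k_{PL}$ is the only
  estimated dimension, so bolus-timing errors propagate into $k_{PL}$ (the
  sensitivity module quantifies this).
* The echo-train aggregation convention above determines the absolute
  signal scale; statistics that depend on that scale (CVs at a given
  $\sigma$, SNR ratios between GRE and bSSFP designs) should be compared
  across conventions with care.
* No k-space trajectory or reconstruction modeling; spatial encoding is
  abstracted into the per-block echo aggregate.
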