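---
title: "Constrained low-rank removal of photocurrent artifacts: model, algorithm and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained low-rank removal of photocurrent artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

Voltage-clamp snippets from an optogenetic mapping experiment are stacked
into an N×T matrix **Y** after rectification (inward current positive,
sub-zero deflections clipped as noise). The package models the direct
photocurrent artifact as a constrained low-rank term:

    Y = X + U_base V_base + U_stim V_stim + β 1ᵀ

* `U_stim V_stim` — the current trial's artifact: one (optionally two)
  temporal waveform(s), scaled per trial. The biophysical premise is that
  the artifact arises in a single patched cell, so its waveform is nearly
  stereotyped within an experiment while its amplitude varies with laser
  power and stimulus position.
* `U_base V_base` — a rank-one, exponentially decaying term for
  photocurrent left over from the *previous* trial: at 30–33 ms
  inter-stimulus intervals, slow opsin variants have not relaxed by the
  next stimulus.
* `β 1ᵀ` — per-trial constant offsets (corrupted baselines).
* **X** — the postsynaptic currents (PSCs) of interest.

Three families of constraints make the decomposition identifiable:

1. **Nonnegativity** of all factors (currents are rectified).
2. **Underapproximation**: artifact + baseline + offsets ≤ Y elementwise.
   Since PSCs and photocurrents sum approximately linearly under voltage
   clamp, the artifact should never exceed the recorded trace; this stops
   the low-rank term from swallowing PSCs riding on top of it.
3. **Exponential decay** `v_i ≤ γ v_{i−1}`: everywhere for the baseline
   waveform (it can only be a relaxing tail), and from `t3` (10 ms after
   stimulus offset) for the stimulus waveforms, so the tail cannot absorb
   the *next* trial's currents.

Fitting is two-step. **Step one** works on the integration window `[0, t2]`
(up to ~5 ms after laser onset): photocurrents switch on instantly with the
laser while monosynaptic PSCs need ≥ ~3 ms (spike initiation plus synaptic
delay), so weights learned here reflect artifact strength, not synaptic
strength. A few (default 10) coordinate-descent sweeps cycle through
baseline term, offsets and stimulus components; a sweep that increases the
residual (the rank-one subproblems are solved inexactly) is rolled back, so
the step-one residual is non-increasing. **Step two** freezes all weights
and offsets and re-fits full-length waveforms under the same constraints,
deflating components in order of decreasing energy.

Each rank-one subproblem is solved by ADMM with two splits — the residual
split `Y − uvᵀ = R ≥ 0` carrying the underapproximation, and `q = v`
carrying the decay constraint via an exact Euclidean projection onto
γ-decreasing vectors (pool-adjacent-violators generalized to exponential
decay; computed by the C++ core in `O(T)`).

Trials are processed in batches of ~200, ordered by their signal sum during
stimulation ("energy"): artifact kinetics co-vary slightly with power, and
batching groups trials whose artifacts a rank-one term can describe.
Batches much smaller than ~200 risk over-subtracting PSCs (a reliable PSC
family can masquerade as the dominant rank-one structure of a small batch).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `gamma` | 0.999 | per sample at 20 kHz | upper bound on waveform decay rate; rescaled as `γ^(20000/fs)` at other rates so the implied time constant is rate-invariant |
| `integration_window_ms` | min(pulse, 5) | ms | window for learning weights; longer removes more artifact but risks low-latency PSCs |
| `t3_offset_ms` | 10 | ms after stimulus offset | start of the enforced decay on stimulus waveforms |
| `rank` | 1 | — | artifact components per batch; 2 only when artifacts dwarf PSCs |
| `batch_size` | 200 | trials | energy-sorted batch size |
| `coord_iters` | 10 | sweeps | step-one coordinate descent (top of the useful 5–10 range) |
| `admm$rho` | 1 (adaptive) | — | penalty after max-scaling each batch |
| `admm$tol` | 1e-4 | relative | iterate/residual convergence tolerance |
| `noise_margin` | 3 | noise SDs | underapproximation slack (below) |
| `stim_floor` | 3 | noise SDs | component evidence guards (below) |

## Numerical choices

**Penalty adaptation and iteration cap.** With a fixed ρ = 1 the ADMM
iterates converge in objective but can stall with the underapproximation
measurably violated (overshoot ~0.4 on a random 10×50 matrix). The solver
therefore escalates ρ (×2 every 25 iterations, ceiling 64) while the
overshoot exceeds `10·tol`, and caps iterations at 1000 (measured
convergence: a few hundred iterations on realistic batches). When all
residuals have converged but feasibility is pinned at the ρ ceiling, the
solver returns its best iterate rather than burning the remaining budget.

**Noise-margin slack.** A hard `uvᵀ ≤ Y` constraint on noisy data binds on
single-sample noise *minima*: with hundreds of trials per batch the fitted
waveform settles ~3 noise SDs below the true artifact, leaving a
systematic residual on every contaminated trial. The solver therefore
relaxes the envelope to `uvᵀ ≤ Y + noise_margin·σ̂` (σ̂ estimated robustly
from the negative half of the signed pre-stimulus context) while the
least-squares objective still targets Y — the envelope then guards against
absorbing structured signal without the noise bias. The assembled artifact
is clamped elementwise below the rectified trace on output, so the
published underapproximation contract holds exactly and
`Y = artifact + demixed` is an identity.

**Evidence guards.** Two guards stop the low-rank terms from subtracting
what cannot be distinguished from noise: a stimulus component whose peak
reconstruction inside the integration window is below `stim_floor·σ̂` is
dropped entirely (in artifact-free batches the dominant coherent structure
is a reliable PSC family, not an artifact); and a trial's baseline weight
is zeroed unless the trial's own pre-stimulus mean exceeds the
rectified-noise expectation `σ̂/√(2π)` by `stim_floor` standard errors — a
genuine prior-trial tail is visible in the context window, while a
sub-noise "tail" is usually an envelope over mid-trial PSCs.

**Offsets before components.** β is initialized from the row-wise pointwise
minimum of the residual *before* any stimulus component is fitted. With no
components present this minimum is exactly the constant-offset content
(components are zero before laser onset); on rectified recordings row
minima are ≈ 0 so this is a no-op, but it stops the rank-one term from
absorbing clean pedestals in synthetic data. Offsets are re-estimated each
sweep by the same clipped pointwise minimum and frozen in step two.

**Degenerate inputs.** An all-zero batch returns all-zero factors; `t1 = 1`
(no pre-stimulus context) disables the baseline term with a warning rather
than fitting it degenerately; non-convergence returns the best iterate
flagged, never an error.

## What the simulator emulates — and what it does not

`simulate_mapping_experiment()` builds a *continuous* recording (so
snippets genuinely overlap at 30 ms ISIs: each carries the previous trial's
decaying tail and the next trial's onset) from:

* a double two-state gating model for the photocurrent waveform, with one
  kinetics draw per experiment (the artifact lives in the one patched
  cell), parameter ranges spanning fast to slow decay variants;
* per-target Bernoulli(p) photocurrent flags with Gamma(2, 250 pA) mean
  amplitudes (mean 500 pA, within the 0.3–0.8 nA range typical of direct
  somatic excitation), scaled linearly by relative laser power with 10%
  trial-to-trial jitter, clipped at zero;
* connections with probability 0.1, Gamma(2, 25 pA) peak weights,
  difference-of-exponentials kernels (rise 0.5–2 ms, decay 5–15 ms),
  power-scaled success probability (0.95 at max power), and latency
  `3 ms + Gamma(shape 2)` with mean excess 4 ms at maximum power
  (shrinking with power) — evoked spike latency plus synaptic delay, with
  only the early tail of the distribution reaching into the laser-on
  window;
* spontaneous PSCs at 2 Hz and white Gaussian noise at 5 pA SD;
* 100 targets × 3 powers × 5 repetitions by default (~1500 trials); the
  repetition count is a desk-scale choice (real experiments use 7–15 per
  condition) and is the main reason detection thresholds are as permissive
  as they are.

Ground truth records connectivity, per-target weights both as peak
amplitude (pA) and as evoked charge (pA·ms — the quantity comparable to
charge-based weight estimates), photocurrent flags and per-trial
amplitudes, and every PSC event.

Not emulated: dendritic filtering and space-clamp error (the linearity
premise is exact by construction here, only approximate in neurons);
optics (holographic point-spread, power calibration); electrode drift and
series-resistance changes; opsin desensitization across trials within an
experiment; correlated network activity (spontaneous events are Poisson).
A green simulation test therefore establishes correctness of the
*algorithmic* claims — separation under the stated generative model — not
robustness to every physiological nuisance in real recordings.

## The downstream detection surrogate

The full statistical connectivity pipeline used alongside this method in
practice is out of scope; detection here is a deliberately simple stand-in
whose only job is to score demixing end-to-end:

* per-trial responses are charge transfer over the standard 35 ms window,
  computed on *signed* traces (noise averages to zero) and truncated at
  the ISI, since the next trial's onset — deliberately not subtracted from
  the current snippet — would otherwise leak into the window;
* a target is detected when its *median* max-power trial charge exceeds an
  empirical null by `k_sigma` (default 4) standard errors. The median
  suppresses spontaneous PSCs (rare per trial, heavy-tailed in charge);
  the null center and scale are the median/MAD of all max-power trial
  charges (floored at white-noise propagation), because spontaneous
  background skews single-trial charges well beyond electrical noise;
* the reported weight stays the *mean* charge, matching how maps are
  averaged; ensemble experiments are unmixed by nonnegative least squares
  against the trial-by-target design before thresholding.

For scoring, a single least-squares gain maps charge-unit estimates onto
the simulator's weight scale before computing R² (the pipelines being
imitated establish a common scale internally; the gain is the minimal
analog). The same gain — calibrated on the post-subtraction fit — is used
to score bypassed (no-subtraction) estimates; fitting a separate gain there
would let it collapse toward zero and mask the failure being measured.

## Design decisions on genuinely open points

* The windowed objective is taken over `[0, t2]` (snippet start through
  integration-window end) throughout, matching the coordinate-descent
  pseudocode rather than the narrower window printed in one equation.
* The step-two loop updates the *stimulus* components; the printed
  pseudocode's "base" subscripts inside that loop are read as typos.
* β is frozen in step two, as printed (step two optimizes waveforms only).
* Heaviside convention Θ(0) = 1: pulse-on intervals are closed on the left.
* After the pulse, the recovery gate relaxes toward 1 (not its on-phase
  asymptote), as printed.
* Ensemble photocurrents sum linearly over stimulated targets (no
  occupancy saturation).
* The waveform ridge regression uses squared norms (standard ridge),
  reading the printed unsquared norms as notational shorthand.
* Rectification precedes baseline handling; β absorbs residual positive
  offsets only.

## Known limitations

* The underapproximation model cannot, even in principle, distinguish a
  perfectly reliable, zero-jitter, laser-locked PSC family from an
  artifact; the integration window and the evidence guards make this rare
  (it needs an artifact-free batch *and* sub-window latencies) but not
  impossible. This is the over-subtraction mode quantified by the
  acceptance suite.
* Residual artifact after subtraction is bounded below by the noise level;
  targets whose artifact is within a few noise SDs of zero contribute
  charge on the order of the spontaneous background either way.
* Batches are fitted independently; no information is shared across
  batches, so per-trial results can shift slightly (< 5% in the
  batch-robustness test) when the batch size changes.
* No online/streaming mode, no automatic rank selection (a residual-energy
  diagnostic is reported instead), and no modeling of real-recording
  nuisances listed above.
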