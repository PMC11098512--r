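# photodemix

Removal of direct photocurrent artifacts from two-photon optogenetic
connectivity-mapping recordings, by constrained low-rank matrix
factorization — together with a complete simulation framework for
validating the method end-to-end without experimental data.

## The problem

In single-cell-resolution connectivity mapping, a patched postsynaptic
neuron is held in voltage clamp while candidate presynaptic cells are
stimulated holographically. If the patched cell itself expresses opsin,
stimulation aimed at nearby targets excites it directly, producing a
*photocurrent*: an inward current that begins at laser onset and decays
roughly exponentially after offset. Photocurrents superimpose on the
postsynaptic currents (PSCs) that mapping is trying to measure, creating
spurious "connections" around the patched cell — and, with ensemble
stimulation, corrupting measurements for *every* target in a contaminated
ensemble.

## The model

Stack the N trial snippets (rectified so inward current is positive) into
an N×T matrix **Y**. Photocurrent waveforms are nearly identical across
trials up to a per-trial amplitude, so the artifact is modelled as a
constrained low-rank term:

    Y = X + U_base V_base + U_stim V_stim + β1ᵀ

subject to nonnegativity of all factors, the *underapproximation*
constraint

    U_stim V_stim + U_base V_base + β1ᵀ ≤ Y   (elementwise),

an exponential-decay constraint `v_i ≤ γ v_{i−1}` on the baseline waveform
(everywhere) and on the stimulus waveforms (from `t3`, ~10 ms after
stimulus offset), with γ = 0.999 per sample at 20 kHz. `U_base V_base` is a
rank-one term for decaying photocurrent left over from the *previous* trial
(inter-stimulus intervals are 30–33 ms, shorter than opsin decay); `β`
absorbs constant offsets; **X** is the PSC signal of interest.

Fitting proceeds in two steps. Step one learns the per-trial weights on a
short *integration window* after laser onset (≤ 5 ms, while the laser is
on), where photocurrents dominate and monosynaptic PSCs (latency ≥ ~3 ms)
have barely begun. Step two freezes the weights and re-fits full-length
waveforms under the same constraints. Each rank-one subproblem

    min ‖Y − uvᵀ‖²_F   s.t.  u ≥ 0, v ≥ 0, uvᵀ ≤ Y, F(γ)v ≤ 0

is solved by ADMM (C++ core), with the decay constraint enforced by an
exact O(T) pool-adjacent-violators projection generalized to γ-exponential
decay. Trials are processed in energy-sorted batches of ~200 so each batch
contains artifacts of similar size and kinetics.

## Worked example

```r
library(photodemix)

# simulate a mapping experiment: 100 candidate targets, 10% connected,
# 10% evoking direct photocurrent, 3 laser powers, 30 ms ISI
sim <- simulate_mapping_experiment(seed = 1,
                                   photo = photocurrent_population(p = 0.1))
dim(sim$raw)
#> [1] 1500  900      # 1500 trials x 45 ms at 20 kHz

fit <- remove_photocurrents(sim$raw, "inward_negative",
                            stim_onset_sample = sim$window$t1,
                            stim_duration_samples = sim$window$stim_duration_samples)
fit
#> <demix_fit> 1500 trials x 900 samples, 8 batches
#>  batch n_trials max_overshoot clipped_negative_mass subtracted_fraction
#>      1      200     27.311553            288627.839         0.936509483
#>      2      200     20.590978            635716.196         0.650718375
#>      3      200      9.366007             42823.323         0.063358114
#>      4      200     15.320552             66434.803         0.055280186
#>      5      200      4.958003              4508.229         0.012704769
#>      6      200      9.500322             17086.823         0.023499466
#>      7      200      3.364607              1514.344         0.004455198
#>      8      100      0.000000                 0.000         0.000000000

est <- detect_connections(fit$demixed, sim$metadata, sim$window,
                          polarity = "inward_negative")
report <- evaluate_connectivity(
  list(connected = sim$truth$connected,
       weights = sim$truth$weights_charge), est)
report
#> <eval_report> R^2 = 0.838 (gain 1.12); TP 6, FP 8, FN 0 of 100 targets
```

`subtracted_fraction` is the share of stimulus-window signal removed per
batch — large for the artifact-dominated top-energy batches, near 0 for
batches holding only PSCs and noise. The gain-corrected R² compares
estimated evoked charge (pA·ms) against the simulator's ground-truth
synaptic charge. This single realization uses a 10% photocurrent fraction
(the hardest condition); pooled over the standard 10-realization sweep of
1–10% contamination the same pipeline reaches R² ≈ 0.95 (see
`scripts/acceptance.R` below), versus a strongly negative R² when
subtraction is bypassed.

A command-line interface mirrors the R API:

```sh
Rscript inst/cli/photodemix.R simulate --out exp/ --seed 1
Rscript inst/cli/photodemix.R run --in exp/ --out res/ --rank 1 --gamma 0.999
Rscript inst/cli/photodemix.R evaluate --in exp/ --results res/ --out report.json
```

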