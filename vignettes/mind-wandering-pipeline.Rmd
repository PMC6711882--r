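---
title: "Detecting mind-wandering from single-trial EEG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mind-wandering from single-trial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mind-wandering — self-generated, task-unrelated thought — can only be
observed directly by interrupting people with thought probes, which is
both intrusive and sparse in time. A classifier that reads the
attentional state from the EEG of a single trial would remove that
limitation. `mweeg` implements such a pipeline end to end: it extracts
interpretable electrophysiological markers trial by trial, labels trials
from experience-sampling probe responses, and trains per-subject
support-vector machines to tell mind-wandering (MW) from on-task (OT)
states, within and across two very different tasks (a go/no-go sustained
attention task, SART, and a visual search task, VS).

Because no public recordings accompany this design, the package ships a
synthetic-session generator that reproduces the experiment's statistical
structure. Every stage of the analysis is exercised — and every claim in
the test suite is computed — on data from that generator.

# The markers

Twenty-five predictors per trial, all with a mechanistic reading:

* **Single-trial ERPs** — P1 and N1 at the lateral occipital channels
  A10/B7 (sensory processing; their attenuation during MW is the
  "perceptual decoupling" signature) and P3 at parietal A19 (task-related
  cognitive processing). 5 markers.
* **Band power** — alpha (8.5–12 Hz) and theta (4–8 Hz) at A10, A19, B7
  and frontal C21; elevated alpha accompanies disengagement from sensory
  input. 8 markers.
* **Intersite phase clustering (ISPC)** — phase coherence for each of the
  six channel pairs in both bands, indexing inter-regional communication.
  12 markers.

## Single-trial ERP estimation

Averaging across trials destroys exactly the trial-to-trial variation a
classifier needs. Instead each component is estimated per trial by
template matching with a Mexican-hat waveform

$$\psi(u) = (1 - 16u^2)\,e^{-8u^2},$$

scanned over time lags $t$ and scales $s$ (the scale is roughly the
wavelength of the bump in ms):

$$W(s, t) = \frac{1}{\sqrt{s}} \int f(\tau)\,
\psi\!\left(\frac{\tau - t}{s}\right) d\tau .$$

The polarity-appropriate extreme of $W$ inside a component's search
window (P1: 50–150 ms, N1: 100–200 ms, P3: 250–600 ms) gives amplitude,
latency and breadth in one step. Numerical choices:

* The integral is a Riemann sum over the epoch samples
  ($\Delta\tau = 1/f_s$), with zero contribution outside the epoch. Two
  routes — per-grid-point sums and FFT convolution (the template is even,
  so correlation equals convolution) — agree to machine precision and are
  cross-checked in the tests.
* Scale grids are logarithmic with 32 steps: 50–400 ms for the narrow
  early components, 200–1400 ms for the broad P3. The analysis the
  package follows does not document its grids; these ranges bracket each
  component's plausible breadth.
* The "local extreme" is implemented as the grid extreme within the
  window across all scales. A detection is flagged `degraded` when it
  sits on the search boundary or has the wrong sign; ties break toward
  the earliest lag, then the smallest scale.
* The N1 window defaults to the literal 100–200 ms; `sterp_config(n1_hi_ms
  = 230)` widens it, since late N1 peaks (the true N1 often centers near
  200 ms) are otherwise clipped.
* Signed amplitudes are kept (N1 is negative) and no baseline is
  subtracted before matching — the cross-covariance has no centering
  term.

A traditional counterpart (`traditional_erp()`) computes per-state
averaged waveforms and fixed-window mean amplitudes (P1 120–130 ms, N1
195–205 ms, P3 400–500 ms) so both methods can be compared on the same
trials.

## Spectral features

Each epoch channel is band-pass filtered with a linear-phase
least-squares FIR kernel and Hilbert transformed; power is
$|z(t)|^2$ and ISPC for channels $x, y$ is

$$\mathrm{ISPC} = \left| n^{-1} \sum_{t=1}^{n}
e^{i(\phi_{x,t} - \phi_{y,t})} \right|,$$

both averaged over the baseline (−400–0 ms) and after-stimulus-onset
(ASO, 0–600 ms) periods. Filter design choices, all validated by an
explicit quality gate (`design_filter()` reports them):

* The ideal response is plateau-shaped: unit passband, zero stopbands,
  20% transition ramps on each band edge. The realized response must
  keep its sum of squared errors against that ideal below 1 on a
  1000-point grid to Nyquist, its midband gain within [0.95, 1.05] and
  its DC gain at or below 0.05.
* The kernel spans five cycles of the band's lowest frequency (the
  three-cycle requirement is kept as a hard floor). Three cycles alone
  leaves more than 5% passband ripple at a 256 Hz sampling rate; five
  cycles (alpha: 151 taps, theta: 321 taps) realizes a flat plateau and
  still fits comfortably inside a 410-sample epoch.
* In the least-squares fit the transition bands are don't-care regions,
  the passband is weighted 4:1 over the stopband (in-band amplitude
  fidelity matters more than stopband depth for power estimates), and
  the response is constrained to be exactly zero at DC, which makes every
  feature invariant to constant offsets by construction.
* Epochs are mirror-padded by one kernel length before (zero-phase)
  convolution to suppress edge transients; whether the original analysis
  filtered epochs or continuous data is unknown, and epoch-wise
  processing is the only option for an epoched container.
* Per-trial features are each trial's own period means; no baseline
  normalization or dB conversion is applied.

## Classification

Per subject and task, the 25 markers (spectral values from the ASO
period; the baseline period feeds only the state-by-time ANOVAs) are
z-transformed and fed to an RBF-kernel C-SVC. Design choices:

* **Imbalance.** Minority-class training rows are duplicated by sampling
  with replacement until classes balance (random oversampling), *inside
  each training fold only* — duplicating before the train/test split
  would place copies of test rows in the training set.
* **Validation.** Within-task leave-one-out cross-validation;
  across-task transfer trains once per direction on all of one task and
  tests on all of the other; single-marker models pool both tasks
  (normalized within task) and re-run LOOCV per marker.
* **Tuning.** Grid search over $C \in 2^{\{-5,-3,\dots,15\}}$,
  $\gamma \in 2^{\{-15,-13,\dots,3\}}$ with stratified 5-fold inner CV,
  ties toward smaller $C$ then smaller $\gamma$. By default the search
  runs once per model on the full table (as when tuning once per
  subject); `model_spec(nested = TRUE)` re-runs it inside every LOOCV
  fold.
* **Normalization scope.** The default `global_per_subject_task` scope
  z-scores each subject-task table once, mirroring per-subject
  normalization before model fitting; `train_fold_only` re-estimates the
  statistics in each training fold and applies them to the held-out
  trial, the leakage-free variant used in hygiene tests.
* **Solver.** No SVM package is assumed: the dual problem is solved by a
  compact SMO (maximal-violating-pair working set) in C++, cross-checked
  in the tests against an independent quadratic-programming solve. The
  iteration cap (10⁴) can stop heavily overlapping problems at large
  $C$ slightly early with a near-converged boundary; this is flagged on
  the model object and is immaterial for cross-validated prediction.
* Mind-wandering is the positive class everywhere: sensitivity is the
  detected fraction of MW trials, specificity of OT trials. Metrics whose
  reference class is absent propagate as `NA`, never as zero.

## Labeling and inclusion

Probe responses map 1–2 → on-task, 3 and 5 → mind-wandering, 4
(external distraction) and 6 (mind-blanking) → excluded. The six trials
up to and including the probed trial inherit the probe's class — the
probed no-go trial is read as the last of the six, since probes
immediately follow it. Subjects are retained only when every task-state
cell holds at least 30 clean labeled trials (scaled sessions in the
analysis scripts lower this threshold proportionally).

# The synthetic cohort

`simulate_session()` emulates the experiment: 12 blocks of 135 (SART) or
140 (VS) trials, 54 probes separated by 7–24 trials, 256 Hz epochs from
−400 to +1200 ms. Defaults state the world the analysis assumes:

* Mind-wandering probability 0.4 per probe (cohort scripts spread
  per-subject rates over the observed 0.16–0.82 range); 16% of probe
  reports leak into the excluded categories.
* ERP components are scaled Mexican-hat bumps — P1 (+3 µV, 120 ms), N1
  (−3 µV, 180 ms) at A10/B7, P3 (+5 µV, 450 ms, scale 600 ms) at A19 —
  with 20 ms latency jitter; MW attenuates all of them to 70%
  (perceptual and cognitive decoupling). Reusing the matching template
  as the embedded waveform makes the matched filter exact under zero
  noise, so parameter recovery is testable.
* Alpha (10 Hz) amplitude is 2 µV OT vs 3 µV MW; theta (6 Hz) is 1.5 µV
  in both states. Oscillation amplitudes carry log-normal per-trial
  variability (`osc_sdlog = 0.5`): real band power varies strongly
  across trials, and without this the classifier sits at an unrealistic
  ceiling.
* The A19–A10 theta pair shares a common oscillator; the second channel
  is phase-shifted by a piecewise-constant von Mises process
  (concentration κ = 0.5 OT vs 2 MW, redrawn every 86 samples ≈ two
  theta cycles). The block length matches the band filter's integration
  time, so the marginal distribution of the measured phase difference
  survives filtering: the pooled-across-trials resultant
  (`ispc_pooled()`) recovers the closed form $I_1(\kappa)/I_0(\kappa)$,
  while per-trial ISPC rises monotonically with κ — giving both a
  testable oracle and a usable state effect.
* Background activity is pink (1/f, spectrally shaped white noise) plus
  white noise, 2 µV each.
* Behavior: accuracy 0.95/0.93 (SART OT/MW) and 0.97/0.95 (VS); mean RT
  462/444 ms in the SART (faster, mindless responding) and 654/687 ms in
  VS (slower under MW).

Epochs are synthesized only for the six pre-probe trials of each probe
(filler trials carry metadata only) — the analysis never touches other
trials, and this keeps a full cohort in desktop seconds.

What the generator does **not** emulate: eye-blink/EMG artifacts,
volume-conduction correlations between channels, non-stationary drifts,
the 128-channel montage, or any systematic ERP difference between
stimulus types. A green test therefore establishes that the *pipeline*
recovers what was embedded, not that real EEG carries these effects.

# Statistical machinery

Group inference uses paired *t* tests with Cohen's *d* on the difference
scores, one-sample *t* tests against the 0.5 chance level, Spearman rank
correlations (average ranks on ties) for the classifier-bias analysis,
two one-sided tests (TOST; the 90% two-sided interval is the "95% TOST
interval") for marker-vs-full-model equivalence, and 2×2 within-subject
ANOVAs (state × time) with generalized eta squared,
$\eta_g^2 = SS_{\text{effect}} / (SS_{\text{effect}} +
\sum SS_{\text{subject-related}})$, each effect tested against its own
subject-by-effect interaction. Degenerate inputs error rather than
silently return 0: zero-variance difference scores (including identical
paired vectors) are rejected, and one-sample tests are two-sided by
default with the alternative exposed as an argument.

# Running it

The numbered scripts under `analysis/` are the workflow:

```{r}
# Rscript analysis/01_simulate.R --subjects 8 --probes 30 --seed 1
# Rscript analysis/02_label.R
# Rscript analysis/03_extract.R
# Rscript analysis/04_classify.R
# Rscript analysis/05_evaluate.R
```

or equivalently in one call:

```{r}
library(mweeg)
report <- run_pipeline(default_config(n_subjects = 6, n_probes = 20,
                                      min_trials_inclusion = 10))
```

# Known limitations

* Accuracies on the default synthetic cohort (≈0.75–0.86) sit above the
  0.5–0.85 range typical of real recordings: even with log-normal power
  variability the generator's class overlap is milder than reality's.
  The direction and structure of every effect — not the absolute
  accuracy level — is what the test suite pins down.
* The SMO solver precomputes the dense kernel matrix; per-subject trial
  counts (hundreds) are its intended regime, not pooled corpora of many
  thousands.
* `select_trials()` assumes probe windows never overlap (guaranteed by
  the ≥7-trial gap) and errors otherwise rather than resolving claims.
* Scale-grid and window defaults are choices this package owns; where a
  published analysis leaves a knob undocumented, the vignette text above
  records what was chosen and why.
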