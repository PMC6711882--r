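# mweeg — task-general mind-wandering detection from single-trial EEG

Mind-wandering (self-generated, task-unrelated thought) is usually
measured by interrupting people with thought probes. `mweeg` implements
and tests a complete analysis pipeline for detecting it from the EEG of
a *single trial* instead: interpretable electrophysiological markers are
extracted trial by trial, trials are labeled from experience-sampling
probe responses, and a per-subject RBF support-vector machine separates
mind-wandering from on-task states — within a task, and transferring
across two very different tasks (a go/no-go sustained-attention task and
a visual search task).

Because no public recordings exist for this design, the package includes
a synthetic-session generator that reproduces the experiment's structure
(probe schedules, six-trial pre-probe state windows, per-subject
mind-wandering rates) and the expected state effects (attenuated P1/N1/P3,
elevated alpha power, tighter parietal–occipital theta phase coupling
during mind-wandering). Every pipeline stage runs, and is tested, on
that generator.

## The method in brief

**Single-trial ERPs.** Each component is estimated per trial by template
matching with a Mexican-hat waveform ψ(u) = (1 − 16u²) e^(−8u²), scanned
over lags *t* and scales *s*:

    W(s, t) = s^(−1/2) ∫ f(τ) ψ((τ − t)/s) dτ

The polarity-signed extreme of W inside a component's window (P1
50–150 ms and N1 100–200 ms at occipital A10/B7, P3 250–600 ms at
parietal A19) gives amplitude, latency and breadth in one step.

**Spectral markers.** Epochs are band-pass filtered (plateau-shaped
least-squares FIR; alpha 8.5–12 Hz, theta 4–8 Hz, 20% transitions,
SSE < 1 quality gate) and Hilbert-transformed. Band power is |z(t)|²;
intersite phase clustering for a channel pair is

    ISPC = | n^(−1) Σ_t exp(i(φ_x,t − φ_y,t)) |

both averaged over baseline (−400–0 ms) and after stimulus onset
(0–600 ms).

**Classification.** 25 z-scored markers per trial (5 ERP + 8 power + 12
ISPC) feed a per-subject RBF-SVM (an SMO solver in C++; no external SVM
library): random oversampling to class balance inside each training
fold, grid-searched C and γ, leave-one-out cross-validation, across-task
transfer, and single-marker models. Mind-wandering is the positive
class.

**Evaluation.** One-sample *t* against the 0.5 chance level, paired
*t*/Cohen's *d* state comparisons for every ERP marker (single-trial and
traditional averaging), Spearman correlations of classifier bias with
the mind-wandering rate, state × time repeated-measures ANOVAs with
generalized eta squared, and TOST equivalence of single markers with the
full model.

## Worked example

```r
library(mweeg)

# one subject, one SART session, scaled to 20 probes
sess <- simulate_session("SART", gen_params(mw_rate = 0.4), seed = 42,
                         design_args = list(n_probes = 20))
lab <- label_session(sess)
ef  <- extract_erp_features(lab$epochs)
sf  <- extract_spectral_features(lab$epochs)
tab <- assemble_features(ef, sf,
         data.frame(trial_id = lab$epochs$trials$trial_id,
                    state = lab$epochs$trials$label))
dim(tab)
#> [1] 78 27        # 78 labeled trials x (trial_id + 25 markers + state)

set.seed(7)
res <- loocv(tab, model_spec(C_grid = 2^c(-1, 1, 3),
                             gamma_grid = 2^c(-7, -5, -3)))
round(res$metrics, 3)
#>    accuracy sensitivity specificity
#>       0.782       0.667       0.817
```

78 labeled trials come from the 20 probes (six pre-probe trials each,
minus probes answered with the excluded "distraction"/"mind-blanking"
options). The LOOCV metrics say how often held-out trials were assigned
the probed state; sensitivity counts detected mind-wandering trials,
specificity detected on-task trials; cohort accuracies typically land
around 0.75–0.86 on the default generator.

The full workflow is the numbered scripts under `analysis/` —
simulate a cohort, label, extract features, classify, evaluate — each a
thin driver over the package that narrates what it finds and writes its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R --subjects 8 --probes 30 --seed 1
Rscript analysis/02_label.R
Rscript analysis/03_extract.R
Rscript analysis/04_classify.R
Rscript analysis/05_evaluate.R
```

`run_pipeline(default_config(...))` does the same in one call.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulating a cohort, extracting all markers, classifying
within- and across-task, and evaluating the group statistics — and
writes its JSON summary to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

| Where | What |
|---|---|
| `R/synth.R` | task designs, latent states, epoch synthesis, behavior |
| `R/sterp.R` | Mexican-hat wavelet template matching, traditional ERP |
| `R/spectral.R` | FIR design, Hilbert transform, band power, ISPC |
| `R/labeling.R` | probe-response mapping, trial selection, inclusion |
| `R/classify.R`, `R/svm.R`, `src/` | feature table, oversampling, grid search, LOOCV, transfer, single markers; SMO solver |
| `R/evaluate.R` | metrics and group statistics |
| `R/pipeline.R` | config validation and the end-to-end run |
| `vignettes/` | the methods vignette: model, parameters, design choices |
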