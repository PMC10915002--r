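# painstate

Classification of spontaneous pain, non-pain, and drug-induced analgesic
states from two-photon calcium imaging of primary somatosensory cortex
(S1).

Spontaneous pain — pain present without an applied stimulus — is hard to
measure preclinically: behavioral assays such as conditioned place
preference need intact learning and reward systems, which rules out many
disease models. `painstate` instead reads the state from cortical
population activity. It takes per-ROI fluorescence traces (one time
series per segmented neuron, ~5 Hz) together with a movement mask derived
from a 30 fps behavior video, and turns each session into a three-class
prediction with an explainable, handcrafted feature set in between.

## The method

For an evaluation session A and a same-subject reference session B with
*n* matched ROIs, the core statistic is the per-ROI **activity-share
difference**

    D_i = (X_i / Σ_j X_j)_A − (X_i / Σ_j X_j)_B

where X_i is ROI *i*'s mean normalized signal over a frame subset
(movement, stationary, or all frames), after Gaussian denoising (window
29), baseline-percentile normalization (ΔF/F = (X−μ)/μ or Z = (X−μ)/σ
with μ, σ from the frames at or below the 30th percentile), and flooring
at zero. Cells with D > 0.3 count as up-regulated, cells with D < −0.2
as down-regulated. The two ratios across {ΔF, Z} × {movement,
stationary, total} give 12 features; the mean pairwise ROI correlation
of the session is the 13th. Features are screened per contrast by
ROC-AUC (Mann–Whitney), standardized, reduced by PCA from 13 to 6
components, and classified by a small dense-layer softmax network.
Because spontaneous pain cannot be guaranteed present throughout every
pain-labeled recording, the bottom 10% of pain-labeled training sessions
by predicted pain value are removed before the final fit (false-label
management). Validation is leave-one-subject-out: all sessions of one
animal are the test fold, and filtering, imputation, PCA, and training
see only the remaining subjects.

A synthetic cohort generator (`generate_cohort()`) produces sessions
with GCaMP6s-like transients, locomotion bouts with a motion-energy
trace, planted state-dependent up/down-regulated cell fractions, and a
state-dependent shared drive controlling pairwise correlation — plus a
ground-truth sidecar, so the whole pipeline is testable without animal
data. See the vignette (`vignettes/pain-state-classification.Rmd`) for
the model, its assumptions, and the generator's design rationale.

## Worked example

```r
library(painstate)

cfg <- pipeline_config(seed = 1,
  sim = simulation_config(n_subjects = 6, sessions_per_subject_per_state = 2,
                          effect_size = 20, seed = 1))
bundle <- run_pipeline(cfg)

head(bundle$auc_table[, 1:3], 4)
#>                feature baseline_vs_pain pain_vs_analgesics
#> 1   zscore_up_movement             0.58               0.58
#> 2 zscore_up_stationary             0.50               0.50
#> 3      zscore_up_total             0.50               0.50
#> 4 zscore_down_movement             0.50               0.54

head(bundle$fold_results[, c("session_id", "class", "predicted_pain_value",
                             "predicted_class")], 4)
#>       session_id    class predicted_pain_value predicted_class
#> 1 S01_nonpain_01 non-pain               0.0089        non-pain
#> 2 S01_nonpain_02 non-pain               0.0122        non-pain
#> 3    S01_pain_01     pain               0.9966            pain
#> 4    S01_pain_02     pain               0.9740            pain

ev <- bundle$evaluations$pain_vs_nonpain
ev$summary
#>      group  n mean   sem
#> 1 non-pain 12 0.12 0.082
#> 2     pain 12 0.89 0.081
```

The AUC table is the per-feature screen (0.5 = chance) over the three
class contrasts. `fold_results` holds one row per session with the
held-out class probabilities; `predicted_pain_value` is the probability
assigned to the pain class, and here separates planted pain from
non-pain sessions (group means 0.89 vs 0.12, Welch p ≈ 1e-06, AUC 0.92
on this 6-subject toy cohort). `bundle$removal_log` lists the
training sessions dropped per fold by the false-label filter.

A thin command-line wrapper over the same functions lives at
`inst/cli/painstate.R`:

```sh
Rscript inst/cli/painstate.R simulate --out cohort/ --seed 1
Rscript inst/cli/painstate.R features --in cohort/ --out features.csv
Rscript inst/cli/painstate.R loso --features features.csv --out folds.csv --seed 1
```

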