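# fptriage

Machine-learning triage of false positive germline variant calls, so that
orthogonal (Sanger) confirmation can be restricted to the calls that need
it while guaranteeing a target false-positive capture rate.

## The problem

Clinical laboratories confirm reported NGS variants with an orthogonal
assay before sign-out. Most confirmations are wasted effort: the vast
majority of calls are real. The opposite mistake — reporting a false
positive call unconfirmed — is far more costly. `fptriage` implements a
framework for deciding, per variant, whether a confirmation must be
ordered:

1. **Labeling.** Each sample's calls are compared against a truth set
   restricted to benchmark regions; calls present in the truth set are
   true positive (TP) calls, the rest false positive (FP) calls.
2. **Stratification.** Calls are split into six variant-type × genotype
   strata (`snv`/`indel` × `het`/`hom`/`complexhet`), each modeled
   independently.
3. **Training and calibration.** Per stratum, four classifier families
   (AdaBoost, EasyEnsemble, GradientBoosting, RandomForest) are tuned by
   leave-one-sample-out cross-validation (LOSO CV); the classifier score
   *s* (higher = more FP-like) is thresholded at the order statistic of
   the training FP scores that guarantees a chosen **capture rate**
   `c ∈ [0.99, 1]`:

   ```
   capture rate  = flagged FP / total FP   (sensitivity for the FP class)
   TP flag rate  = flagged TP / total TP   (needless confirmations)
   t(c) = max { t : #{s_FP ≥ t} / n_FP ≥ c }
   ```

   Eight capture-rate targets in 99–100% are calibrated for every model.
4. **Clinical acceptance.** With CV capture-rate mean `m` and sample SD
   `σ` across folds, a candidate model passes only if
   `m − 2σ ≥ minimum_capture` **and** `final_capture ≥ m − 2σ`. Ties among
   passing candidates are broken by a modified F1 — the harmonic mean of
   capture rate and specificity (`1 −` TP flag rate). A stratum with no
   passing model is always confirmed.
5. **Deployment.** Under four risk approaches (all variants / benchmark
   regions only / nonactionable only / both restrictions), eligible
   variants predicted true skip confirmation; everything else is ordered.

A synthetic cohort generator (truth VCFs, call VCFs with quality-metric
features, benchmark BEDs, clinical tables; controllable TP/FP separation)
makes the entire workflow testable without any sequencing data.

## Worked example

```r
library(fptriage)

cfg <- synthetic_config(
  n_samples = 3, calls_per_sample = 8000,
  fp_prevalence = c("snv-het" = 0.03, "snv-hom" = 0.03, "snv-complexhet" = 0.03,
                    "indel-het" = 0.05, "indel-hom" = 0.05, "indel-complexhet" = 0.05),
  separation = 6, seed = 7
)
cohort <- simulate_cohort_calls(cfg)   # 24,000 calls: 800 FP, 23,200 TP
ms <- train_stratum_models(cohort, grid = small_learner_grid(), seed = 7)
ms
#> <model_set> 4/6 strata with a selected model (minimum 0.99, target 0.995)
#>   snv-het            (none — always confirmed)
#>   snv-hom            gradientboosting @ capture target 0.995 (threshold 0.1979)
#>   snv-complexhet     (none — always confirmed)
#>   indel-het          gradientboosting @ capture target 0.99 (threshold 0.9726)
#>   indel-hom          adaboost @ capture target 0.99 (threshold 1)
#>   indel-complexhet   adaboost @ capture target 0.99 (threshold 1)
```

Each selected line reads: for that stratum, flag a call for confirmation
when its score reaches the threshold calibrated at the shown capture-rate
target. Strata without a passing model (here `snv-het` fails the −2 SD
rule at this small cohort size, and `snv-complexhet` has too few FP
calls) are always confirmed — the framework fails safe.

Applying the confirmation policy to the bundled 306-variant demonstration
cohort of reported variants:

```r
d <- decide_confirmation(demo_reported_variants(), "nonactionable")
summarize_approach(d)$confirmation_order_rate   # 0.2941  (29.41%)
order_reduction(d)                              # 0.8571  (85.71% of eligible
                                                #  confirmations skipped)
```

## Package layout

| Surface | Purpose |
| --- | --- |
| `read_vcf()`, `read_bed()`, `union_regions()`, `span_in_regions()`, `write_predictions()` | VCF/BED I/O and schema-driven feature extraction |
| `trim_variant()`, `label_calls()`, `write_labeled_vcfs()` | truth matching and TP/FP labeling |
| `classify_stratum()`, `partition_by_stratum()` | six-way stratification |
| `split_train_test()`, `loso_cv()`, `calibrate_threshold()`, `evaluate_at_threshold()`, `train_final()` | training and capture-rate calibration |
| `lower_bound()`, `acceptance_check()`, `modified_f1()`, `select_models()` | clinical model selection |
| `decide_confirmation()`, `summarize_approach()`, `order_reduction()`, `retrospective_concordance()` | confirmation policy and reporting |
| `synthetic_config()`, `generate_cohort()`, `simulate_cohort_calls()` | synthetic data |
| `read_run_config()`, `write_model_bundle()` | configuration and deployment |

See the methods vignette (`vignettes/capture-rate-triage.Rmd`) for the
model, its assumptions, and the design decisions.
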