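---
title: "Capture-rate calibrated triage of false positive variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capture-rate calibrated triage of false positive variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fptriage` decides, per reported germline variant, whether an orthogonal
confirmation (typically Sanger sequencing) must be ordered. This vignette
is the package's account of the underlying model, its assumptions, the
parameters that matter, and the design decisions taken where the design
was genuinely open.

## The model

Calls are labeled against a truth set restricted to benchmark regions and
stratified into six variant-type × genotype classes. Within each stratum a
binary classifier is trained with false positive (FP) calls as the
positive class; its score $s \in [0,1]$ measures FP evidence. The
clinical quantity is not the score but an *operating point*: for a target
capture rate $c$, the decision threshold is

$$ t(c) \;=\; \max\{\, t : \tfrac{1}{n}\#\{s_i^{FP} \ge t\} \ge c \,\} $$

over the $n$ training-set FP scores — the appropriate order statistic.
Two consequences are load-bearing:

* **Exact in-sample guarantee.** On the calibration data the achieved
  capture is $\ge c$ by construction, for every target; the tests assert
  this exactly, not approximately.
* **Distribution-free transfer.** For a *new* exchangeable sample, the
  probability that a fresh FP score falls below the $k$-th smallest of
  $n$ calibration FP scores is $k/(n+1)$ regardless of the score
  distribution. Out-of-sample capture therefore depends only on FP
  *counts*, not on how separable the classes are; separability governs
  the TP flag rate (the fraction of true calls needlessly confirmed).

Ties at the threshold are flagged (`score >= threshold`): ambiguity
resolves toward confirmation, the safe direction.

## Cross-validation and the −2 SD rule

Hyperparameters are chosen by leave-one-sample-out cross-validation
(LOSO CV): each fold trains on all samples but one, calibrates thresholds
on that training portion's FP scores, and evaluates the left-out sample —
simulating a new specimen. The winner per algorithm maximizes mean ROC
AUC across folds. Thresholds are calibrated *per fold* rather than on
pooled out-of-fold scores; the per-fold scheme is the one that matches
deployment, where a threshold fixed in advance meets a sample never seen.

From the winning fold metrics the capture-rate mean $m$ and sample
standard deviation $\sigma$ (denominator $n-1$; with few folds the
uncorrected estimator would be noticeably biased) give the lower bound
$m - 2\sigma$. A candidate passes for clinical use only if

1. $m - 2\sigma \ge$ `minimum_capture` (consistency well above the floor), and
2. final testing capture $\ge m - 2\sigma$ (agreement between the
   retrained model and its CV behaviour, rejecting over/underfitting).

Defaults are `minimum_capture = 0.99`, `target_capture = 0.995`; a
`stringent_criteria()` preset (0.999 / 1.0) ships for settings where
essentially no FP call may escape. Among passing candidates (algorithms ×
eight capture-rate targets) one is selected by the **modified F1**, the
harmonic mean of capture rate and specificity ($1-$ TP flag rate). The
harmonic-mean form is this package's named, swappable definition
(`modified_f1()`); laboratories using a different tie-break statistic can
substitute their own. Remaining ties resolve deterministically: lower TP
flag rate, then lower target, then algorithm name.

**A noise floor worth knowing.** Because out-of-sample capture is
rank-based, a fold with $n_{FP}$ left-out false positive calls has
capture-rate sampling SD of roughly $\sqrt{c(1-c)/n_{FP}}$. With, say, 70
FP calls per fold that is $\approx 0.8\%$ — so $m - 2\sigma$ cannot
reliably clear a 99% floor no matter how good the classifier is. Passing
the rules at `minimum_capture = 0.99` genuinely requires FP counts in the
high hundreds per fold (or score saturation producing capture exactly 1.0
in every fold). This is a property of the acceptance rules themselves,
and the package reproduces it faithfully: small demonstration cohorts
legitimately leave strata without a passing model, which are then always
confirmed — the framework fails safe rather than optimistic.

## Labeling and stratification conventions

* **Trimming.** `trim_variant()` removes the shared allele prefix (advancing
  the position) and then the shared suffix, always retaining one base per
  allele. Matching is invariant to the prefix/suffix order since query
  and truth are normalized identically.
* **Simplified matcher.** `label_calls()` matches per record after
  trimming. It does not left-align against a reference genome (no FASTA
  dependency) and gives no credit for multi-record haplotype equivalence,
  a deliberate divergence from haplotype-aware engines such as RTG
  vcfeval in exchange for desk-scale determinism. Synthetic fixtures
  control their own representation, so the simplification is exact there;
  on real data it can mislabel complex representation differences as FP —
  the conservative direction for a confirmation pipeline.
* **Genotype awareness.** By default a genotype-discordant match (het
  call at a truly hom site) is a false positive call — such a call should
  be confirmed. The check can be disabled per run.
* **Mixed alleles.** A genotype carrying one SNV and one indel allele
  classifies into the indel stratum: indel error modes dominate such
  sites, and the alternative would let the better-behaved SNV models vouch
  for indel-containing genotypes.
* **Multiallelic records** are never split; the complex-heterozygous
  strata need both alleles of a genotype together.

## Clinical policy

Eligibility under an approach is resolved in a fixed order: approach
restrictions first (a variant both outside the benchmark union and
actionable is counted once, in the combined category), then model
availability; only then may a predicted-true variant skip confirmation.
The invariant `confirm = !(eligible & predicted_true)` is enforced by
construction and tested exhaustively over category × prediction ×
approach; no actionable variant can ever skip confirmation under the
nonactionable-restricted approaches.

## The synthetic generator

`synthetic_config()` emulates the *structure* of a benchmark-derived
training resource: per-sample call VCFs, truth VCFs holding exactly the
true calls, benchmark BEDs covering all but an `excluded_fraction` of
loci, and a clinical table. Quality features are independent Gaussians
(site quality, genotype quality, depth, mapping quality, quality-by-depth)
shifted down by `separation` SDs for FP calls, plus an allele-fraction
feature that is symmetric for heterozygous true calls, concentrated near
1 for homozygous ones, and mixed toward a low-fraction skew for FP calls
with a weight that vanishes as `separation` goes to 0 — so `separation = 0`
makes labels exactly independent of features. Loci live on two synthetic
chromosomes at positions spaced so reference spans never touch, keeping
region arithmetic and label round-trips exact.

Defaults are chosen once as the study conditions: 7 samples, 50,000
calls per sample, FP prevalence 0.005 for SNV strata and 0.02 for indel
strata (indel calling is roughly an order of magnitude less precise), a
heterozygous-SNV-dominated stratum mix, and `separation = 1.5`, which
yields a realistic imperfectly-separable problem (held-out AUC around
0.99, TP flag rates in the tens of percent at 99.5% capture).

What the generator does **not** emulate: alignment context (homopolymers,
tandem repeats, pseudogenes), correlated features, sequencing-error
profiles, or real genome coordinates. Passing tests on synthetic cohorts
therefore demonstrate the correctness of the machinery — labeling,
calibration guarantees, CV bookkeeping, selection logic, policy
arithmetic — not clinical performance on any particular assay, which must
be established per laboratory on real truth-set data.

## Numerical and degenerate-input choices

* The training side receives the ceiling of each per-sample, per-label
  half in `split_train_test()`.
* The required flagged count uses `ceiling(n * c - 1e-9)`; the epsilon
  guards against binary-representation artifacts (e.g. `0.99 * 100`
  evaluating just above 99) inflating the count by one.
* A stratum with no FP calls cannot be calibrated: `calibrate_threshold()`
  errors, and the pipeline records the stratum as having no model.
* A CV fold whose left-out sample has no FP calls contributes no capture
  estimate; it is excluded from $m$ and $\sigma$ with a warning.
* Chromosome-naming mismatches between query and truth raise an explicit
  error instead of silently labeling everything FP.
* All randomness (splits, subsampling learners, the generator) is driven
  by explicit seeds through a local-RNG helper, so identical
  configuration + seed reproduces every summary exactly on one platform.

## Problem sizes used by the test suite

The end-to-end acceptance check runs the full LOSO CV + selection
workflow on a 7-sample × 50,000-call cohort with one hyperparameter point
per algorithm (the grid is configuration, not contract; the default
45-point grid is exercised structurally elsewhere). Chance-level and
flag-rate-convergence properties use 20,000-call samples with elevated FP
prevalence so that binomial tolerances are tight; the convergence test
calibrates on a held-out sample because in-sample calibration with a
flexible learner is biased low by overfit score separation — the LOSO
design itself is the justification for out-of-sample calibration.

## Known limitations

* Per-record matching understates TP labels relative to haplotype-aware
  comparison on real data (conservative for triage, pessimistic for
  benchmarking callers).
* The modified F1 here is one reasonable tie-break, not an attempt to
  reconstruct any particular laboratory's statistic.
* AdaBoost score granularity (weighted stump votes) can saturate on
  well-separated data; saturation makes its capture behaviour very stable
  but its thresholds uninformative (`threshold = 1`), which the selection
  report makes visible rather than hiding.
* No cost model beyond counting skipped confirmations; no multiple-testing
  adjustment across strata (none is applied by design).
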