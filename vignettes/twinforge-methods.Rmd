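---
title: "Methods: building and stress-testing an offline digital twin from two-wave cohort data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and stress-testing an offline digital twin from two-wave cohort data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinforge)
```

## The problem

Large midlife panel studies measure thousands of biological, behavioral,
psychosocial, and socioeconomic variables at widely spaced waves. twinforge
turns such a paired two-wave panel into an *offline digital twin*: a set of
trained models that (i) predict follow-up disease onset from baseline
features, (ii) summarize each participant's predicted risk into a small
number of interpretable risk states, (iii) model the between-wave state
transition, and (iv) answer deterministic "what-if" questions by rerunning
the trained models on perturbed baseline inputs. The what-if engine is a
*model sensitivity* instrument, not a causal estimator: a perturbation
result says how the trained models respond to changed inputs, nothing more.

Because the motivating cohort data are access-restricted, the package ships
a first-class synthetic cohort generator with known ground truth. All
development, testing, and the acceptance protocol run against it.

## The synthetic cohort generator

`generate_cohort()` draws a baseline cross-section whose marginals are
anchored to published descriptive statistics of a US midlife cohort:
age 56.0 (SD 12.4) years, BMI 27.9 (SD 5.7) kg/m², 30.3% hypertension,
light activity 2.0 (1.5) h/week, depression score 0.6 (1.7), education 7.3
(2.5) scale units, and log-normal household income with median $57,500.
Physical activity is an ordinal 1–6 scale (a discretized Gaussian), which
is what gives the composite lifestyle scenario's "+1 category ≈ 20% of the
scale" semantics. Weight is generated consistently with BMI through a
per-participant height, so a relative weight change propagates exactly to
BMI at fixed height.

The follow-up wave is baseline value + configured drift + Gaussian
innovation; the design deliberately models *no* richer dynamics, because the
framework only ever sees paired records. The binary follow-up outcome is
drawn from a logistic model on baseline values,

$$\Pr(Y_{W3}=1\mid x_{W2}) = \operatorname{logit}^{-1}\!\big(\beta_0 + \textstyle\sum_v \beta_v x_{W2,v}\big),$$

with default weights on age, BMI, hypertension, smoking, distress scores
(positive) and physical activity, income, education (negative). The
intercept is *calibrated by 1-D root finding* so that the mean true risk
equals the target incidence (default 14.7%); this gives exact control of
the expected case mix at any cohort size. `true_risk()` exposes the
ground-truth probabilities, which is what makes parameter-recovery and
Bayes-AUC tests possible.

Administrative variables (interviewer id, collection site, plus numeric
noise columns) are generated independent of the outcome; a prescription
checklist variable is generated *downstream* of the risk drivers and
flagged `proxy`. These populate the "noise" and "proxy" classes of the
semantic audit. Item missingness is MCAR or MAR-on-a-named-covariate
(missingness concentrated above the covariate's median at twice the
marginal rate), and attrition drops whole follow-up records before
pairing. The missing marker is R's `NA`, which is by construction distinct
from every legal value and survives the CSV round trip as an empty field.

What the generator does *not* emulate: real item wordings and codings,
informative (MNAR) dropout, measurement error correlated across items, and
the full variable inventory of a production survey. Passing tests on this
generator therefore certify the *machinery* (determinism, leakage safety,
calibration of the estimators, simulator identities), not predictive
performance on any real cohort.

## Ontology retrieval and the relevance agent

Ontology fixtures are JSON files of concepts (IRI, label, definition) and
subject–predicate–object triples. Concept labels are embedded by a
deterministic feature-hashing text embedder (lower-cased character
3-grams hashed into signed buckets, unit-normalized). The embedder
satisfies the same contract a sentence-transformer adapter would — text to
fixed-length unit vector, deterministic per text — while keeping retrieval
bit-reproducible offline. For each variable, the top-k concepts with
cosine similarity at or above a threshold are retrieved (defaults k = 5,
threshold 0.3), ties broken by lexicographic IRI, and rendered into a
structured context block with arrow-formatted triples.

The relevance agent queries a pluggable language-model backend (temperature
0.3 by default) and demands strict JSON:
`{relevance_score ∈ [0,1], classification ∈ {Direct, Indirect, Unrelated},
reasoning}`. A critic validates the schema, the score range, and
score/class band consistency (declared bands: Direct ≥ 0.7, Unrelated
< 0.3, Indirect in between). On an invalid response, an inconsistent band,
or a score below 0.3, the variable is requeried exactly once with expanded
context (retrieval k doubled); a second failure excludes it. This bounds
the loop at two invocations per variable and makes `select_features()`
terminate in at most 2 × |catalog| backend calls. Variables are processed
in fixed catalog order in batches of 40 and the survivors ranked by score
(ties keep catalog order), truncated to the top 200 by default.

The shipped stub backends (scripted, keyword, domain-aware) are test
harnesses: their scoring rules are explicit package code and make no claim
about what any particular live model would answer. Baseline selectors are
provided for the ablation comparison: an L1-regularized logistic path
(ranking by |coefficient| at the largest penalty admitting ≥ k non-zeros)
and a plug-in mutual-information filter on decile-binned features, both
deterministic at seed 42. `semantic_audit()` classifies a ranking into
target-relevant / administrative-noise / downstream-proxy counts via the
catalog tags.

An open choice: whether the embedded variable text is the name, the label,
or both. Both concatenated is the default (`text_fields` argument), since
names alone are often uninformative codes.

## Prediction core

Preprocessing (`clean_and_impute()`) is fitted on the baseline wave only
and stored as a frozen plan: variables with ≤ 5% missingness get mean/mode
imputation, higher-missingness variables get kNN imputation (k = 5,
Euclidean distance over z-scored complete baseline columns, donors drawn
from the baseline wave); continuous values outside plausibility bounds
(catalog scale limits, else mean ± 4 SD) are winsorized and counted;
continuous features are z-scored with baseline parameters. The plan
reapplies to the follow-up wave and to perturbed panels without
re-estimating anything — this frozen-plan property is what makes the
placebo identity exact.

`train_predictors()` runs stratified k-fold cross-validation (default 5)
over logistic regression, random forest, and gradient-boosted trees.
Minority oversampling is SMOTE-style interpolation to a 1:1 ratio applied
*inside each training fold only*; evaluation folds contain original rows
only, which the code asserts and instruments. Out-of-fold predictions are
pooled for accuracy (threshold 0.5), macro-F1, AUC (rank statistic with
midrank ties), PR-AUC (average precision with tie groups), Brier, and ECE
(10 equal-width bins). The metric implementations are hand-written because
they sit under oracle-equivalence tests against brute-force
implementations. Attribution uses TreeSHAP contributions for boosted
models and seeded permutation importance otherwise.

## State construction, transition, and outcome models

The baseline risk score fed to state construction is the out-of-fold
predicted probability of the best-AUC predictor; follow-up risks come from
applying the *same baseline-trained* predictor to follow-up features.
States are fitted by **exact 1-D k-means**: in one dimension the optimal
k-means partition is a contiguous partition of the sorted scores, found by
dynamic programming over within-cluster sums of squares. This replaces
seeded Lloyd's iterations because it is deterministic with no
initialization and provably attains the SSE optimum that the test-suite
oracle enumerates. K = 3 by default (low/medium/high); centroids are
frozen at baseline, verified by digest before and after every simulation.
Nearest-centroid assignment sends exact midpoints to the lower-risk state.
For K > 3 the high-risk population is the union of highest-centroid
clusters accumulating until it first reaches the K = 3 high-risk group
size ("matches" cannot mean exact equality in general); the union is never
empty.

The transition model estimates $P(S_{W3}\mid S_{W2}, x_{W2})$ with a
multiclass classifier (boosted trees by default; random forest and
multinomial logistic as alternatives) under the same stratified-CV
discipline, reporting accuracy ± SD, macro-F1, the average log-likelihood
of the realized next state, and multiclass Brier/ECE. Its out-of-fold soft
outputs are retained, and the outcome model
$P(Y_{W3}\mid S_{W2}, S_{W3}, x_{W2})$ is trained on baseline features,
the one-hot baseline state, and those *cross-fitted* soft states — a
leakage detector refuses soft inputs not flagged as out-of-fold.
Oversampling defaults off for both simulation-stage models (the transition
problem is multiclass; the outcome stage inherits the choice but is
configurable).

## The what-if engine and its protocols

A scenario is a declarative list of perturbations (multiplicative,
additive, ordinal shift, categorical set) plus derived-feature propagation
rules (e.g. weight × 0.9 ⇒ BMI × 0.9 at fixed height). Perturbations apply
to baseline covariates only; the observed baseline state stays fixed as a
conditioning input, since the engine reruns the trained transition and
outcome models rather than re-deriving the baseline stratification.
Ordinal shifts clamp to scale bounds; multiplicative reductions of bounded
scores floor at the scale minimum and are re-rounded on ordinal scales. A
scenario perturbing any non-modifiable variable — administrative fields or
downstream proxies like medication checklists — is rejected by the critic
with the offending variables named.

`simulate_scenario()` runs baseline and perturbed panels through the
identical deterministic pipeline and reports state distributions, case
counts at the 0.5 threshold, mean risk, per-participant deltas, state
changes, high-to-low transitions, and the count with strictly reduced
risk. Three protocols probe the engine:

* **Placebo**: a 0%-magnitude scenario must change *nothing, exactly* —
  the implementation achieves an identity, strictly stronger than the
  sub-0.3% bound it is held to.
* **Monotonicity**: graded weight reductions (5/10/15%) must give
  non-increasing mean predicted risk on the monotone generator.
* **Cross-K stability**: for K = 3–5, size-matched high-risk unions on a
  three-clump risk distribution must overlap at Jaccard ≥ 0.9; extra
  clusters subdivide the populous low-risk stratum rather than moving the
  high-risk boundary.

## Orchestration and reproducibility

`run_pipeline()` is a deterministic hub-and-spoke controller: stages run
in dependency order (cohort → index → select → train → states →
transition/outcome → scenarios), each stage writes a plain-text artifact,
and the run manifest records the config snapshot, per-stage md5 digests,
timings, and critic reports. Reruns from the same config reproduce every
digest; `verify_manifest()` detects post-run artifact modification. Every
random procedure takes an explicit seed; a config without one is rejected
before execution. Free-form agent replanning is deliberately out of scope:
only the two bounded critic behaviors (decision validation, scenario
actionability) are implemented, which is what makes the controller fully
testable.

## Numerical and statistical choices

* Outcome-labeling biomarker cut-offs default to fasting glucose ≥ 126
  mg/dL and HbA1c ≥ 6.5% (standard diagnostic criteria); missing channels
  count as negative evidence, and an all-missing record is labeled 0 with
  an audit flag.
* Multiclass booster probabilities are renormalized to sum exactly to 1
  (single-precision outputs drift at the 1e-8 level).
* Parameter-recovery testing asserts *family-wise* 95% coverage of the
  generator coefficient vector using Bonferroni-adjusted intervals:
  marginal 95% intervals over 10 parameters would fail a joint assertion
  about 40% of the time even for a perfectly specified estimator.
* Problem sizes in the test suite are chosen to make each statistical
  assertion well-powered at desk scale: n = 20,000 for coefficient
  recovery, n = 50,000 for incidence-calibration and noise-independence
  checks, n = 10,000 for the chance-level transition calibration band,
  n = 4,174 (the emulated cohort size) for the end-to-end placebo and
  monotonicity protocols.
* The 1-D k-means DP breaks SSE ties toward the smallest left boundary;
  retrieval ties break by lexicographic IRI; ranking ties keep catalog
  order — every tie-break is deterministic and documented.

## Known limitations

Counterfactual outputs are model sensitivities, not intervention-effect
estimates; nothing here corrects for confounding or MNAR dropout. The
simulator is single-step by construction — two waves admit no multi-step
dynamics, online updating, or continuous-time states. The shipped
embedder captures lexical, not semantic, similarity; a sentence-embedding
adapter can be substituted behind the same contract. The agent stubs are
deterministic harnesses, so agreement between "agent" selection and the
audit categories on synthetic data reflects the stub's declared rules, not
emergent model judgment. Follow-up risks are scored with the
baseline-trained predictor on follow-up features; if a real deployment
retrained per wave, state comparability across waves would need separate
justification.

## A worked example

```{r example, eval = FALSE}
panel <- generate_cohort(cohort_spec(n_participants = 4174, seed = 42))
twin <- build_twin(panel, seed = 42)
summary(twin)

scenario <- read_scenario(system.file("extdata", "scenario_weight10.json",
                                      package = "twinforge"))
simulate(twin, scenario = scenario)

monotonicity_sweep(twin, magnitudes = c(0.05, 0.10, 0.15))
stability_analysis(predict(twin, "risk_w2"), K_range = 3:5)
```
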