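---
title: "Distant supervision for recurrent metastatic breast cancer detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distant supervision for recurrent metastatic breast cancer detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcdetect)
```

## The problem and the approach

Cancer registries identify *de novo* metastatic breast cancer (stage IV at
the initial diagnosis) but not distant recurrences, which arise later in
patients first diagnosed at stages 0–III and make up the large majority of
metastatic disease. Clinical notes do describe recurrences, but training a
supervised classifier normally requires chart-review labels that are
expensive to produce at cohort scale.

`mbcdetect` sidesteps manual annotation with *distant supervision*: a
high-precision textual rule generates noisy case/control labels, and those
labels train a regularized classifier over features deliberately disjoint
from the rule. The pipeline is:

1. tag lexicon terms in notes and resolve each mention's context;
2. assign cohort labels (registry stage IV → de novo; no notes → non-MBC;
   otherwise the site-class rule);
3. build patient-level features and train an L2-penalized logistic
   regression on the distant labels;
4. evaluate on a held-out, adjudicated gold set and compare with an ICD-9
   code rule.

## Tagging and context resolution

Matching is token based. The tokenizer treats maximal alphanumeric (plus
apostrophe) runs as tokens and every other non-space character as its own
token, so hyphenated lexicon surfaces ("in-breast recurrence") align with
note text however the punctuation falls. Sentences break on `.`, `!`, `?`,
`;` and blank lines. Character spans are 0-based half-open into the
newline-normalized text (CRLF → LF), and lowercasing is used for matching
only — the raw surface is preserved in the output.

Within each sentence the tagger takes the **longest match, left to right,
consuming matched tokens**. This is what makes the most specific word class
win: "diffuse skeletal mets" fires `METSBONE` once rather than also firing
a bare "mets" term. A consequence (and a deliberate contract) is that no
token belongs to two mentions and no mention crosses a sentence boundary.

Context resolution scans up to `window = 6` tokens on each side of a
mention, bounded by the sentence and truncated at scope terminators
("but", "however", "although"). Within the window, trigger phrases are
matched longest-first, which gives pseudo-negation its precedence for free:
in "no increase in bone mets" the phrase "no increase in" consumes the
tokens that would otherwise match the bare negation "no". Negation sets
polarity, family triggers set the experiencer, hypothetical triggers set
temporality; the three attributes are independent, so "mother had no bone
mets" is both negated and family-experienced. The six-token window is the
conventional NegEx-style default; it is configurable per run.

Historical temporality ("diagnosed with MBC 14 months ago at an outside
hospital") is *not* modeled. Simple timestamp heuristics are known to fail
on exactly such phrases, and onset-date extraction is out of scope here.

## The distant-label rule

A patient routed through text labeling (stages 0–III or missing stage, at
least one note) is labeled `distant_positive` iff at least one mention is

* from a site class — `METSBONE`, `METSBRAIN`, `METSLIVER`, `METSLUNG` —
  i.e. indicates both metastatic disease *and* a distant location;
* positive in polarity, present in temporality, and about the patient.

Less specific classes (`DRECUR`, `METSNOS`, `MBC`, ...) never trigger the
rule, strictly. Patients with missing stage and notes flow through the
distant branch — they are not stage IV, and their notes are informative.
An optional adjudication table of expert labels supersedes the text rule,
mirroring physician review of borderline cases.

## Features and the classifier

NLP features count, per word class × note type × {total, positive,
negated}, the patient's present-tense patient-experienced mentions, plus an
"ALL" note-type aggregate and one auxiliary per-class tally of
family/hypothetical mentions. Counts are raw, not proportions — the simpler
reading of "frequency", and scale is handled by the penalty. The four site
classes are excluded from features because they define the labels; keeping
them would let the model learn the labeling rule back verbatim. Registry
features are one-hot with an explicit `missing` level everywhere (diagnosis
year binned <2005 / 2005–2009 / 2010–2015; age numeric, standardized by the
training mean/SD stored with the model). Configuration A uses registry
features only, B NLP only, C both; the feature count is therefore
spec-driven rather than fixed, since it depends on the note-type inventory
of the data at hand.

The classifier minimizes the explicitly stated objective

$$ J(b_0, b) = \frac{1}{n}\sum_i \big[\log(1+e^{\eta_i}) - y_i\eta_i\big]
   + \frac{\lambda}{2}\lVert b\rVert_2^2, \qquad \eta_i = b_0 + x_i^Tb, $$

i.e. mean binomial negative log-likelihood plus a ridge penalty on the
slopes, intercept unpenalized, features unstandardized. This is glmnet's
ridge parameterization (`alpha = 0`, `standardize = FALSE`), so glmnet is
the optimizer; the test suite checks the fitted coefficients against a
direct BFGS minimization of $J$ to $10^{-4}$. Ten-fold cross-validation
(folds stratified by label and seeded) selects `lambda.1se`, the largest
penalty whose mean CV deviance is within one standard error of the minimum
— preferring the most regularized model statistically indistinguishable
from the best, a sensible choice when many count features are correlated.
The probability cutoff maximizes F1 over the *out-of-fold* predicted
probabilities (whether the original choice used out-of-fold or refit
probabilities is ambiguous; out-of-fold is the honest variant), tie-broken
toward 0.5 and then toward the smaller cutoff. Class imbalance is handled
only through this cutoff, with no reweighting.

## Evaluation machinery

Point metrics come from the confusion matrix; a ratio with a zero
denominator is reported as absent, never as zero. Confidence intervals are
percentile bootstrap — patients resampled with replacement, metric
recomputed, 2.5th/97.5th percentiles by linear interpolation — rather than
Wilson or BCa intervals, because the patient-resampling percentile
procedure applies uniformly to every metric reported. Resamples where a
metric is undefined are skipped and counted; more than half undefined is an
error.

AUC is the Mann–Whitney statistic with half credit for ties (computed from
average ranks, identical to concordant-pair counting, which the tests
verify by brute force). The DeLong interval uses the placement-value
covariance estimator with a normal approximation truncated to [0, 1]; it is
reported only for probabilistic classifiers, since binary labels have no
score to rank. Both are implemented in-package — they are short, their tie
conventions need to be pinned down, and the test suite cross-checks them
against an independent reference implementation.

The ICD-9 benchmark classifies a patient as metastatic iff any diagnosis
code has string prefix 196–199 before the decimal point. Prefix matching
(not numeric ranges) avoids accidental hits like "1967.1"; the full 199.XX
block is included as written.

## Terminology expansion

`expand_terminology()` supports lexicon curation: it builds a PPMI
co-occurrence matrix (symmetric 5-token window within sentences) over a
vocabulary of unigrams and mined phrases, reduces it to `d = 50` dimensions
with truncated SVD, and ranks non-seed vocabulary by cosine similarity to
each seed term. PPMI+SVD was chosen over neural embeddings because it is
deterministic given the corpus and well-behaved at desk scale. Phrases are
mined as contiguous bigrams with PMI above a threshold (seen at least
twice); multi-word seed surfaces of any length are merged first and
protected from being fragmented, and overlapping phrase occurrences are
resolved by descending PMI rather than left-to-right greed, so a spurious
high-frequency pair cannot eat a token of a genuine phrase. Longer mined
phrases arise as bigrams over already-merged units. Candidates are written
to a review file with a blank decision column: terminology growth is a
human-in-the-loop process, and nothing is ever merged into the lexicon
automatically.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
protected health information. Its design choices:

* **Templated text, not generative prose.** Each planted mention renders
  one template sentence ("Imaging shows {term}.", "No evidence of
  {term}.", "Her mother had {term}.", "Rule out {term}."), so the class,
  attributes and character span of every mention are known exactly and the
  tagger can be held to *exact* manifest recovery.
* **Study-condition defaults.** Stage at diagnosis follows registry-like
  proportions (≈4.3% stage IV); 14% of early-stage patients recur, matching
  the positive rate among distant-labeled patients; text-noise defaults
  (false-negative 0.111, false-positive 0.203) encode the distant-label
  operating point of sensitivity 0.889 / specificity 0.797; ICD-9 code
  rates (0.93 for cases, 0.53 for controls) encode the benchmark's
  characteristic high-sensitivity/low-specificity profile. Other registry
  marginals are uniform with a small missing rate — they are nuisance
  covariates here.
* **Over-dispersion.** Note and mention counts are negative-binomial;
  controls can have zero notes (≈17% do), which exercises the
  no-note exclusion branch. Recurrent patients always have at least one
  note; a configuration that forces recurrent patients to zero notes is
  rejected.
* **Signal for the classifier.** Cases carry correlated non-site mentions
  (`DRECUR`, `MBC`, `RECUR`, ...) at higher rates than controls, so the
  site-class-free feature set is informative; controls receive negated,
  family and hypothetical distractors so context resolution matters.

What the generator does **not** emulate: real clinical prose (abbreviation
ambiguity, section structure, copy-forward), correlated registry
covariates, temporal disease trajectories, or inter-annotator disagreement
in the gold set. Passing tests therefore demonstrate that the machinery is
correct under the stated statistical conditions, not that the shipped
lexicon or operating point transfers to any particular health system's
notes.

## Numerical choices and degenerate inputs

* Spans are 0-based half-open; CRLF is normalized before indexing.
* Empty note text yields zero mentions; an empty corpus yields an empty,
  schema-stable mentions table; malformed note records are skipped with a
  warning and counted.
* Undefined metric ratios are `NA`, and bootstrap intervals degrade to
  `NA` with a warning when a degenerate predictor leaves a metric undefined
  in most resamples (a registry-only classifier on uninformative synthetic
  covariates can predict a single class).
* Zero-variance feature columns are retained (the ridge penalty handles
  them) but logged.
* Cutoff ties break toward 0.5, then toward the smaller grid point;
  all-identical probabilities fall back to 0.5 with a warning.
* Fold assignment, bootstrap resampling and all simulation draw from seeded
  RNG; fitting restores the caller's RNG state.

## Problem sizes

The test suite exercises cohorts of 150–5000 patients: exact manifest
recovery on a noise-free 1000-patient cohort, operating-point recovery
(binomial 95% bands) on 5000 patients, and classifier properties on
2000-observation designs. The acceptance script simulates 4000 patients,
which yields roughly 600 recurrent cases and a stable gold-set evaluation
while keeping a full run in the low minutes on one core.

## Known limitations

* The bundled lexicon is a faithful but partial serialization of the
  concept table it derives from (that table prints example terms only);
  real deployments should expand it against local notes with
  `expand_terminology()` and expert review.
* The tagger has no section awareness, coreference, or abbreviation
  disambiguation; a mention in a pasted outside report reads the same as
  current disease.
* Recurrence *dates* are out of scope; labels are patient-level and
  atemporal.
* The classifier is intentionally simple (one penalized linear model); the
  framework's value is the labeling scheme, not the estimator.
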