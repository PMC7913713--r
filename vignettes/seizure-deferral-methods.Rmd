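---
title: "Methods: deferral and low-trust filtering for seizure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deferral and low-trust filtering for seizure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizedefer)
```

## The problem this package addresses

Long-term EEG monitoring of people with epilepsy produces days of signal
per patient, of which seizures occupy minutes.  Automated detectors cut
the recording into 2-s feature segments at 50% overlap, classify each
segment, and post-process the per-segment predictions into discrete
*seizure flags*.  Two complementary strategies make an imperfect
detector clinically usable:

1. **Deferral**: hand the recording segments on which the classifier is
   least confident to a human annotator (modelled as perfect), trading
   review time for detection sensitivity.
2. **Low-trust filtering (LTF)**: before flagging, discard the
   per-segment predictions that look least trustworthy, which removes
   false detections caused by artifacts without retraining the
   classifier.

`seizedefer` implements both, together with the event-based metrics,
the calibration and trust-scoring machinery, the cross-validation
harnesses that select the filtering percentage, and a synthetic cohort
generator that replaces the (private) clinical recordings for testing.

## The processing chain

### Segments, labels, flags

A recording of $T$ seconds holds $T-1$ segments starting at
$0,1,\dots,T-2$ s.  Two label regimes exist: *full-seizure* (FS) labels
mark every segment overlapping an annotated event by at least 1 s;
*clear-ictal* (CI) labels mark only the nine segments fully contained
in a designated 10-s window with an unambiguous ictal pattern, selected
by priority: first 10-s window with an amplitude rise over the
pre-event background, else the first with a frequency-content change,
else the window at seizure onset.  The overlap and containment
thresholds are package choices (the qualitative rules do not fix them):
1 s is the natural majority rule for a 2-s segment, and full
containment guarantees CI training segments are purely ictal.

Flags follow the *more-than-7-of-10* rule: a sliding block of 10
consecutive segments (1-s hop) is flagged when at least 8 are predicted
ictal; within a run of consecutive flagged blocks only the first is
retained.  Because of the 50% overlap a 10-segment block physically
spans 11 s; the flag interval is stored as $[s, s+11]$ and reported
nominally as a 10-s flag.

### Confidences and trust scores

A margin classifier supplies a signed distance $d$ to its separating
hyperplane.  Temperature scaling maps it to a probability
$p_a = 1/(1+e^{-a d})$, $a>0$; the decision threshold sits at
$p_a = 0.5$ for every $a$, so the temperature can never change the
predicted class, and the confidence $|p_a - 0.5|$ ranks segments
exactly as $|d|$ does.  Consequently every deferral or filtering
decision driven by the classifier's own confidence is
temperature-invariant, and raw distances are an admissible confidence.

The trust score of a segment is computed in a 20-component PCA
projection of the training features: the Euclidean distance to the
nearest reference point of the *other* class divided by the distance to
the nearest reference point of the *predicted* class.  Scores above 1
mean the prediction looks typical; artifact-like segments score low for
both classes.  No density-based pruning of the reference sets is
applied, which removes the two hyper-parameters such pruning would
introduce.  Reference sets come from a subsample: every
seizure-labelled segment, plus up to 100 one-minute background windows
per patient drawn from a 15-min grid (5-min grid when fewer than 100
candidates exist; all windows when even that is not enough — the only
monotone completion of the fallback rule).  The projection is fitted on
this same subsample, since that is the data the model sees.  Exact
duplicates of a reference point receive score $+\infty$ (or 1 when
both distances vanish); nearest-neighbour value ties are irrelevant to
the ratio.

### Low-trust filtering

Per patient, the fraction $q$ of segments with the lowest trust (or
confidence) is marked untrustworthy, identically across patients.  Each
10-block is then re-evaluated: with $r<5$ marked segments the block is
flagged when the mean of the remaining $10-r$ predictions exceeds 0.7;
with $r\ge 5$, when the mean of the 5 highest-trusted predictions
(drawn from all 10, ties to earlier segments) exceeds 0.7.  With
$q = 0$ this is exactly the 8-of-10 rule, since a mean above 0.7 over
10 binary predictions requires at least 8 ones — which also supports
reading "more than 7" strictly as $\ge 8$.

### Deferral

Every flag is centred in a 300-s segment (shifted inward at recording
boundaries); flag segments closer than 300 s are merged; the remaining
signal is tiled left-to-right with 300-s segments, the last remainder
of each gap allowed shorter.  We follow the operational tiling rule
and accept sub-300-s remainder pieces also between merged flag
segments; a remainder too short to contain one full 2-s segment gets
score $+\infty$ so confidence sweeps never abort on it.  Each non-flag
segment is scored by the mean of its $p_\mathrm{low}$ percent
least-confident 2-s segments ($\lceil p_\mathrm{low}/100\cdot n\rceil$,
at least one; reported default $p_\mathrm{low}=5$).  Flag segments are
deferred unconditionally; the rest are deferred in increasing score
order until the deferred time reaches the requested fraction of the
recording (the quota is on recording *time*, matching how deferral
curves are plotted against "fraction of the data"; the first segment
crossing the quota is included).  The annotator is perfect: reviewed
false positives vanish, and a seizure with at least 10 s of deferred
extent is detected.  A seizure split so that neither its deferred nor
its non-deferred part holds 10 s, with no flag on the non-deferred
part, stays undetected.  Detection delays are only averaged over
events detected by a flag; purely human-detected events are excluded
(an algorithmic delay is undefined for them).  An alternative analysis
mode does not prioritize flag segments and treats a flag as reviewed
when it overlaps deferred time by at least 1 s.

### Metrics and testing

Scoring is event-based: a flag overlapping an event makes it a true
positive (several flags still count once); unmatched events are false
negatives; unmatched flags are false positives, with FPs whose starts
lie within 10 s of each other merged (start-to-start anchoring chosen
for determinism).  Detection sensitivity, PPV, F1 and mean delay are
computed per patient and averaged over patients with seizures; the FDR
per 24 h over all patients.  Excluding seizure-free patients from the
DS average is forced by its undefined denominator.  Model comparisons
use the one-sided paired Wilcoxon signed-rank test at 0.05 (exact null
for small tie-free samples, tie-corrected normal approximation
otherwise, as `stats::wilcox.test` switches); all-zero difference
vectors return $p=1$.  Ranking agreement between confidences and trust
scores is the per-patient Kendall rank correlation, averaged.

### Choosing the filtering percentage

For trust-based LTF the percentage is chosen by nested
cross-validation: patients are randomly partitioned into 6 folds under
balance bounds on per-fold seizure load and recording days
(rescaled from the clinical bounds to the cohort's totals; rejection
sampling with an attempt budget).  For each test fold the remaining
folds form two inner half-cohorts (two merged fold pairs; the leftover
fold split in half by greedy seizure-load balancing); a trust model is
fitted on each half and the F1-optimal $q$ found on the other; the
test-fold $q$ is the mean of the two inner optima and may fall
off-grid (it is applied as-is, since filtering takes
$\lfloor q\,n\rfloor$ segments).  Final test scoring uses a trust
model fitted on all patients except the one under evaluation.  The
inner objective is the patient-averaged F1, consistent with how every
other metric is aggregated.  For confidence-based LTF a
leave-one-patient-out grid search over $(a, q)$ is used; by the
temperature-invariance above, the chosen $q$ cannot depend on $a$.

## The synthetic world

The generator (`sim_config()`, `generate_cohort()`) replaces a private
clinical cohort of 54 patients (42 with seizures, about 4 days each,
114 seizures in roughly 220 days of signal).  The full-scale preset
mirrors that shape; the default desk preset (12 patients x 6 h,
seizure rate 2.5, durations 20-120 s) keeps every pipeline stage
exercised at laptop scale — seizure density is deliberately higher
than clinical reality so that a few hours of recording contain enough
events to estimate per-patient metrics.

Features are class-conditional Gaussian with identity covariance:
non-seizure segments at $m_0 = 0$, seizure segments at $m_1$ with
$\lVert m_1 - m_0\rVert$ = `class_separation` (default 4, which puts
per-segment Bayes error near 2% — hard enough that the detector
misses events, as real detectors do).  The separation direction spans
features 3..67; features 1 and 2 are reserved as amplitude and
frequency-change proxies so the clear-ictal selection rule has
something to operate on.  Each seizure draws a mechanism — amplitude
rise (70%), frequency change (20%), neither (10%) — and elevates the
corresponding proxy by 3 SD from its clear-ictal start, so all three
priority branches of the selection rule occur.

Artifacts are rhythmic bursts (default 10 per 24 h, 30 s long) whose
contaminated segments are drawn around
$m_1 + \texttt{artifact\_shift}/\sqrt2\,(e_1+e_2)$: confidently on the
seizure side of any sensible decision boundary (hence false
positives), yet `artifact_shift` (default 6) away from the seizure
mean and further from the non-seizure mean (hence low trust).  Bursts
cycle 4 s contaminated / 1 s clean (`artifact_duty = 0.8`), as
movement and chewing artifacts do.  The duty cycle matters
structurally: a burst contaminating every segment would produce
windows with 9 or 10 positive predictions, which the LTF fallback rule
can never un-flag (the mean of the 5 highest-trusted predictions is
then at least 0.8); rhythmic bursts yield the characteristic
8-positives-2-trusted-negatives windows that filtering removes.  An
early generator draft with independent per-segment contamination was
discarded for exactly this reason.

What a green test establishes — and what it does not: the synthetic
cohort has Gaussian features, stationary background, independent
segments and artifacts that are *constructed* to be separable by trust
scores.  Passing tests therefore validate the post-processing logic,
the selective-prediction identities and the CV plumbing, not clinical
performance; none of the clinical headline numbers are reproduced
here, and the marginal distribution of real EEG features is unknown
(the Gaussian choice is a stand-in, not a claim about data).

## Numerical and degenerate-input choices

* The margin classifier is a hand-written linear, class-weighted,
  L2-regularized squared-hinge SVM fitted by L-BFGS from a zero start:
  convex, deterministic, and near-Bayes-optimal for the generator's
  homoscedastic Gaussian classes.  No kernel SVM library is required;
  an RBF machine would add hyper-parameters without changing anything
  downstream, since the post-processing consumes only $d$.
* Features are standardized inside `train_classifier()`; constant
  columns get unit scale.  Distances are geometric ($f(x)/\lVert w\rVert$).
* Trust-model projections keep `min(20, feature_dim, n-1)` components;
  the nearest-neighbour search is exact, chunked, and folds the
  reference norms into a single BLAS product per chunk.
* Tie-breaks are always "earlier segment first" (masking, top-5
  selection), making every pipeline stage deterministic given seeds.
* Series shorter than 10 segments yield zero flags rather than errors;
  an event shorter than 10 s is an annotation-contract violation and
  errors.
* Fold plans, subsampling draws and cohort generation take explicit
  seeds; repeated calls are identical.

## Known limitations

* No raw EEG is synthesized or read: the package starts at the
  feature-matrix level (EDF ingestion is an extension point only).
* The 67 features of the clinical pipeline are not reproduced; feature
  extraction is out of scope.
* The alternative LTF window rules and jointly-learned
  classifier/rejector schemes are not implemented.
* Kendall correlation is computed exactly and is quadratic in series
  length; long series are subsampled (cap configurable) in the
  experiment driver.
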