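---
title: "Graph-based disease-progression subphenotyping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based disease-progression subphenotyping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(progphen)
```

progphen identifies subgroups of patients who traverse the
Pre-MCI &rarr; MCI &rarr; AD continuum in clinically distinct ways, using
nothing but routinely collected longitudinal EHR codes. This vignette
explains each stage of the model, the parameters that matter, the synthetic
data the package is validated on, and the design decisions taken where the
method leaves room.

## The pipeline at a glance

1. **Enhanced encounter windows.** Each patient's record is tiled with
   contiguous half-open 90-day windows anchored at the first encounter. A
   window becomes a binary vector over 5-year age bins, sex, race-ethnicity,
   Phecodes, ATC level-3 drug classes, and discretized vitals (BMI, blood
   pressure, smoking), and carries the patient's progression state in the
   *following* window as its supervised label.
2. **Directed patient graph (DPG).** Windows are nodes. Each node is linked
   to its top-k Jaccard-similar windows of other patients, and consecutive
   windows of one patient are always chained. Every edge points from the
   earlier window to the later one and stores the elapsed days.
3. **Outcome-oriented representation learning.** A two-layer graph
   convolution with a softmax head predicts the next-window state; the
   flagship encoder is a MagNet-style spectral convolution on the magnetic
   Laplacian, which keeps edge direction in a complex phase. The hidden
   activations after the second layer are the node embeddings.
4. **DTW K-means.** Per-patient embedding sequences are clustered under
   dynamic time warping; K is scanned with silhouette (SS) and
   Davies-Bouldin (DBI) validity (acceptable when SS > 0.25 and DBI < 1)
   and checked by bootstrap stability (100 iterations, 90% subsamples,
   Jaccard agreement after Hungarian label matching).
5. **Characterization and predictability.** Clusters are profiled with
   transition-time statistics, Kaplan-Meier curves (Greenwood log(-log)
   intervals), log-rank tests and prevalence contrasts; a separate model
   asks whether pre-index (first-MCI-date) information predicts the cluster.

## The magnetic Laplacian

For a directed adjacency \(A\), the package forms
\(A_s = (A + A^\top)/2\), the phase
\(\Theta = 2\pi q\,(A - A^\top)\), the Hermitian matrix
\(H = A_s \odot e^{i\Theta}\) and the normalized Laplacian
\(L = I - D_s^{-1/2} H D_s^{-1/2}\). \(L\) is Hermitian with real
eigenvalues in \([0, 2]\); at \(q = 0\) it reduces to the symmetrized
normalized Laplacian, and at \(q = 0.25\) a one-way edge becomes purely
imaginary.

**Choice of q.** The default is \(q = 0.05\), not the maximal 0.25. At
\(q = 0.25\) the real part of every off-diagonal entry is
\(\cos(\pi/2) = 0\): neighbor aggregation then happens only in the
imaginary channel, as the *difference* between later and earlier
neighbors. That difference cancels the shared clinical signal that
neighbors carry, so the convolution stops smoothing and the learned
representation degrades sharply. A small positive charge keeps
\(\cos(2\pi q) \approx 1\) — near-full averaging in the real channel —
while the imaginary channel still sees direction. The parameter remains
configurable in `encoder_config()`.

## Training the encoder

Optimization is Adam (learning rate 1e-3) for up to 200 epochs, full-graph
(transductive) with patient-level label masks: patients are split 70/10/20
into train/validation/test, validation loss drives early stopping (patience
20) and best-checkpoint selection, and each patient's final window carries
no label. The loss is focal loss with \(\gamma = 2\) by default (the usual
focal-loss convention; \(\gamma = 0\) recovers cross-entropy exactly).

**Dropout.** A unit-level inverted dropout of 0.5 is applied between the
two convolution layers during training (evaluation and embedding extraction
use the full network). This follows the reference implementations of the
graph-convolution family, and it matters here beyond regularization: the
next-window prediction task is an *auxiliary* objective whose purpose is a
faithful longitudinal representation, and without dropout, prolonged
training collapses the within-class variability of the hidden units onto
the three outcome classes — exactly the patient-level heterogeneity the
clustering stage needs. Dropout keeps units from co-adapting to the three
logits and preserves that heterogeneity while discrimination keeps
improving.

**Embedding scaling.** Before DTW, embedding units are standardized across
windows (`scale = TRUE` in `embedding_sequences()`), so no single
high-variance unit dominates the pointwise Euclidean distances. A MagNet
unit is one complex number whose real and imaginary parts live in separate
columns; each unit is therefore centred and divided by one shared scale
(its total real+imaginary standard deviation). Standardizing the two parts
separately would blow the small imaginary channel up to unit variance —
amplifying a direction-contrast signal that behaves like noise in the
sequence geometry — which measurably degrades the clustering.

## DTW and the K-means objective

DTW is the minimum cumulative Euclidean pointwise distance over monotone,
boundary-anchored warping paths with steps (1,0), (0,1), (1,1), computed by
the classic dynamic program (Rcpp; no band constraint by default). The
clustering objective is
\(J = \sum_i \sum_{j \in C_i} \mathrm{DTW}(H_j, \mu_i)\), minimized by
alternating nearest-centroid assignment and DTW-barycenter-averaging (DBA)
updates. Implementation choices:

* centroids have fixed length equal to the median sequence length, except
  that a singleton cluster's centroid is its member itself (the barycenter
  of one sequence);
* initialization is k-means++-style under DTW with `n_init = 5` seeded
  restarts;
* an emptied cluster is re-seeded from the sequence farthest from its
  centroid;
* the recorded objective is non-increasing within a restart: the loop keeps
  the best state and stops if a DBA update would raise J (DBA is a descent
  heuristic, not a guaranteed descent step).

Silhouette and DBI use DTW distances throughout; a K is flagged acceptable
when SS > 0.25 and DBI < 1. The final choice of K is left to the analyst
(the quantitative scan is one input into it). The two indices are not
interchangeable: on the planted cohort the recovered clustering clears the
silhouette line comfortably while DBI sits above 1 even when the planted
labels are recovered exactly, because the generator's within-subtype
transition-time dispersion is deliberately generous (sojourn sds of
570-730 days) — members spread around their centroid *in time* even when
their feature profiles are homogeneous, and DBI compares that spread
directly against centroid separation. Under DTW, DBI < 1 demands clusters
tight in both profile and timing; treat it as the stricter index. Bootstrap stability refits on
90% subsamples, assigns *all* sequences to the subsample centroids, aligns
labels with a maximum-overlap Hungarian assignment, and reports per-cluster
Jaccard agreement with the full-sample solution alongside SS and DBI
(re-fitting rather than re-assigning on the full data would leave the
subsample centroids unused, so nearest-centroid assignment is the reading
implemented).

## The synthetic cohort generator

`generate_cohort()` plants a known subphenotype structure so every stage is
testable without access to protected records:

* **Progression process.** A three-state semi-Markov chain with log-normal
  sojourns. Default MCI-to-AD sojourn means/sds per subtype are
  (854/577, 1236/725, 952/628, 805/563) days; pre-MCI record lengths are
  the corresponding first-record-to-AD times minus the sojourns
  (1541, 1703, 1591, 1560 days); post-AD survival means
  (1460, 900, 950, 1500 days) reproduce the qualitative ordering that the
  slower-progressing subtypes have the poorer five-year survival. Subtype
  shares are (0.51, 0.17, 0.16, 0.16) — the dominant share is the reported
  cohort's largest subphenotype, the remainder split evenly.
* **Inclusion by construction.** Age at first MCI is Normal(76, 8.88)
  truncated at 50; conversion times are resampled to exceed 180 days; at
  least 365 days of record exist on both sides of the index date.
* **Chronic conditions, not memoryless codes.** Subtype profiles are
  *patient-level* prevalences (prevalence is how subphenotypes are
  characterized clinically). One uniform draw per patient per code decides,
  against the cumulative state-specific prevalence, whether a condition is
  active in each state — so comorbidity burden accumulates with disease
  stage — and active conditions are documented in each 90-day window with
  recurrence probability 0.9. An earlier design that redrew codes
  independently per window produced memoryless records unlike any real
  EHR and, incidentally, far harder clustering for the wrong reason
  (pointwise noise rather than patient heterogeneity).
* **The separation dial.** `separation` in [0, 1] scales (a) the
  subtype-signature prevalence offsets (at 1, a subtype's signature codes
  sit near 0.9 prevalence for its patients and are strongly suppressed for
  others; at 0 all profiles coincide) and (b) the spread of the subtype
  timing parameters around their weighted mean. At `separation = 0` the
  subtypes are therefore fully exchangeable — planted labels are
  unrecoverable in principle — and at 1 the defaults above apply
  unchanged. Separation = 1 is the generator's definition of "clearly
  distinct subphenotypes"; it is deliberately an easy regime, because its
  role is to verify that the pipeline recovers structure that is
  unambiguously present, not to simulate the difficulty of any particular
  real cohort.
* **Encounters.** Poisson arrivals at 3 per 90-day window (the windowing
  granularity downstream); state-marker diagnoses are guaranteed on the
  transition dates and recur with probability 0.6 per window afterwards.
  Encounter-frequency distributions of real research networks are not
  public; this rate is a plausible placeholder, not a calibrated value.

What passing tests on this generator do *not* show: robustness to coding
sparsity and site effects, to non-chronic (episodic) conditions, to
state misclassification in the code lists, or to cohorts whose subtype
structure is weaker than the planted one. The `separation` dial gives a
one-parameter path toward harder regimes, and `separation = 0` verifies
the pipeline does not hallucinate structure.

## Cohort filters and featurization details

* "More than six months" is read as conversion strictly greater than 180
  days; "one year" as at least 365 days; both at day resolution.
* Windows are half-open `[start, start + 90)`, anchored at each patient's
  first encounter; an event dated exactly on a boundary belongs to the next
  window.
* Age bins are uniform 5-year bins from 50 to 90+, with an under-50 bin so
  pre-MCI windows of younger records remain encodable; age is re-evaluated
  at every window start.
* Blood pressure uses the five-class guideline cutoffs (normal, elevated,
  stage 1, stage 2, crisis); both readings must be present.
* States are absorbing from the first qualifying code onward, which makes
  the per-patient label sequence monotone and the next-window label
  well-defined.
* Unmapped diagnosis/drug codes map to a single catch-all feature per
  system, so the feature dimension never depends on map coverage.
* Patients with MCI but no AD code are excluded: the cohort is defined as
  MCI-to-AD converters and the conversion-time rule is undefined without an
  AD date.

## Directed-graph construction details

* The top-k candidate pool contains only *other* patients' windows; a
  patient's own windows are linked by the always-present temporal chain.
  Admitting own windows would spend most of the similarity budget on
  trivially self-similar nodes (a patient's chronic conditions recur every
  window) and sever the cross-patient smoothing the graph exists for.
* Ties in similarity break by descending similarity then node order
  ((patient, window)), and same-date edges orient by node order, so
  rebuilding a graph is bit-reproducible.
* Convolution consumes 0/1 connectivity by default; the stored elapsed-day
  weights can enter as `exp(-days/tau)` via
  `encoder_config(connectivity = "exp_decay")`.

## Problem sizes used in the bundled checks

The packaged end-to-end checks run the full pipeline on a 300-patient
planted cohort (about 12,000 windows) with k = 15 similarity neighbors,
a 64-dimensional MagNet encoder, and DTW K-means at the planted K = 4 —
a desk-scale configuration chosen so the complete suite runs in minutes
while leaving each stage's behavior clearly measurable. Generator-recovery
checks use 1,000 patients. The reported cohort behind the default
parameters is an order of magnitude larger; nothing in the implementation
is specific to the desk scale, and `build_dpg()`'s blocked exact Jaccard
search is the only stage whose cost is quadratic in the window count.

## Known limitations

* The similarity search is exact and quadratic; beyond ~50k windows an
  inverted-index or LSH candidate generator would be needed.
* DBA with a fixed centroid length is a heuristic; J can stall at local
  minima, which the seeded restarts mitigate but do not eliminate.
* Significance tiers in `prevalence_tests()` are raw, uncorrected p-value
  bands, reported as such; treat them as descriptive.
* The log-rank test is the package's reading of "difference between KM
  curves"; no other test is implied by the method.
* Transductive training means test-set windows participate in message
  passing (not in the loss); deployment to truly unseen patients would
  need an inductive formulation.
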