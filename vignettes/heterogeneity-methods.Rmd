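---
title: "Scoring intratumor heterogeneity from multiplexed tissue imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring intratumor heterogeneity from multiplexed tissue imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycifith)
```

## The problem

Cyclic immunofluorescence (CyCIF) measures a dozen or more protein markers in
every cell of a formalin-fixed tissue section by iterating stain / image /
bleach cycles. Applied to tissue-microarray (TMA) cohorts — hundreds of
tumors, each sampled as triplicate 0.6 mm cores — it yields a per-cell
intensity table spanning hundreds of thousands of cells. `cycifith`
implements the analysis chain that turns such a table (or the underlying
images) into per-patient *intratumor heterogeneity* (ITH) statistics and
tests their association with recurrence: segmentation and quantification,
mixture-model gating, antibody qualification, phenotype clustering and
embedding, the two ITH scores, and the survival battery.

## The two heterogeneity statistics

Cells are clustered into $k$ phenotypes (Gaussian mixture in log, z-scored
marker space; $k = 7$ is the conventional default for the
receptor/lineage panel, and $k$ is configurable because no selection
criterion is implied by the panel itself — a BIC sweep can be run with
`mclust` directly on the features if wanted). Write $p$ for a patient's
cluster-composition vector over its pooled triplicate cores and $q$ for the
cohort-wide composition.

**Composition (GMM) score.**
$$\mathrm{score}(p) = 1 - \lVert q - p\rVert_2 .$$
A cohort-typical patient scores 1; the further a patient's phenotype mixture
sits from the cohort's, the lower the score ("lower = more heterogeneous").
The distance is Euclidean: among the common vector distances this is the
only choice that reproduces the reference worked example
(`gmm_score(rep(.25,4), c(.3,.2,.2,.3))` is exactly 0.9 and
`gmm_score(rep(.25,4), c(.1,.3,0,.6))` is $1-\sqrt{0.21}\approx 0.54$), so
it is locked in by test. The score is deliberately not clamped: its
attainable minimum is $1-\sqrt 2$.

**Embedding dispersion (t-SNE) score.** After a 2-D t-SNE of the same
feature space, with cohort means $(m_1, m_2)$ taken over *all embedded
cells*, a patient with cells $C$ gets
$$S = \sum_{c\in C}(t1_c - m_1)^2 + \sum_{c\in C}(t2_c - m_2)^2 .$$
The literal root $\sqrt S$ grows with $|C|$, which mixes cellularity into
the heterogeneity signal; the package therefore defaults to the
root-mean-square form $\sqrt{S/|C|}$ (invariant to duplicating every cell)
and also offers $\sqrt S$ (`"sum"`) and $\sqrt S / |C|$ (`"mean"`). The
normalization used is recorded on every score table. Cohort-wide (rather
than per-sample) means are used because the definition references all
cells; both the full feature table and the visualization subsample can be
embedded (`subsample = Inf`-like behavior by passing a value at least the
row count).

A third, model-free statistic is the per-patient coefficient of variation
of a single marker's raw intensities (conventionally HER2), `marker_cv()`.

Patients enter scoring only if their pooled cores hold at least 500 cells
(`filter_patients()`, boundary inclusive).

## Stage conventions

* **Segmentation** — watershed on the smoothed (Gaussian, `sigma = 2` px)
  nuclear channel, Otsu foreground, minimum object area 20 px²; these
  seeding parameters are package choices, exposed as arguments, since only
  the watershed itself is canonical. Nuclear masks are expanded 3 px
  (exact Euclidean nearest-label assignment, ties to the lower label ID,
  deterministic) to capture membrane/cytoplasmic signal; centroids and
  areas are reported from the *pre*-expansion mask; pixel coordinates are
  0-based with `x` the column.
* **Gating** — intensities are transformed `log(x+1)`; the +1 offset
  avoids `log(0)` for background cells. `gmm2` fits a 2-component mixture
  and thresholds at the equal-posterior crossing between the component
  means (mixture semantics, rather than the midpoint); `local_min`
  thresholds at the deepest KDE valley (Silverman bandwidth) between the
  outermost modes and falls back to `gmm2`, with a warning, on unimodal
  data. Effectively two-valued inputs are split by a deterministic
  one-dimensional two-means cut.
* **Qualification** — pixel-, cell- and core-level Pearson correlations on
  log intensities (seeded 5000-pair subsamples), dynamic range as the
  P99–P1 log-intensity spread (robust to outliers), strata
  `[0,25) [25,50) [50,75) [75,100]` on percent-positive reference scores,
  and a 1–3 star verdict with configurable thresholds
  (`r_high = 0.7`, matching the "strong concordance" range reported for
  qualified antibodies, `r_low = 0.3`); the published ranking criteria are
  verbal, so the numeric cut-offs are package defaults, not claims.
* **Clustering** — full covariance per component (marker co-expression,
  e.g. ER/PR, is exactly the phenomenon of interest), best-of-`n_init`
  EM fits initialized on random subsets, hard labels by posterior argmax
  with ties to the lower index. Whether to cluster raw, log or normalized
  intensities is a genuine free choice; log + z-score is used for both
  clustering and embedding so the two scores operate in one space.

## The synthetic cohort generator

No imaging cohort ships with the package, so every stage is validated on
`generate_cohort()`, which emulates the structure of a HER2-positive TMA
study: 189 patients by default, triplicate cores, negative-binomial
per-core cellularity (mean 350), an eleven-marker panel, and `k_true`
latent phenotype clusters with log-normal marker intensities (means in
`default_cluster_means()`: a dominant keratin+/HER2+ tumor cluster, an
ER/PR+ tumor cluster, CD45+ immune and CD45+/CD68+ macrophage clusters,
log-SD 0.5).

Design choices worth spelling out:

* **Compositions.** Patient compositions are
  $\mathrm{Dirichlet}(\alpha w)$ around cohort weights $w$, with cores
  jittered around the patient composition (concentration 200, so
  triplicates resemble each other). Default $\alpha = 3$ gives a broad
  spread of patient mixtures; $\alpha \to \infty$ collapses every patient
  onto $w$.
* **Dominant cluster.** $w = (0.55, 0.15, 0.15, 0.15)$ by default. A
  cohort selected for HER2 positivity is dominated by its HER2+ tumor
  phenotype, and the skew matters for the statistics: around a *uniform*
  cohort composition, deviation from the cohort and composition entropy
  are anti-correlated (deviating from uniform always lowers entropy),
  which would invert the intended "low score = heterogeneous" reading.
  With a dominant cluster, patients far from the cohort mixture are
  typically those with expanded minority populations — higher entropy,
  wider phenotype spread, and larger embedding dispersion, so all three
  statistics point the same way.
* **Ground-truth heterogeneity.** The generator defines a patient's true
  heterogeneity as the Euclidean divergence
  $\lVert p - w\rVert_2$ of its true composition from the cohort weights.
  This is the quantity the composition score estimates (up to clustering
  noise), it decreases monotonically in $\alpha$, and it is the scalar the
  recurrence hazard couples to. Shannon entropy of the composition is
  also stored as a descriptive field, but it is *not* the coupled truth:
  under any single-Dirichlet design, entropy and divergence-from-cohort
  are nearly orthogonal, so entropy cannot serve as the latent trait that
  both scores track.
* **Survival.** Event times are exponential with
  $h = h_0\,\exp(\beta\,\lVert p - w\rVert_2)$, $h_0 = \log 2 / 60$
  months$^{-1}$, and `hazard_coupling` $\beta$ (0 by default; 5 in the
  coupled validation studies, chosen at design time to give a strong but
  realistic effect). A fraction `censor_rate` (default 0.35) of patients
  is censored uniformly on $(0, t_{\mathrm{event}})$ — the simplest
  mechanism adequate for sign-recovery testing, not a model of cohort
  follow-up.
* **What is not simulated** — optics (PSFs, autofluorescence,
  registration error), tissue morphology, spatial structure within cores,
  and any non-log-normal intensity behavior of real CyCIF data (the
  log-normal family is an assumption). Passing tests on these cohorts
  demonstrates correctness of the computations and recoverability under
  the stated model, not performance on real tissue.

The image fixture generator (`generate_image_fixture()`) packs
non-overlapping Gaussian nuclei with marker channels held constant within
each true cell disc, so segmentation counts, centroids and quantified
means can be checked against construction.

## Association battery

Scores are tested against clinical features with rank statistics (Wilcoxon
for two-category features: ER, PR, combined grade; Kruskal–Wallis for
combined stage; Spearman for age and the CyCIF-derived Ki67 positivity)
and against recurrence with two Cox proportional-hazards models — one per
score, each adjusted for ER, PR, stage (II and III–IV vs I), age, Ki67 and
high grade. Stage III substages and IV are merged to "III-IV" and grades
I–II merged, mirroring the standard sparse-category combining. Efron tie
handling is used (the common default). Raw p-values are reported without
multiplicity correction, matching how such batteries are conventionally
tabulated; `p.adjust` can be applied downstream. Time units are whatever
the clinical table's `time_months` column carries; the package does not
guess units.

## Numerical and testing notes

* Determinism: every stochastic step (simulation, subsampling, embedding,
  EM initialization) is governed by an explicit integer seed; identical
  configurations are bit-identical, and t-SNE runs single-threaded for
  reproducibility.
* Degenerate inputs: empty images give empty masks (not errors); empty
  score tables propagate through the pipeline with warnings rather than
  crashes; zero-variance markers become zero features; constant
  intensities make gating error out as undefined.
* The validation suite runs on deliberately scaled-down studies — e.g.
  phenotype/heterogeneity recovery on 50 patients × 3 cores × ~300 cells
  with 4 separated clusters, and survival sign recovery on 20 replicates
  of 200-patient cohorts with ~150 cells per patient and 2,500-cell
  embeddings. These sizes were chosen as the smallest at which the
  statistical properties under test are expected to be stable.
* Known limitations: no spatial statistics (neighborhoods, ASCO/CAP-style
  spatial HER2 patterns), no deep-learning segmentation, no UMAP/graph
  clustering, no stitching/registration; the qualification verdict encodes
  configurable thresholds, not a validated clinical rubric.
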