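# cycifith

Single-cell analysis of multiplexed tissue imaging (CyCIF) with
per-patient **intratumor heterogeneity (ITH) scoring**, for
tissue-microarray (TMA) cohorts such as HER2-positive breast cancer
sampled in triplicate 0.6 mm cores.

The package covers the full chain from images (or an exported per-cell
intensity table) to recurrence association:

* **Segmentation / quantification** — watershed nuclear segmentation on
  the Hoechst channel, 3-pixel Euclidean boundary expansion, per-cell
  centroid, nuclear area and mean marker intensities.
* **Gating** — binary positive/negative calls per marker by a
  2-component Gaussian mixture on `log(x+1)` intensities (threshold at
  the equal-posterior crossing) or by the deepest kernel-density local
  minimum; per-core positivity ratios.
* **Antibody qualification** — pixel-, cell- and core-level Pearson
  concordance between candidate and reference antibodies on seeded
  5000-pair subsamples, dynamic range (P99−P1 log intensity), stratified
  cross-assay bins (0–24, 25–49, 50–74, 75–100 percent positive), 1–3
  star verdicts.
* **Clustering / embedding** — k-component Gaussian mixture (full
  covariance) over log, z-scored marker space; median-expression cluster
  profiles; keratin/CD45 lineage annotation; seeded t-SNE embedding.
* **Heterogeneity scores** — for a patient composition *p* over the k
  clusters (triplicate cores pooled, ≥ 500 cells required) and cohort
  composition *q*:

  **GMM score** = 1 − ‖q − p‖₂  (lower = more heterogeneous; 1 iff the
  patient matches the cohort mixture)

  **t-SNE score** = √(Σ(t1 − m₁)² + Σ(t2 − m₂)²) over the patient's
  embedded cells, with (m₁, m₂) the cohort-mean coordinates (higher =
  more heterogeneous; root-mean-square normalization by default), plus
  the per-patient coefficient of variation of a marker (HER2).
* **Association** — Wilcoxon / Kruskal–Wallis / Spearman battery of the
  scores against clinical features, and Cox proportional-hazards models
  (score + ER, PR, stage, age, Ki67, grade; Efron ties).
* **Synthetic cohorts** — a simulator with known ground truth (latent
  phenotype clusters, Dirichlet patient compositions, log-normal
  intensities, heterogeneity-coupled recurrence) so every stage is
  testable without patient data.

## Worked example

```r
library(cycifith)

# the score itself on explicit compositions
gmm_score(c(0.25, 0.25, 0.25, 0.25), c(0.3, 0.2, 0.2, 0.3))
#> [1] 0.9

# a synthetic 40-patient cohort with recurrence coupled to heterogeneity
cfg <- cohort_config(n_patients = 40,
                     cells_per_core = list(mean = 220, dispersion = 0.1),
                     hazard_coupling = 5, seed = 42)
coh <- generate_cohort(cfg)
coh
#> Synthetic CyCIF cohort: 40 patients, 120 cores, 27337 cells, 11 markers, k_true = 4

res <- run_pipeline(coh$cells, coh$clinical,
                    pipeline_config(k = 4, seed = 1, n_init = 1,
                                    embed_subsample = 10000, min_cells = 500))
head(res$scores, 5)
#>   patient_id n_cells gmm_score tsne_score        cv
#> 1       P001     559 0.8174210   11.77467 0.8950691
#> 2       P002     751 0.7525390   13.18663 0.9447379
#> 3       P003     857 0.6816326   12.96573 1.2514620
#> 4       P004     526 0.7267850   13.14258 0.9508491
#> 5       P005     805 0.7133603   11.93133 0.7643760

res$annotation
#> [1] "tumor"          "immune-stromal" "immune-stromal" "tumor"

res$cox$gmm
#> Model (gmm score): n = 38, events = 24
#>                term  log_hr     hr  lower    upper      p
#> 1             score -7.5564 0.0005 0.0000   0.0581 0.0017
#> 2 er_statusPositive -0.9377 0.3915 0.0420   3.6513 0.4104
#> ...
```

Reading the output: `gmm_score` near 1 marks cohort-typical patients,
lower values mark tumors whose phenotype mixture deviates from the
cohort; `tsne_score` grows with the spread of a patient's cells across
phenotype space; `cv` is the unit-free HER2 expression dispersion. In
this simulation recurrence was generated with higher hazard for more
heterogeneous patients, and the fitted Cox model recovers that direction:
the score term's hazard ratio is far below 1 (log HR −7.6, p ≈ 0.002),
i.e. a *higher* (more homogeneous) GMM score is protective.

The methods vignette (`vignettes/heterogeneity-methods.Rmd`) documents
the model, parameter defaults, simulator design and numerical choices.

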