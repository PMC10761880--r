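#' Configure a synthetic TMA cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults emulate a tissue-microarray study of HER2-positive invasive
#' breast cancer: 189 patients sampled in triplicate 0.6 mm cores, a few
#' hundred cells per core (roughly 200k cells cohort-wide), an
#' eleven-marker receptor/lineage panel, and cells drawn from latent
#' phenotype clusters with log-normal marker intensities. One phenotype
#' cluster (keratin+/HER2+ tumor cells) dominates the cohort mixture, as
#' expected when a cohort is selected for HER2 positivity; heterogeneous
#' patients are those whose cluster composition deviates from that
#' cohort-typical mixture.
#'
#' Per-patient compositions are drawn from
#' `Dirichlet(composition_alpha * global_weights)`: small
#' `composition_alpha` makes patients deviate strongly from the cohort
#' mixture (high intratumor-heterogeneity spread across the cohort), large
#' values make every patient cohort-like. Triplicate cores share the
#' patient composition up to a small Dirichlet jitter.
#'
#' @param n_patients number of patients.
#' @param cores_per_patient TMA cores per patient (default 3, triplicate).
#' @param cells_per_core list with `mean` and `dispersion`: per-core cell
#'   counts are negative-binomial with that mean and variance
#'   `mean + dispersion * mean^2`.
#' @param markers character vector of marker names. `"Hoechst"` (nuclear
#'   counterstain) may be included; it is simulated cluster-independent.
#' @param k_true number of latent phenotype clusters (>= 2).
#' @param cluster_means `k_true x length(markers)` matrix of per-cluster
#'   log-intensity means (log AU); default is a separated lineage-themed
#'   layout, see [default_cluster_means()].
#' @param cluster_sds per-cluster per-marker log-intensity SDs; a scalar,
#'   a vector of length `k_true`, or a full matrix (default 0.5).
#' @param global_weights cohort-level cluster mixing weights (sum to 1);
#'   default puts 55% of cells in cluster 1 and splits the rest evenly.
#' @param composition_alpha Dirichlet concentration controlling
#'   patient-to-patient composition heterogeneity (> 0; default 3).
#' @param core_jitter concentration of the within-patient core-level
#'   Dirichlet jitter (larger = cores more similar; default 200).
#' @param hazard_coupling log-hazard increment per unit of true
#'   heterogeneity (Euclidean divergence of the patient composition from
#'   `global_weights`); 0 decouples recurrence from heterogeneity.
#' @param baseline_hazard recurrence hazard (events per month) for a
#'   patient with heterogeneity 0; default `log(2)/60` (median 60 months).
#' @param censor_rate expected fraction of patients censored before their
#'   event (uniformly on `(0, t_event)`); default 0.35.
#' @param seed integer RNG seed; identical configurations generate
#'   bit-identical cohorts.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 189,
                          cores_per_patient = 3,
                          cells_per_core = list(mean = 350, dispersion = 0.15),
                          markers = default_marker_panel(),
                          k_true = 4,
                          cluster_means = NULL,
                          cluster_sds = 0.5,
                          global_weights = NULL,
                          composition_alpha = 3,
                          core_jitter = 200,
                          hazard_coupling = 0,
                          baseline_hazard = log(2) / 60,
                          censor_rate = 0.35,
                          seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 1)
  cores_per_patient <- check_count(cores_per_patient, "cores_per_patient", min = 1)
  if (!is.list(cells_per_core) || is.null(cells_per_core$mean)) {
    stop_("invalid configuration: 'cells_per_core' must be list(mean=, dispersion=)")
  }
  cells_per_core$mean <- check_number(cells_per_core$mean, "cells_per_core$mean", min = 1)
  cells_per_core$dispersion <-
    check_number(cells_per_core$dispersion %||% 0.15, "cells_per_core$dispersion", min = 0)
  if (!is.character(markers) || length(markers) < 1L || anyDuplicated(markers)) {
    stop_("invalid configuration: 'markers' must be distinct marker names")
  }
  k_true <- check_count(k_true, "k_true", min = 2)
  if (is.null(cluster_means)) {
    cluster_means <- default_cluster_means(k_true, markers)
  }
  cluster_means <- as.matrix(cluster_means)
  if (nrow(cluster_means) != k_true || ncol(cluster_means) != length(markers)) {
    stop_("invalid configuration: 'cluster_means' must be %d x %d (one entry per cluster per marker)",
          k_true, length(markers))
  }
  colnames(cluster_means) <- markers
  if (is.matrix(cluster_sds)) {
    if (nrow(cluster_sds) != k_true || ncol(cluster_sds) != length(markers)) {
      stop_("invalid configuration: 'cluster_sds' matrix must be %d x %d",
            k_true, length(markers))
    }
  } else if (length(cluster_sds) %in% c(1L, k_true)) {
    cluster_sds <- matrix(cluster_sds, k_true, length(markers))
  } else {
    stop_("invalid configuration: 'cluster_sds' must be scalar, length k_true, or a matrix")
  }
  if (any(!is.finite(cluster_sds)) || any(cluster_sds <= 0)) {
    stop_("invalid configuration: 'cluster_sds' must be positive")
  }
  if (is.null(global_weights)) {
    global_weights <- c(0.55, rep(0.45 / (k_true - 1), k_true - 1))
  }
  if (length(global_weights) != k_true || !is_composition(global_weights)) {
    stop_("invalid configuration: 'global_weights' must be %d nonnegative fractions summing to 1",
          k_true)
  }
  composition_alpha <- check_number(composition_alpha, "composition_alpha")
  if (composition_alpha <= 0) {
    stop_("invalid configuration: 'composition_alpha' must be > 0")
  }
  core_jitter <- check_number(core_jitter, "core_jitter")
  if (core_jitter <= 0) stop_("invalid configuration: 'core_jitter' must be > 0")
  hazard_coupling <- check_number(hazard_coupling, "hazard_coupling")
  baseline_hazard <- check_number(baseline_hazard, "baseline_hazard")
  if (baseline_hazard <= 0) stop_("invalid configuration: 'baseline_hazard' must be > 0")
  censor_rate <- check_number(censor_rate, "censor_rate", min = 0, max = 1)
  seed <- check_count(seed, "seed", min = 0)

  structure(list(
    n_patients = n_patients, cores_per_patient = cores_per_patient,
    cells_per_core = cells_per_core, markers = markers, k_true = k_true,
    cluster_means = cluster_means, cluster_sds = cluster_sds,
    global_weights = as.numeric(global_weights) / sum(global_weights),
    composition_alpha = composition_alpha, core_jitter = core_jitter,
    hazard_coupling = hazard_coupling, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, seed = seed
  ), class = "cohort_config")
}

#' Default CyCIF marker panel
#'
#' The receptor/lineage panel used throughout the package: hormone and
#' growth-factor receptors (HER2, ER, PR, AR), p53, the proliferation
#' marker Ki67, PD-L1, the epithelial marker keratin, the leukocyte marker
#' CD45, the macrophage marker CD68 and the Hoechst nuclear counterstain.
#'
#' @return character vector of marker names.
#' @export
default_marker_panel <- function() {
  c("HER2", "ER", "PR", "AR", "p53", "Ki67", "PD_L1",
    "Keratin", "CD45", "CD68", "Hoechst")
}

#' Default per-cluster log-intensity means
#'
#' For the default eleven-marker panel with `k = 4` this is a
#' lineage-themed layout: a keratin+/HER2+ tumor cluster, a
#' keratin+/ER+/PR+ tumor cluster, a CD45+ immune cluster and a
#' CD45+/CD68+ macrophage cluster, all sharing a Hoechst signal. For any
#' other panel or `k`, a generic well-separated layout is produced: every
#' cluster receives a high mean (5.5 log AU) on a round-robin subset of
#' markers and background (1.5 log AU) elsewhere; a marker named
#' `"Hoechst"` is always cluster-independent at 5 log AU.
#'
#' @param k number of clusters.
#' @param markers marker names.
#' @return `k x length(markers)` matrix of log-intensity means (log AU).
#' @export
default_cluster_means <- function(k, markers) {
  panel <- default_marker_panel()
  if (k == 4L && identical(markers, panel)) {
    m <- rbind(
      #          HER2  ER   PR   AR  p53 Ki67 PDL1 Krt CD45 CD68 Hoechst
      tumor_her2 = c(6.0, 2.0, 2.0, 3.0, 4.0, 4.0, 2.0, 6.0, 1.0, 1.0, 5.0),
      tumor_hr   = c(3.0, 6.0, 5.5, 4.0, 3.0, 3.0, 2.0, 6.0, 1.0, 1.0, 5.0),
      immune     = c(1.0, 1.0, 1.0, 1.0, 2.0, 2.5, 3.0, 1.0, 6.0, 2.0, 5.0),
      macrophage = c(1.0, 1.0, 1.0, 1.0, 2.0, 2.0, 4.0, 1.0, 4.5, 6.0, 5.0)
    )
    colnames(m) <- markers
    return(m)
  }
  m <- matrix(1.5, k, length(markers), dimnames = list(NULL, markers))
  free <- setdiff(markers, "Hoechst")
  for (j in seq_along(free)) {
    m[((j - 1L) %% k) + 1L, free[j]] <- 5.5
  }
  if ("Hoechst" %in% markers) m[, "Hoechst"] <- 5
  m
}

#' Generate a synthetic CyCIF cohort with known ground truth
#'
#' Simulates a per-cell intensity table, a clinical table and the
#' generative ground truth for a TMA cohort described by a
#' [cohort_config()]. Cells belong to latent phenotype clusters; marker
#' intensities are log-normal given the cluster; per-patient cluster
#' compositions are Dirichlet-distributed around the cohort mixture; and
#' recurrence times are exponential with log-hazard proportional to the
#' patient's true heterogeneity (Euclidean divergence of its composition
#' from the cohort mixing weights).
#'
#' @param config a [cohort_config()].
#' @return a list of class `cycif_cohort` with elements
#' \describe{
#'   \item{cells}{data frame, one row per cell: `cell_id`, `patient_id`,
#'     `core_id`, centroid `x`, `y` (pixels), nuclear `area` (px^2) and
#'     one nonnegative intensity column per marker (AU).}
#'   \item{clinical}{data frame, one row per patient: hormone-receptor
#'     status, stage, grade, age, treatment, `recurrence` (0/1 event
#'     flag) and `time_months`.}
#'   \item{truth}{list: `cell_labels` (1..k_true, aligned with `cells`),
#'     `patient_composition` (patients x k matrix), `cohort_weights`,
#'     `heterogeneity` (per-patient Euclidean divergence from the cohort
#'     weights; this is what the hazard couples to), `entropy` (Shannon
#'     entropy of the composition, descriptive), `event_time`, `event`.}
#' }
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 4,
#'   cells_per_core = list(mean = 50, dispersion = 0.1), seed = 7))
#' nrow(coh$clinical)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_("'config' must be created by cohort_config()")
  }
  set.seed(config$seed)
  np <- config$n_patients
  k <- config$k_true
  w <- config$global_weights
  patient_ids <- sprintf("P%03d", seq_len(np))

  comp <- rdirichlet(np, config$composition_alpha * w)
  rownames(comp) <- patient_ids
  heterogeneity <- sqrt(rowSums(sweep(comp, 2, w)^2))
  entropy <- apply(comp, 1, shannon_entropy)

  # cells
  cell_rows <- vector("list", np * config$cores_per_patient)
  labels_all <- vector("list", np * config$cores_per_patient)
  ii <- 0L
  disp <- config$cells_per_core$dispersion
  mu_cells <- config$cells_per_core$mean
  for (i in seq_len(np)) {
    for (ci in seq_len(config$cores_per_patient)) {
      ii <- ii + 1L
      n_cells <- if (disp > 0) {
        max(5L, rnbinom(1, mu = mu_cells, size = 1 / disp))
      } else {
        max(5L, round(mu_cells))
      }
      core_comp <- drop(rdirichlet(1, config$core_jitter * pmax(comp[i, ], 1e-8)))
      lab <- sample.int(k, n_cells, replace = TRUE, prob = core_comp)
      logint <- config$cluster_means[lab, , drop = FALSE] +
        matrix(rnorm(n_cells * length(config$markers)), n_cells) *
        config$cluster_sds[lab, , drop = FALSE]
      # uniform positions in a 0.6 mm core (~920 px diameter at 0.65 um/px)
      r <- 460 * sqrt(runif(n_cells))
      th <- runif(n_cells, 0, 2 * pi)
      df <- data.frame(
        patient_id = patient_ids[i],
        core_id = sprintf("%s_c%d", patient_ids[i], ci),
        x = round(460 + r * cos(th), 1),
        y = round(460 + r * sin(th), 1),
        area = pmax(10, round(rlnorm(n_cells, log(80), 0.3))),
        stringsAsFactors = FALSE
      )
      df[config$markers] <- exp(logint)
      cell_rows[[ii]] <- df
      labels_all[[ii]] <- lab
    }
  }
  cells <- do.call(rbind, cell_rows)
  cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
  rownames(cells) <- NULL
  cell_labels <- unlist(labels_all, use.names = FALSE)

  # recurrence: exponential with log-hazard linear in true heterogeneity;
  # an expected fraction censor_rate is censored uniformly before the event
  hz <- config$baseline_hazard * exp(config$hazard_coupling * heterogeneity)
  event_time <- rexp(np, rate = hz)
  censored <- runif(np) < config$censor_rate
  time_obs <- ifelse(censored, runif(np) * event_time, event_time)

  er <- sample(c("Positive", "Negative"), np, TRUE, prob = c(0.45, 0.55))
  pr <- ifelse(runif(np) < ifelse(er == "Positive", 0.7, 0.15),
               "Positive", "Negative")
  clinical <- data.frame(
    patient_id = patient_ids,
    er_status = er, pr_status = pr,
    stage = sample(c("I", "IIA", "IIB", "IIIA", "IIIB", "IV"), np, TRUE,
                   prob = c(0.20, 0.30, 0.20, 0.15, 0.10, 0.05)),
    grade = sample(c("I", "II", "III"), np, TRUE, prob = c(0.10, 0.40, 0.50)),
    age = pmin(90, pmax(25, round(rnorm(np, 55, 11)))),
    treatment = sample(c("chemo+trastuzumab", "chemo", "none"), np, TRUE,
                       prob = c(0.60, 0.25, 0.15)),
    recurrence = as.integer(!censored),
    time_months = round(time_obs, 2),
    stringsAsFactors = FALSE
  )

  truth <- list(
    cell_labels = cell_labels,
    patient_composition = comp,
    cohort_weights = w,
    heterogeneity = heterogeneity,
    entropy = entropy,
    event_time = event_time,
    event = as.integer(!censored)
  )
  structure(list(cells = cells, clinical = clinical, truth = truth,
                 config = config),
            class = "cycif_cohort")
}

#' @export
print.cycif_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CyCIF cohort: %d patients, %d cores, %d cells, %d markers, k_true = %d\n",
              x$config$n_patients,
              length(unique(x$cells$core_id)),
              nrow(x$cells), length(x$config$markers), x$config$k_true))
  invisible(x)
}
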