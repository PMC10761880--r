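#' Configure the analysis pipeline
#'
#' Collects the stage parameters for [run_pipeline()]: the marker panel
#' to gate and cluster on, gating method, number of phenotype clusters,
#' embedding settings, the t-SNE score normalization, the eligibility
#' threshold on pooled cells, and the per-stage seed.
#'
#' @param markers markers used for gating/clustering (default: every
#'   marker column except `Hoechst`); `NULL` defers to the cell table.
#' @param gate_method `"gmm2"` or `"local_min"`.
#' @param k number of phenotype clusters.
#' @param seed integer seed used for every stochastic stage.
#' @param n_init clustering initializations.
#' @param embed_subsample cells embedded by t-SNE.
#' @param perplexity t-SNE perplexity.
#' @param tsne_normalization `"rms"`, `"sum"` or `"mean"`.
#' @param min_cells pooled-cell eligibility threshold.
#' @param cv_marker marker for the per-patient CV column.
#' @param level `"patient"` (pool triplicate cores; default) or `"core"`.
#' @param tumor_marker,immune_marker lineage markers for cluster
#'   annotation.
#' @param out_dir optional output directory; when set, every stage writes
#'   its table there plus a JSON provenance manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(markers = NULL, gate_method = c("gmm2", "local_min"),
                            k = 7, seed = 1L, n_init = 3,
                            embed_subsample = 50000, perplexity = 30,
                            tsne_normalization = c("rms", "sum", "mean"),
                            min_cells = 500, cv_marker = "HER2",
                            level = c("patient", "core"),
                            tumor_marker = "Keratin", immune_marker = "CD45",
                            out_dir = NULL) {
  cfg <- list(
    markers = markers,
    gate_method = match.arg(gate_method),
    k = check_count(k, "k", min = 2),
    seed = check_count(seed, "seed", min = 0),
    n_init = check_count(n_init, "n_init", min = 1),
    embed_subsample = check_count(embed_subsample, "embed_subsample", min = 4),
    perplexity = check_number(perplexity, "perplexity", min = 2),
    tsne_normalization = match.arg(tsne_normalization),
    min_cells = check_count(min_cells, "min_cells", min = 1),
    cv_marker = cv_marker,
    level = match.arg(level),
    tumor_marker = tumor_marker, immune_marker = immune_marker,
    out_dir = out_dir
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages of the analysis in order on a per-cell intensity
#' table: \emph{gate} (binary calls and positivity ratios per marker,
#' including the per-patient Ki67 positivity used as a clinical
#' covariate), \emph{cluster} (Gaussian-mixture phenotypes, profiles and
#' lineage annotation), \emph{embed} (t-SNE), \emph{score} (per-patient
#' GMM and t-SNE heterogeneity scores and marker CV, after the
#' pooled-cell eligibility filter) and, when a clinical table with
#' follow-up is supplied, \emph{associate} (the univariate battery and
#' the two Cox models). A failing stage halts the pipeline with the stage
#' name in the error. Reruns with the same inputs and configuration are
#' bit-identical.
#'
#' @param cells cell table (see [read_cell_table()] for the schema).
#' @param clinical optional clinical table.
#' @param config a [pipeline_config()].
#' @return list of class `cycif_pipeline`: `gates`, `positivity`,
#'   `clinical` (augmented with `ki67`), `model`, `labels`, `profile`,
#'   `annotation`, `embedding`, `scores`, `associations`, `cox` and
#'   `manifest`.
#' @export
run_pipeline <- function(cells, clinical = NULL, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_("'config' must come from pipeline_config()")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  manifest <- list(stages = list(), seed = config$seed,
                   package_version = as.character(packageVersion("cycifith")))
  markers <- config$markers %||%
    setdiff(attr(cells, "markers") %||%
              setdiff(names(cells), c("cell_id", "patient_id", "core_id",
                                      "x", "y", "area")),
            "Hoechst")
  ids <- if (config$level == "patient") cells$patient_id else cells$core_id

  # gate
  gates <- stage("gate", lapply(setNames(markers, markers), function(m) {
    gate_marker(cells[[m]], method = config$gate_method, seed = config$seed,
                marker = m)
  }))
  positivity <- stage("gate", lapply(gates, function(g) {
    positivity_ratio(g$calls, cells$core_id)
  }))
  if ("Ki67" %in% names(gates)) {
    ki <- positivity_ratio(gates[["Ki67"]]$calls, cells$patient_id)
    ki67 <- data.frame(patient_id = ki$sample_id, ki67 = ki$ratio,
                       stringsAsFactors = FALSE)
    if (!is.null(clinical)) {
      clinical$ki67 <- NULL
      clinical <- merge(clinical, ki67, by = "patient_id", all.x = TRUE)
    }
  } else {
    ki67 <- NULL
  }
  manifest$stages$gate <- "completed"

  # cluster
  feats <- stage("cluster", build_features(cells, markers))
  cl <- stage("cluster", fit_clusters(feats, k = config$k, seed = config$seed,
                                      n_init = config$n_init))
  profile <- stage("cluster", profile_clusters(cells, cl$labels, markers,
                                               k = config$k))
  annotation <- if (all(c(config$tumor_marker, config$immune_marker) %in% markers)) {
    stage("cluster", annotate_clusters(
      profile,
      tumor_threshold = gates[[config$tumor_marker]]$threshold,
      immune_threshold = gates[[config$immune_marker]]$threshold))
  } else {
    rep("unannotated", config$k)
  }
  manifest$stages$cluster <- "completed"

  # embed
  embedding <- stage("embed", embed_cells(
    feats, subsample = config$embed_subsample, seed = config$seed,
    perplexity = min(config$perplexity,
                     floor((min(nrow(feats), config$embed_subsample) - 2) / 3))))
  manifest$stages$embed <- "completed"

  # score
  scores <- stage("score", score_heterogeneity(
    cells, cl$labels, embedding, k = config$k, min_cells = config$min_cells,
    normalization = config$tsne_normalization, cv_marker = config$cv_marker,
    ids = ids))
  manifest$stages$score <- if (nrow(scores) == 0L) {
    "completed (warning: no eligible patients)"
  } else {
    "completed"
  }

  # associate
  associations <- NULL
  cox <- list()
  if (!is.null(clinical) && nrow(scores) > 0L &&
      all(c("recurrence", "time_months") %in% names(clinical))) {
    associations <- stage("associate",
                          score_feature_tests(scores, clinical,
                                              score_col = "gmm_score"))
    for (sn in c("gmm", "tsne")) {
      cox[[sn]] <- tryCatch(fit_cox(scores, clinical, score_name = sn),
                            error = function(e) conditionMessage(e))
    }
    manifest$stages$associate <- "completed"
  } else {
    manifest$stages$associate <- "skipped (no clinical follow-up or no eligible patients)"
  }

  manifest$parameters <- unclass(config)[setdiff(names(config), "out_dir")]
  manifest$parameters$markers <- markers
  manifest$parameters$tsne_normalization <- attr(scores, "normalization") %||%
    config$tsne_normalization

  res <- structure(list(gates = gates, positivity = positivity,
                        clinical = clinical, ki67 = ki67,
                        model = cl$model, labels = cl$labels,
                        profile = profile, annotation = annotation,
                        embedding = embedding, scores = scores,
                        associations = associations, cox = cox,
                        manifest = manifest),
                   class = "cycif_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, cells, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, cells, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aug <- cells
  aug$cluster <- res$labels
  write_cell_table(aug, file.path(out_dir, "cells_labeled.csv"))
  write.csv(res$scores, file.path(out_dir, "heterogeneity_scores.csv"),
            row.names = FALSE)
  prof <- data.frame(cluster = seq_len(res$profile$k),
                     annotation = res$annotation,
                     fraction = res$profile$fractions,
                     res$profile$medians, check.names = FALSE)
  write.csv(prof, file.path(out_dir, "cluster_profile.csv"), row.names = FALSE)
  write.csv(res$embedding$coords, file.path(out_dir, "embedding.csv"),
            row.names = FALSE)
  if (!is.null(res$associations)) {
    write.csv(res$associations, file.path(out_dir, "associations.csv"),
              row.names = FALSE)
  }
  for (sn in names(res$cox)) {
    if (is.data.frame(res$cox[[sn]])) {
      write.csv(res$cox[[sn]], file.path(out_dir, sprintf("cox_%s.csv", sn)),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cycif_pipeline <- function(x, ...) {
  cat("CyCIF heterogeneity pipeline\n")
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  %-9s %s\n", s, x$manifest$stages[[s]]))
  }
  cat(sprintf("  %d scored patients; tsne normalization '%s'\n",
              nrow(x$scores), x$manifest$parameters$tsne_normalization))
  invisible(x)
}
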