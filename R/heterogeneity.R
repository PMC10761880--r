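#' Cluster-composition vectors per patient and for the cohort
#'
#' Tabulates per-cell cluster labels into per-patient composition vectors
#' (fractions over the patient's pooled cells, triplicate cores pooled)
#' and the cohort-wide composition over all cells. Patients carried as
#' factor levels but holding zero cells are dropped with a warning.
#'
#' @param labels integer per-cell cluster labels in `1..k`.
#' @param ids per-cell patient (or core) identifiers.
#' @param k number of clusters (default `max(labels)`).
#' @return object of class `composition_set`: `patients` (matrix,
#'   patients x k, rows sum to 1), `n_cells` (per patient), `cohort`
#'   (length-k fractions over all cells), `k`.
#' @export
compositions <- function(labels, ids, k = max(labels)) {
  if (length(labels) != length(ids)) {
    stop_("'labels' and 'ids' must have the same length")
  }
  k <- as.integer(k)
  if (any(labels < 1 | labels > k | labels != floor(labels))) {
    stop_("'labels' must be integers in 1..k")
  }
  f <- if (is.factor(ids)) ids else factor(ids)
  tab <- table(f, factor(labels, levels = seq_len(k)))
  n <- rowSums(tab)
  empty <- n == 0
  if (any(empty)) {
    warn_("excluding %d patient(s) with zero cells", sum(empty))
    tab <- tab[!empty, , drop = FALSE]
    n <- n[!empty]
  }
  pat <- sweep(unclass(tab), 1, n, "/")
  dimnames(pat) <- list(rownames(tab), paste0("cluster", seq_len(k)))
  cohort <- as.numeric(colSums(tab) / sum(tab))
  structure(list(patients = pat, n_cells = as.integer(n),
                 cohort = cohort, k = k),
            class = "composition_set")
}

#' @export
print.composition_set <- function(x, ...) {
  cat(sprintf("Cluster compositions: %d patients over k = %d clusters; cohort = (%s)\n",
              nrow(x$patients), x$k,
              paste(sprintf("%.3f", x$cohort), collapse = ", ")))
  invisible(x)
}

#' GMM composition heterogeneity score
#'
#' The cluster-composition heterogeneity statistic:
#' \deqn{\mathrm{score} = 1 - \lVert q - p \rVert_2,}
#' one minus the Euclidean distance between the cohort's cluster
#' composition \eqn{q} and a patient's composition \eqn{p}. A patient
#' whose composition equals the cohort's scores exactly 1; the lower the
#' score, the more the patient deviates from the cohort-typical mixture,
#' i.e. the more heterogeneous. The score is not clamped: its minimum
#' attainable value is \eqn{1 - \sqrt{2}}.
#'
#' @param cohort cohort composition vector (fractions summing to 1), or a
#'   [compositions()] result, in which case `patient` may be omitted and
#'   every patient in it is scored.
#' @param patient a patient composition vector, or a matrix with one
#'   composition per row.
#' @return a numeric score per patient; for a `composition_set` input, a
#'   data frame `patient_id`, `n_cells`, `gmm_score`.
#' @examples
#' gmm_score(rep(0.25, 4), c(0.3, 0.2, 0.2, 0.3))  # 0.9
#' gmm_score(rep(0.25, 4), c(0.1, 0.3, 0, 0.6))    # 1 - sqrt(0.21)
#' @export
gmm_score <- function(cohort, patient) {
  if (inherits(cohort, "composition_set")) {
    cs <- cohort
    p <- if (missing(patient)) cs$patients else patient
    s <- gmm_score(cs$cohort, p)
    if (missing(patient)) {
      return(data.frame(patient_id = rownames(cs$patients),
                        n_cells = cs$n_cells, gmm_score = as.numeric(s),
                        stringsAsFactors = FALSE))
    }
    return(s)
  }
  if (!is_composition(cohort)) {
    stop_("'cohort' must be nonnegative fractions summing to 1")
  }
  p <- if (is.matrix(patient)) patient else matrix(patient, nrow = 1)
  if (ncol(p) != length(cohort)) {
    stop_("composition length mismatch: cohort has %d clusters, patient %d",
          length(cohort), ncol(p))
  }
  ok <- apply(p, 1, is_composition)
  if (!all(ok)) stop_("'patient' rows must be nonnegative fractions summing to 1")
  s <- 1 - sqrt(rowSums(sweep(p, 2, cohort)^2))
  if (!is.matrix(patient)) s <- unname(s[1]) else names(s) <- rownames(patient)
  s
}

#' t-SNE dispersion heterogeneity score
#'
#' Dispersion of a patient's embedded cells around the cohort-mean
#' embedding coordinates. For a patient's cells \eqn{C} with coordinates
#' \eqn{(t1_c, t2_c)} and cohort means \eqn{(m_1, m_2)} over all embedded
#' cells,
#' \deqn{S = \sum_{c \in C} (t1_c - m_1)^2 + \sum_{c \in C} (t2_c - m_2)^2}
#' and the score is \eqn{\sqrt{S}} (`"sum"`, the literal summed form,
#' which grows with cell count), \eqn{\sqrt{S}/|C|} (`"mean"`) or
#' \eqn{\sqrt{S/|C|}} (`"rms"`, the default: the root-mean-square
#' deviation, invariant to cell count). Higher scores mean a wider spread
#' of the patient's cells over phenotype space, i.e. higher intratumor
#' heterogeneity.
#'
#' @param embedding a [embed_cells()] result.
#' @param ids per-cell patient identifiers, either for all `n_total`
#'   cells the feature matrix held (subset internally to the embedded
#'   ones) or one per embedded cell.
#' @param normalization `"rms"` (default), `"sum"` or `"mean"`.
#' @return data frame `patient_id`, `n_cells` (embedded cells used),
#'   `tsne_score`, with the normalization recorded as an attribute.
#'   Patients with no embedded cells are dropped with a warning.
#' @export
tsne_score <- function(embedding, ids, normalization = c("rms", "sum", "mean")) {
  normalization <- match.arg(normalization)
  if (!inherits(embedding, "cell_embedding")) {
    stop_("'embedding' must come from embed_cells()")
  }
  co <- embedding$coords
  if (length(ids) == embedding$n_total) {
    ids_emb <- ids[co$row]
  } else if (length(ids) == nrow(co)) {
    ids_emb <- ids
  } else {
    stop_("'ids' must cover all %d cells or the %d embedded cells",
          embedding$n_total, nrow(co))
  }
  f <- factor(ids_emb)
  all_ids <- if (length(ids) == embedding$n_total) unique(ids) else levels(f)
  lost <- setdiff(all_ids, levels(droplevels(f)))
  if (length(lost)) {
    warn_("excluding %d patient(s) with no embedded cells", length(lost))
  }
  d2 <- (co$tsne1 - embedding$mean1)^2 + (co$tsne2 - embedding$mean2)^2
  S <- vapply(split(d2, f), sum, numeric(1))
  n <- tabulate(f, nbins = nlevels(f))
  score <- switch(normalization,
                  sum = sqrt(S),
                  mean = sqrt(S) / n,
                  rms = sqrt(S / n))
  out <- data.frame(patient_id = levels(f), n_cells = n,
                    tsne_score = as.numeric(score),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "normalization") <- normalization
  out
}

#' Per-patient coefficient of variation of a marker
#'
#' CV (sample SD divided by mean) of the raw, untransformed intensities
#' of one marker over each patient's pooled cells - a unit-free,
#' scale-invariant dispersion measure of expression heterogeneity
#' (conventionally applied to HER2).
#'
#' @param cells cell table with the marker column.
#' @param marker marker name.
#' @param ids per-cell patient identifiers (default
#'   `cells$patient_id`).
#' @return data frame `patient_id`, `n_cells`, `cv` (`NA` with a warning
#'   where undefined: fewer than 2 cells or zero mean).
#' @export
marker_cv <- function(cells, marker, ids = cells$patient_id) {
  if (!marker %in% names(cells)) {
    stop_("unknown marker '%s': not a column of the cell table", marker)
  }
  x <- cells[[marker]]
  f <- factor(ids)
  n <- tabulate(f, nbins = nlevels(f))
  mu <- vapply(split(x, f), mean, numeric(1))
  sdv <- vapply(split(x, f), sd, numeric(1))
  cv <- ifelse(n >= 2 & mu > 0, sdv / mu, NA_real_)
  if (anyNA(cv)) {
    warn_("CV undefined for %d patient(s) (zero mean or < 2 cells)", sum(is.na(cv)))
  }
  data.frame(patient_id = levels(f), n_cells = n, cv = as.numeric(cv),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Eligibility filter on pooled cell count
#'
#' Retains patients whose cells pooled across their (triplicate) cores
#' number at least `min_cells`; the boundary is inclusive ("at least
#' 500" keeps a patient with exactly 500 cells).
#'
#' @param cells cell table with a `patient_id` column.
#' @param min_cells minimum pooled cell count (default 500).
#' @return list with `retained` and `excluded` patient-ID vectors and
#'   `counts`, a data frame (`patient_id`, `n_cells`, `eligible`).
#' @export
filter_patients <- function(cells, min_cells = 500) {
  if (!"patient_id" %in% names(cells)) {
    stop_("cell table needs a 'patient_id' column")
  }
  f <- factor(cells$patient_id)
  n <- tabulate(f, nbins = nlevels(f))
  eligible <- n >= min_cells
  list(retained = levels(f)[eligible],
       excluded = levels(f)[!eligible],
       counts = data.frame(patient_id = levels(f), n_cells = n,
                           eligible = eligible,
                           stringsAsFactors = FALSE, row.names = NULL))
}

#' Per-patient heterogeneity score table
#'
#' Convenience wrapper assembling the per-patient ITH statistics from a
#' labeled, embedded cell table: the composition [gmm_score()], the
#' [tsne_score()] dispersion, and the [marker_cv()] of a reference
#' marker, restricted to patients passing the pooled-cell-count filter.
#'
#' @param cells cell table (`patient_id` plus marker columns).
#' @param labels per-cell cluster labels.
#' @param embedding a [embed_cells()] result on the same cell order.
#' @param k number of clusters.
#' @param min_cells eligibility threshold, see [filter_patients()].
#' @param normalization t-SNE score normalization.
#' @param cv_marker marker for the CV column (skipped if absent).
#' @param ids grouping identifiers (default patient; pass
#'   `cells$core_id` for per-core scores).
#' @return data frame `patient_id`, `n_cells`, `gmm_score`,
#'   `tsne_score`, `cv`; cohort composition and settings as attributes.
#' @export
score_heterogeneity <- function(cells, labels, embedding, k = max(labels),
                                min_cells = 500, normalization = "rms",
                                cv_marker = "HER2", ids = cells$patient_id) {
  flt <- filter_patients(data.frame(patient_id = ids), min_cells = min_cells)
  keep <- ids %in% flt$retained
  if (!any(keep)) {
    warn_("no patient reaches %d pooled cells; returning empty score table", min_cells)
    out <- data.frame(patient_id = character(0), n_cells = integer(0),
                      gmm_score = numeric(0), tsne_score = numeric(0),
                      cv = numeric(0), stringsAsFactors = FALSE)
    attr(out, "eligibility") <- flt$counts
    return(out)
  }
  # cohort composition over all cells; per-patient vectors over eligible ones
  cohort <- compositions(labels, rep("cohort", length(labels)), k = k)$cohort
  cs <- compositions(labels[keep], ids[keep], k = k)
  g <- data.frame(patient_id = rownames(cs$patients),
                  n_cells = cs$n_cells,
                  gmm_score = as.numeric(gmm_score(cohort, cs$patients)),
                  stringsAsFactors = FALSE)
  ts <- tsne_score(embedding, ids, normalization = normalization)
  out <- merge(g, ts[c("patient_id", "tsne_score")], by = "patient_id",
               all.x = TRUE, sort = TRUE)
  if (!is.null(cv_marker) && cv_marker %in% names(cells)) {
    cvt <- marker_cv(cells[keep, , drop = FALSE], cv_marker, ids = ids[keep])
    out <- merge(out, cvt[c("patient_id", "cv")], by = "patient_id",
                 all.x = TRUE, sort = TRUE)
  } else {
    out$cv <- NA_real_
  }
  attr(out, "cohort_composition") <- cohort
  attr(out, "normalization") <- normalization
  attr(out, "min_cells") <- min_cells
  attr(out, "eligibility") <- flt$counts
  out
}
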