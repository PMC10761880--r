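#' Combine sparse clinical stage and grade categories
#'
#' Standard category combining used before association testing: clinical
#' stages III (any substage) and IV are merged into `"III-IV"`, substages
#' of I and II are collapsed to `"I"` and `"II"`, and tumor grades I and
#' II are merged into `"I-II"` (grade III stays `"III"`). The mapping is
#' idempotent: already-combined tables pass through unchanged.
#'
#' @param clinical clinical table; `stage` and/or `grade` columns are
#'   transformed when present, everything else is untouched.
#' @return the clinical table with combined categories.
#' @export
combine_categories <- function(clinical) {
  if ("stage" %in% names(clinical)) {
    clinical$stage <- vapply(as.character(clinical$stage), combine_stage, character(1),
                             USE.NAMES = FALSE)
  }
  if ("grade" %in% names(clinical)) {
    clinical$grade <- vapply(as.character(clinical$grade), combine_grade, character(1),
                             USE.NAMES = FALSE)
  }
  clinical
}

combine_stage <- function(v) {
  s <- toupper(trimws(v))
  if (s %in% c("I", "II", "III-IV")) return(s)      # already combined
  if (grepl("^IV", s) || grepl("^III", s)) return("III-IV")
  if (grepl("^II", s)) return("II")
  if (grepl("^I", s)) return("I")
  stop_("unknown clinical stage category: '%s'", v)
}

combine_grade <- function(v) {
  g <- toupper(trimws(v))
  if (g %in% c("I-II", "III")) return(g)            # already combined
  if (grepl("^III", g) || grepl("^3", g) || grepl("HIGH", g)) return("III")
  if (grepl("^II", g) || grepl("^I", g) || grepl("^[12]", g) ||
      grepl("LOW", g) || grepl("INTERMEDIATE", g)) return("I-II")
  stop_("unknown tumor grade category: '%s'", v)
}

#' Univariate association battery for a heterogeneity score
#'
#' Tests a per-patient heterogeneity score against clinical features with
#' the rank-based battery: two-category features (ER status, PR status,
#' combined tumor grade) use the two-sided Wilcoxon rank-sum test,
#' features with three or more categories (combined clinical stage) the
#' Kruskal-Wallis test, and continuous features (age, Ki67 positivity)
#' the Spearman correlation test. Comparisons where any group holds fewer
#' than `min_group` patients are skipped with the reason recorded.
#'
#' @param scores data frame with `patient_id` and the score column.
#' @param clinical clinical table (categories combined internally via
#'   [combine_categories()]).
#' @param score_col name of the score column (default `"gmm_score"`).
#' @param min_group minimum patients per compared group (default 3).
#' @return data frame: `feature`, `test`, `statistic`, `p_value`, `n`,
#'   `note`.
#' @export
score_feature_tests <- function(scores, clinical, score_col = "gmm_score",
                                min_group = 3) {
  if (!score_col %in% names(scores)) stop_("'%s' not found in scores", score_col)
  d <- merge(scores[c("patient_id", score_col)], combine_categories(clinical),
             by = "patient_id")
  s <- d[[score_col]]
  rows <- list()
  add <- function(feature, test, statistic, p, n, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, test = test, statistic = statistic, p_value = p,
      n = n, note = note, stringsAsFactors = FALSE)
  }
  two_cat <- function(col, feature) {
    if (!col %in% names(d)) return(invisible())
    g <- factor(d[[col]])
    sizes <- table(g)
    if (nlevels(droplevels(g)) != 2L || any(sizes < min_group)) {
      add(feature, "wilcoxon", NA_real_, NA_real_, sum(sizes),
          sprintf("skipped: needs 2 groups of >= %d patients", min_group))
      return(invisible())
    }
    w <- suppressWarnings(wilcox.test(s ~ g))
    add(feature, "wilcoxon", unname(w$statistic), w$p.value, length(s))
  }
  two_cat("er_status", "ER status")
  two_cat("pr_status", "PR status")
  two_cat("grade", "tumor grade")
  if ("stage" %in% names(d)) {
    g <- droplevels(factor(d$stage))
    if (nlevels(g) >= 2L && all(table(g) >= min_group)) {
      kw <- kruskal.test(s, g)
      add("clinical stage", "kruskal-wallis", unname(kw$statistic), kw$p.value,
          length(s))
    } else {
      add("clinical stage", "kruskal-wallis", NA_real_, NA_real_, length(s),
          sprintf("skipped: needs groups of >= %d patients", min_group))
    }
  }
  spearman <- function(col, feature) {
    if (!col %in% names(d)) return(invisible())
    ok <- is.finite(d[[col]]) & is.finite(s)
    if (sum(ok) < min_group) {
      add(feature, "spearman", NA_real_, NA_real_, sum(ok), "skipped: too few patients")
      return(invisible())
    }
    ct <- suppressWarnings(cor.test(s[ok], d[[col]][ok], method = "spearman",
                                    exact = FALSE))
    add(feature, "spearman", unname(ct$estimate), ct$p.value, sum(ok))
  }
  spearman("age", "age")
  spearman("ki67", "Ki67 positivity")
  do.call(rbind, rows)
}

#' Cox proportional-hazards model for recurrence
#'
#' Fits recurrence (time-to-event with event indicator) on one
#' heterogeneity score plus the clinical covariates: ER status, PR
#' status, combined clinical stage (II and III-IV each against stage I),
#' age, Ki67 positivity and high tumor grade (III against I-II). Ties are
#' handled by the Efron approximation. Constant covariates are dropped
#' with a note; suspected monotone-likelihood separation (a coefficient
#' walking to infinity) is flagged.
#'
#' @param scores data frame with `patient_id` and `gmm_score` and/or
#'   `tsne_score`.
#' @param clinical clinical table with `recurrence` (0/1) and
#'   `time_months`; categories combined internally.
#' @param score_name `"gmm"` or `"tsne"`: which score enters the model.
#' @param min_events minimum number of events required (default 10).
#' @param covariates clinical covariates to include when available.
#' @return object of class `cox_report`: data frame `term`, `log_hr`,
#'   `hr`, `lower`, `upper` (95% CI), `p`, with attributes `n`, `events`,
#'   `notes` and the fitted `survival::coxph` object as `fit`.
#' @export
fit_cox <- function(scores, clinical, score_name = c("gmm", "tsne"),
                    min_events = 10,
                    covariates = c("er_status", "pr_status", "stage",
                                   "age", "ki67", "grade")) {
  score_name <- match.arg(score_name)
  score_col <- paste0(score_name, "_score")
  if (!score_col %in% names(scores)) stop_("'%s' not found in scores", score_col)
  d <- merge(scores[c("patient_id", score_col)], combine_categories(clinical),
             by = "patient_id")
  if (!all(c("recurrence", "time_months") %in% names(d))) {
    stop_("clinical table needs 'recurrence' and 'time_months'")
  }
  d <- d[is.finite(d$time_months) & d$time_months >= 0 &
           d$recurrence %in% c(0, 1) & is.finite(d[[score_col]]), ]
  events <- sum(d$recurrence)
  if (events < min_events) {
    stop_("insufficient events for a Cox fit: %d < %d", events, min_events)
  }
  notes <- character(0)
  d$score <- d[[score_col]]
  terms <- "score"
  for (cv in covariates) {
    if (!cv %in% names(d)) next
    v <- d[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      notes <- c(notes, sprintf("dropped constant covariate '%s'", cv))
      next
    }
    if (cv %in% c("er_status", "pr_status", "grade")) d[[cv]] <- factor(v)
    if (cv == "stage") d[[cv]] <- factor(v, levels = c("I", "II", "III-IV"))
    terms <- c(terms, cv)
  }
  fml <- stats::as.formula(paste("survival::Surv(time_months, recurrence) ~",
                                 paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = d, ties = "efron"),
             error = function(e) {
               mm <- stats::model.matrix(stats::as.formula(
                 paste("~", paste(terms, collapse = "+"))), data = d)
               stop_("Cox fit failed: %s (model-matrix condition number %.3g)",
                     conditionMessage(e), kappa(mm))
             }),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  if (any(abs(co[, "coef"]) > 15)) {
    notes <- c(notes, "possible separation / monotone likelihood: |log HR| > 15; consider a penalized fit")
  }
  out <- data.frame(term = rownames(co),
                    log_hr = co[, "coef"],
                    hr = ci[, "exp(coef)"],
                    lower = ci[, "lower .95"],
                    upper = ci[, "upper .95"],
                    p = co[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("cox_report", "data.frame"),
            model = sprintf("Model (%s score)", score_name),
            n = nrow(d), events = events, notes = notes, fit = fit)
}

#' @export
print.cox_report <- function(x, ...) {
  cat(sprintf("%s: n = %d, events = %d\n", attr(x, "model"), attr(x, "n"),
              attr(x, "events")))
  print.data.frame(cbind(x["term"], round(x[-1], 4)))
  for (n in attr(x, "notes")) cat("  note:", n, "\n")
  invisible(x)
}
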