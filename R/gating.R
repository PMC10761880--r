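#' Gate a marker into positive/negative calls
#'
#' Derives a binary positive/negative threshold for one marker from its
#' per-cell intensity distribution. Intensities are log-transformed as
#' `log(x + 1)` internally. Two methods are provided:
#' \describe{
#'   \item{`gmm2`}{a 2-component univariate Gaussian mixture is fitted to
#'     the log intensities; the threshold is the equal-posterior crossing
#'     between the two component means (the point where membership in the
#'     negative and positive components is equally likely).}
#'   \item{`local_min`}{the threshold is the deepest local minimum of a
#'     Gaussian kernel-density estimate (Silverman bandwidth) between the
#'     two outermost modes; if the density is unimodal the function falls
#'     back to `gmm2` with a warning.}
#' }
#' A cell is called positive when its intensity exceeds the threshold
#' (`log1p(x) > threshold`).
#'
#' @param intensities nonnegative per-cell intensities (AU).
#' @param method `"gmm2"` (default) or `"local_min"`.
#' @param seed RNG seed (the fits are deterministic; the seed is recorded
#'   for provenance).
#' @param marker optional marker name recorded in the result.
#' @return object of class `gate_result`: list with `marker`, `method`
#'   (the method actually used), `threshold` (log AU, on the `log1p`
#'   scale), `calls` (logical per cell), `positivity_ratio`, `means`
#'   (fitted component means for `gmm2`), and `fallback` (TRUE if
#'   `local_min` fell back to `gmm2`).
#' @examples
#' x <- c(rlnorm(300, 1, 0.3), rlnorm(300, 4, 0.3))
#' g <- gate_marker(x, seed = 1)
#' g$positivity_ratio
#' @export
gate_marker <- function(intensities, method = c("gmm2", "local_min"),
                        seed = 1L, marker = NULL) {
  method <- match.arg(method)
  x <- intensities
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_("'intensities' must be finite and nonnegative")
  }
  lx <- log1p(x)
  if (stats::var(lx) == 0) {
    stop_("degenerate input: intensities have no variance, gate undefined")
  }
  set.seed(seed)
  fallback <- FALSE
  if (method == "local_min") {
    lm <- local_min_threshold(lx)
    if (is.null(lm)) {
      warn_("density of '%s' is unimodal; falling back to gmm2 gating",
            marker %||% "marker")
      method <- "gmm2"
      fallback <- TRUE
    } else {
      threshold <- lm
      means <- NULL
    }
  }
  if (method == "gmm2") {
    if (length(x) < 10L) {
      stop_("insufficient data: gmm2 gating needs at least 10 values, got %d",
            length(x))
    }
    fit <- gmm2_fit(lx)
    threshold <- gmm2_threshold(fit)
    means <- fit$mean
  }
  calls <- lx > threshold
  structure(list(
    marker = marker, method = method, threshold = threshold,
    calls = calls, positivity_ratio = mean(calls),
    means = means, fallback = fallback, seed = seed
  ), class = "gate_result")
}

# 2-component univariate Gaussian mixture on log intensities via mclust
# (unequal variances; equal-variance, then two-means fallbacks for
# near-degenerate data such as effectively two-valued distributions)
gmm2_fit <- function(lx) {
  fit <- tryCatch(mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(mclust::Mclust(lx, G = 2, modelNames = "E", verbose = FALSE),
                    error = function(e) NULL)
  }
  if (is.null(fit)) return(two_means_fit(lx))
  p <- fit$parameters
  sds <- sqrt(if (length(p$variance$sigmasq) == 1L) {
    rep(p$variance$sigmasq, 2)
  } else {
    p$variance$sigmasq
  })
  o <- order(p$mean)
  list(mean = as.numeric(p$mean[o]), sd = sds[o], weight = p$pro[o])
}

# deterministic 1-D two-means split (EM degenerate, e.g. two-valued data):
# split at the midpoint-optimal cut found by sweeping sorted gaps
two_means_fit <- function(lx) {
  sx <- sort(lx)
  n <- length(sx)
  cs <- cumsum(sx); cs2 <- cumsum(sx^2)
  i <- seq_len(n - 1)
  wss <- (cs2[i] - cs[i]^2 / i) +
    ((cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i))
  cut <- which.min(wss)
  lo <- sx[1:cut]; hi <- sx[(cut + 1):n]
  s <- c(max(sd(lo), 1e-6), max(sd(hi), 1e-6))
  if (is.na(s[1])) s[1] <- 1e-6
  if (is.na(s[2])) s[2] <- 1e-6
  list(mean = c(mean(lo), mean(hi)), sd = s, weight = c(cut, n - cut) / n)
}

# equal-posterior crossing between the two component means
gmm2_threshold <- function(fit) {
  g <- function(t) {
    log(fit$weight[1]) + dnorm(t, fit$mean[1], fit$sd[1], log = TRUE) -
      log(fit$weight[2]) - dnorm(t, fit$mean[2], fit$sd[2], log = TRUE)
  }
  lo <- fit$mean[1]; hi <- fit$mean[2]
  if (hi - lo < 1e-12) return((lo + hi) / 2)
  glo <- g(lo); ghi <- g(hi)
  if (is.finite(glo) && is.finite(ghi) && glo > 0 && ghi < 0) {
    uniroot(g, c(lo, hi))$root
  } else {
    # posteriors never cross between the means (extreme weights); take the
    # point of closest approach, which still lies strictly between them
    optimize(function(t) abs(g(t)), c(lo, hi))$minimum
  }
}

# deepest KDE local minimum between the two outermost modes, or NULL if
# the density is unimodal
local_min_threshold <- function(lx) {
  d <- density(lx, bw = "nrd0")
  s <- diff(sign(diff(d$y)))
  maxima <- which(s == -2) + 1L
  maxima <- maxima[d$y[maxima] > 0.01 * max(d$y)]
  if (length(maxima) < 2L) return(NULL)
  lo <- min(maxima); hi <- max(maxima)
  minima <- which(s == 2) + 1L
  minima <- minima[minima > lo & minima < hi]
  if (length(minima) == 0L) return(NULL)
  d$x[minima[which.min(d$y[minima])]]
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("Gate%s [%s%s]: threshold = %.3f (log AU), positivity = %.3f (n = %d)\n",
              if (is.null(x$marker)) "" else paste0(" for ", x$marker),
              x$method, if (isTRUE(x$fallback)) ", fallback" else "",
              x$threshold, x$positivity_ratio, length(x$calls)))
  invisible(x)
}

#' Per-sample positivity ratios
#'
#' Fraction of positive cells per sample (core or patient): positives
#' divided by total cells. Samples carried as factor levels but holding
#' zero cells are dropped with a warning.
#'
#' @param calls logical per-cell positive calls.
#' @param group_ids per-cell sample identifiers (same length).
#' @return data frame: `sample_id`, `n_cells`, `n_positive`, `ratio`.
#' @export
positivity_ratio <- function(calls, group_ids) {
  if (length(calls) != length(group_ids)) {
    stop_("'calls' and 'group_ids' must have the same length")
  }
  f <- if (is.factor(group_ids)) group_ids else factor(group_ids)
  n <- tabulate(f, nbins = nlevels(f))
  pos <- vapply(split(as.logical(calls), f), sum, numeric(1))
  empty <- n == 0
  if (any(empty)) {
    warn_("excluding %d sample(s) with zero cells", sum(empty))
  }
  data.frame(sample_id = levels(f)[!empty],
             n_cells = n[!empty],
             n_positive = as.integer(pos[!empty]),
             ratio = as.numeric(pos[!empty] / n[!empty]),
             stringsAsFactors = FALSE, row.names = NULL)
}
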