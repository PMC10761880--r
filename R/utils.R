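# internal helpers shared across modules

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop_("invalid configuration: '%s' must be an integer >= %d", field, min)
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_("invalid configuration: '%s' must be a number in [%s, %s]",
          field, format(min), format(max))
  }
  as.numeric(x)
}

# Dirichlet sampler via normalized gamma draws; no sampler for this in the
# imported stack.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, ncol = k, byrow = TRUE)
  s <- rowSums(x)
  # degenerate draws (all-zero row, possible for tiny alpha) fall back to the
  # normalized concentration itself
  bad <- s <= 0
  if (any(bad)) x[bad, ] <- matrix(alpha / sum(alpha), sum(bad), k, byrow = TRUE)
  x / pmax(rowSums(x), .Machine$double.xmin)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

is_composition <- function(p, tol = 1e-6) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) &&
    abs(sum(p) - 1) <= tol
}
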