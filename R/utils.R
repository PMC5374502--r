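## Internal helpers shared across modules.

# classed error so callers can catch specific failure modes
stopc <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(class, "scmge_error", "error")))
}

warnc <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# row variance without matrixStats; x a base matrix
.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# population (divide-by-n) row sd, the convention used for heatmap Z-scores
.rowSdPop <- function(x) {
  m <- rowMeans(x)
  sqrt(rowMeans((x - m)^2))
}

.isWholeNumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}

# deterministic, locale-independent ordering of character ids
.orderIds <- function(...) order(..., method = "radix")

# invert the trigamma function by Newton iteration; used by the
# empirical-Bayes variance squeeze.  Monotone decreasing on (0, Inf).
.trigammaInverse <- function(y) {
  if (length(y) == 0L) return(numeric(0))
  out <- y
  for (i in seq_along(y)) {
    yi <- y[i]
    if (!is.finite(yi)) { out[i] <- if (yi > 0) 0 else Inf; next }
    if (yi <= 0) { out[i] <- Inf; next }
    if (yi > 1e7) { out[i] <- 1 / sqrt(yi); next }
    if (yi < 1e-6) { out[i] <- 1 / yi; next }
    x <- 0.5 + 1 / yi
    for (iter in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    out[i] <- x
  }
  out
}
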