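# Internal helpers: structured error conditions, permutations, seed streams.

SUBGROUP_LEVELS <- c("benign", "malignant", "LCS")

## Structured conditions so callers can dispatch on failure modes
## (rare instances, unseen levels, unusable trials, ...).
.opncbStop <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(subclass, "opncb_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

.assertThat <- function(ok, subclass, message) {
  if (!isTRUE(ok)) .opncbStop(subclass, message, call = sys.call(-1))
  invisible(TRUE)
}

## All permutations of a character vector, emitted in lexicographic order
## of the (name-sorted) elements; the deterministic tie-break order for
## permutation search.
.permutations <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

## Derive independent child seeds from one root seed (kept below 2^31).
.childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

## Mean and 95% t-interval across trials.
.tSummary <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  m <- mean(v)
  if (n < 2L) return(c(mean = m, lo = m, hi = m, n = n))
  half <- stats::qt(0.975, n - 1L) * stats::sd(v) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}

.rowVars <- function(m) {
  if (is.null(dim(m))) return(stats::var(m))
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
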