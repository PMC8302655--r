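#' @useDynLib bmsr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rcauchy sd var cor cor.test quantile median
#'   pnorm qnorm integrate complete.cases wilcox.test setNames
#' @importFrom utils read.table write.table head modifyList
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_input("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_positive <- function(x, name, strict = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(if (strict) x <= 0 else x < 0))
    stop_input("`%s` must be %s", name, if (strict) "positive" else "non-negative")
  x
}

# Pearson correlation with its two-sided (or one-sided) t-test, returning a
# plain list; NA-safe on pairwise-complete input.
cor_with_p <- function(x, y, alternative = "two.sided") {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) stop_input("need >= 3 complete pairs, got %d", n)
  ct <- cor.test(x[ok], y[ok], method = "pearson", alternative = alternative)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
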