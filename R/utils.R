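#' @useDynLib burstdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft quantile sd var rnorm runif t.test wilcox.test
#'   cor.test pbinom qt pt integrate lowess filter arima.sim median approx
#'   uniroot optimize setNames complete.cases dnorm pnorm qnorm
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derived realization seeds: documented counter scheme, kept below 2^31
# (double arithmetic: exact well past any counter used here).
derive_seed <- function(seed, i)
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# inverse error function via the normal quantile
erfinv <- function(y) qnorm((y + 1) / 2) / sqrt(2)
erfc <- function(x) 2 * pnorm(-x * sqrt(2))

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
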