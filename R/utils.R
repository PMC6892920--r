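# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed.
#' @noRd
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Pearson correlation with a t-transform p-value
#'
#' Computes the Pearson coefficient between two numeric vectors and the
#' two-sided p-value from \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2}
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3 paired samples).
#' @return A list with elements `r` and `p`.
#' @examples
#' pearson_test(1:10, (1:10) + rnorm(10))
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation is undefined")
  }
  r <- stats::cor(x, y)
  list(r = r, p = pearson_p(r, length(x)))
}

# Two-sided p for a vector of Pearson r at sample size n (t transform).
#' @noRd
pearson_p <- function(r, n) {
  r2 <- pmin(r * r, 1 - 1e-16)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1 - 1e-15] <- 0
  pmin(p, 1)
}

# Row-wise correlation between paired rows of two matrices (same dim).
#' @noRd
rowwise_cor <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  num / den
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
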