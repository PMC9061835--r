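#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for an independent random stream
#'
#' One global seed drives a hierarchical split, one stream per sub-generator,
#' so adding a generator does not perturb the draws of the others. The result
#' is always a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param stream Integer stream index (>= 0).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 1000003 + as.numeric(stream) * 7919) %% 2147483645 + 1)
}

#' Spearman association with average-rank ties and a t-approximation p-value
#'
#' @param x,y Numeric vectors of equal length; pairwise-complete observations
#'   are used.
#' @return A list with `rho`, two-sided `p`, and the number of complete pairs
#'   `n`. A constant vector yields `rho = NA`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x[ok]), rank(y[ok]))
  list(rho = rho, p = cor_t_pvalue(rho, n), n = n)
}

#' Two-sided p-value for a correlation via the t distribution
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations.
#' @return Two-sided p-value.
#' @export
cor_t_pvalue <- function(r, n) {
  if (!is.finite(r) || n < 3L) return(NA_real_)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return The adjusted Rand index; 1 for identical partitions, ~0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# internal: stop() with a stage prefix used by run_pipeline error contracts
stage_stop <- function(stage, ...) {
  stop(sprintf("stage '%s': %s", stage, paste0(...)), call. = FALSE)
}
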