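# Module overlap testing (2x2 chi-square without continuity correction,
# optional Fisher exact), cross-cohort module matching, a reduced module
# preservation statistic, Mann-Whitney group comparison, and module
# eigengene vs covariate association.

#' 2x2 chi-square (1 df, no continuity correction) from cell counts
#'
#' `chisq = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. The continuity-corrected
#' variant is deliberately not used: the uncorrected statistic is the one that
#' reproduces published worked examples for large sparse tables. When any
#' margin is zero the statistic is undefined and `NA` is returned.
#'
#' @param a,b,c,d Nonnegative cell counts (a = overlap, d = remainder).
#' @return A list with `chisq`, `p` (upper-tail, 1 df), `odds_ratio`, and the
#'   `counts`.
#' @export
contingency_chisq <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(list(chisq = NA_real_, p = NA_real_, odds_ratio = NA_real_,
                counts = c(a = a, b = b, c = c, d = d)))
  }
  chisq <- n * (a * d - b * c)^2 / prod(margins)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       odds_ratio = (a * d) / max(b * c, .Machine$double.xmin),
       counts = c(a = a, b = b, c = c, d = d))
}

#' Overlap test between two genesets in a common universe
#'
#' Builds the 2x2 table `a = |A and B|`, `b = |A \ B|`, `c = |B \ A|`,
#' `d = rest` and applies the uncorrected chi-square plus a Fisher exact test.
#' If any margin is zero the chi-square is dropped (Fisher only) with a
#' warning.
#'
#' @param set_a,set_b Character vectors of ids.
#' @param universe Universe size (count) or the full id vector.
#' @return A list of class `overlap_test`: counts, `chisq`, `p_chisq`,
#'   `odds_ratio`, `p_fisher`, `overlap` (ids in both sets).
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(universe) == 1L && is.numeric(universe)) {
    n <- as.integer(universe)
  } else {
    universe <- unique(universe)
    n <- length(universe)
    set_a <- intersect(set_a, universe)
    set_b <- intersect(set_b, universe)
  }
  if (length(set_a) > n || length(set_b) > n) stop("set larger than the universe")
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c <- length(set_b) - a
  d <- n - a - b - c
  if (d < 0) stop("universe smaller than the union of the sets")
  cs <- contingency_chisq(a, b, c, d)
  if (is.na(cs$chisq)) warning("zero margin: chi-square undefined, Fisher exact only")
  fisher <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE))
  structure(list(counts = cs$counts, chisq = cs$chisq, p_chisq = cs$p,
                 odds_ratio = cs$odds_ratio, p_fisher = fisher$p.value,
                 overlap = intersect(set_a, set_b)),
            class = "overlap_test")
}

#' Match modules across two partitions of a shared gene universe
#'
#' All-pairs overlap tests with BH correction across pairs; for every module
#' in A the best B module (smallest p) is reported, unmatched when
#' `q >= 0.05`.
#'
#' @param partition_a,partition_b Named label vectors (0 = unassigned).
#' @param alpha Match significance threshold on the BH q-value.
#' @return Data frame: module_a, module_b, overlap, p, q, matched.
#' @export
match_modules <- function(partition_a, partition_b, alpha = 0.05) {
  shared <- intersect(names(partition_a), names(partition_b))
  if (length(shared) == 0L) stop("partitions have disjoint gene universes")
  pa <- partition_a[shared]; pb <- partition_b[shared]
  mods_a <- setdiff(sort(unique(pa)), 0L)
  mods_b <- setdiff(sort(unique(pb)), 0L)
  if (length(mods_a) == 0L || length(mods_b) == 0L) {
    stop("no assigned modules to match")
  }
  grid <- expand.grid(module_a = mods_a, module_b = mods_b)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ga <- shared[pa == grid$module_a[i]]
    gb <- shared[pb == grid$module_b[i]]
    ot <- suppressWarnings(overlap_test(ga, gb, length(shared)))
    p <- if (is.na(ot$p_chisq)) ot$p_fisher else ot$p_chisq
    data.frame(module_a = grid$module_a[i], module_b = grid$module_b[i],
               overlap = length(ot$overlap), p = p)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  best <- do.call(rbind, lapply(mods_a, function(m) {
    sub <- res[res$module_a == m, ]
    sub <- sub[order(sub$p, -sub$overlap), ]
    sub[1L, ]
  }))
  best$matched <- best$q < alpha
  rownames(best) <- NULL
  best
}

#' Reduced module preservation statistic
#'
#' Observed statistics in the test cohort: mean within-module signed adjacency
#' (density) and the correlation of intramodular connectivities between
#' reference and test (connectivity). Both are Z-scored against `n_perm`
#' random gene-sets of the same size; `Zsummary` is their mean.
#'
#' @param module_genes Character vector of module member ids (present in both
#'   cohorts).
#' @param expr_ref,expr_test Expression matrices (genes x samples).
#' @param n_perm Number of random gene-sets for the permutation null
#'   (>= 20).
#' @param seed Seed for the permutation stream.
#' @param beta Soft power for the signed adjacency.
#' @return A list: `z_density`, `z_connectivity`, `z_summary`,
#'   `observed`, `n_perm`, `seed`.
#' @export
module_preservation <- function(module_genes, expr_ref, expr_test,
                                n_perm = 200L, seed = 1L, beta = 6L) {
  if (n_perm < 20L) stop("n_perm < 20 gives an unstable permutation null")
  pool <- intersect(rownames(expr_ref), rownames(expr_test))
  if (!all(module_genes %in% pool)) stop("module genes missing from a cohort")
  stat_pair <- function(genes) {
    a_ref <- signed_adjacency(stats::cor(t(expr_ref[genes, , drop = FALSE])), beta)
    a_test <- signed_adjacency(stats::cor(t(expr_test[genes, , drop = FALSE])), beta)
    m <- length(genes)
    density <- sum(a_test) / (m * (m - 1))
    conn <- stats::cor(rowSums(a_ref), rowSums(a_test))
    c(density = density, connectivity = conn)
  }
  obs <- stat_pair(module_genes)
  set.seed(sub_seed(seed, 5L))
  null <- t(vapply(seq_len(n_perm), function(i) {
    stat_pair(sample(pool, length(module_genes)))
  }, numeric(2)))
  mu <- colMeans(null); sd0 <- apply(null, 2L, stats::sd)
  z <- (obs - mu) / sd0
  list(z_density = unname(z["density"]),
       z_connectivity = unname(z["connectivity"]),
       z_summary = mean(z), observed = obs, n_perm = n_perm, seed = seed)
}

#' Two-sided Mann-Whitney U test
#'
#' `U` counts pairs where an A value exceeds a B value (ties count 1/2).
#' Exact enumeration of all group assignments when `n1 + n2 <= 12`, otherwise
#' a tie-corrected normal approximation (no continuity correction).
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return A list: `U`, two-sided `p`, `medians`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 12L) {
    pool <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(i) u_stat(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = u, p = p,
       medians = c(stats::median(x), stats::median(y)), method = method)
}

#' Module eigengene vs covariate association
#'
#' Per covariate: Spearman correlation (average-rank ties) with a
#' t-approximation p-value, plus a Mann-Whitney test of the eigengene between
#' covariate quartile-1 samples and quartile-2-4 samples. BH correction across
#' covariates, separately per test family. Constant covariates are reported
#' as missing.
#'
#' @param me_row Named numeric vector (one eigengene across samples).
#' @param covariates Data frame or matrix, samples x covariates, with sample
#'   ids as row names (or a `sample` column).
#' @return Data frame: covariate, n, rho, p, q, quartile_p, quartile_q.
#' @export
me_covariate_association <- function(me_row, covariates) {
  if (is.data.frame(covariates) && "sample" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample
    covariates$sample <- NULL
  }
  covariates <- as.matrix(covariates)
  shared <- intersect(names(me_row), rownames(covariates))
  if (length(shared) < 8L) stop("need >= 8 paired samples")
  me <- me_row[shared]
  cov <- covariates[shared, , drop = FALSE]
  res <- lapply(colnames(cov), function(cv) {
    v <- cov[, cv]
    sa <- spearman_assoc(v, me)
    if (is.na(sa$rho)) {
      return(data.frame(covariate = cv, n = sa$n, rho = NA_real_, p = NA_real_,
                        quartile_p = NA_real_, stringsAsFactors = FALSE))
    }
    q1 <- v <= stats::quantile(v, 0.25, na.rm = TRUE)
    qp <- if (sum(q1, na.rm = TRUE) > 0L && sum(!q1, na.rm = TRUE) > 0L) {
      mann_whitney(me[which(q1)], me[which(!q1)])$p
    } else NA_real_
    data.frame(covariate = cv, n = sa$n, rho = sa$rho, p = sa$p,
               quartile_p = qp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$quartile_q <- stats::p.adjust(out$quartile_p, method = "BH")
  out[, c("covariate", "n", "rho", "p", "q", "quartile_p", "quartile_q")]
}
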