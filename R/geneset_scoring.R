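# Rank-based single-sample geneset scoring (bounded normalized mean rank),
# transcriptome ranking by eigengene correlation, and preranked enrichment
# with a gene-label permutation null.

#' Rank-based single-sample geneset score
#'
#' Genes are ranked ascending by expression within the sample (average ranks
#' for ties); the mean rank of set members is normalized to its attainable
#' range and centred: `score = (mu - mu_min) / (mu_max - mu_min) - 0.5` with
#' `mu_min = (m + 1) / 2` and `mu_max = N - (m - 1) / 2`. Bounded in
#' `[-0.5, 0.5]` and invariant under any strictly monotone transform of the
#' sample. Up-set direction only.
#'
#' @param values Named numeric vector: one sample's expression over the gene
#'   universe.
#' @param geneset Character vector of member ids.
#' @return The score (numeric scalar).
#' @export
single_sample_score <- function(values, geneset) {
  stopifnot(!is.null(names(values)))
  members <- intersect(unique(geneset), names(values))
  if (length(members) == 0L) stop("geneset does not intersect the gene universe")
  if (length(members) < length(unique(geneset))) {
    warning(length(unique(geneset)) - length(members),
            " geneset members absent from the universe were ignored")
  }
  n <- length(values)
  m <- length(members)
  if (n - m < 2L) stop("need >= 2 genes outside the set")
  r <- rank(values, ties.method = "average")
  mu <- mean(r[members])
  mu_min <- (m + 1) / 2
  mu_max <- n - (m - 1) / 2
  (mu - mu_min) / (mu_max - mu_min) - 0.5
}

#' Score every sample against every geneset
#'
#' @param expr Genes x samples expression matrix.
#' @param genesets Named list of character vectors.
#' @return Samples x genesets score matrix.
#' @export
score_samples <- function(expr, genesets) {
  stopifnot(is.matrix(expr), is.list(genesets))
  out <- vapply(genesets, function(gs) {
    apply(expr, 2L, single_sample_score, geneset = gs)
  }, numeric(ncol(expr)))
  out <- matrix(out, nrow = ncol(expr),
                dimnames = list(colnames(expr), names(genesets)))
  out
}

#' Rank the transcriptome by Spearman correlation with an eigengene
#'
#' Per gene, Spearman correlation with the eigengene across samples; constant
#' genes are recorded as 0 with a flag. Descending order, ties broken by gene
#' id (stable).
#'
#' @param expr Genes x samples expression matrix.
#' @param me_row Named numeric vector (one eigengene).
#' @return Data frame sorted descending: gene, rho, constant.
#' @export
rank_by_me_correlation <- function(expr, me_row) {
  shared <- intersect(colnames(expr), names(me_row))
  if (length(shared) < 8L) stop("need >= 8 samples")
  x <- expr[, shared, drop = FALSE]
  me_rank <- rank(me_row[shared])
  sds <- apply(x, 1L, stats::sd)
  rho <- rep(0, nrow(x))
  ok <- sds > 0
  if (any(ok)) {
    xr <- t(apply(x[ok, , drop = FALSE], 1L, rank))
    rho[ok] <- as.numeric(stats::cor(t(xr), me_rank))
  }
  out <- data.frame(gene = rownames(x), rho = rho, constant = !ok,
                    stringsAsFactors = FALSE)
  out[order(-out$rho, out$gene), , drop = FALSE]
}

# signed maximal deviation of the running enrichment sum; hits add normalized
# |metric|^p weight, misses subtract 1/(N - m)
es_walk <- function(hit, metric, weight_p) {
  n <- length(metric)
  m <- sum(hit)
  w <- abs(metric)^weight_p
  denom <- sum(w[hit])
  steps <- rep(-1 / (n - m), n)
  if (denom == 0) {
    steps[hit] <- 1 / m
  } else {
    steps[hit] <- w[hit] / denom
  }
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Preranked geneset enrichment
#'
#' Walks the ranked list: hits add `|metric|^weight_p` (normalized over hits),
#' misses subtract `1 / (N - m)`; the enrichment score is the signed maximal
#' deviation of the running sum. The null distribution comes from seeded
#' gene-label permutations; `NES = ES / mean(|null ES| of the same sign)` and
#' the nominal p is the same-sign null exceedance fraction (with an add-one
#' correction keeping p in `(0, 1]`).
#'
#' @param ranked Result of [rank_by_me_correlation()] (data frame with `gene`
#'   and `rho`), or a named numeric vector sorted descending.
#' @param geneset Character vector of member ids (effective size within
#'   `[2, N - 2]`).
#' @param n_perm Number of permutations (warning below 100; 0 gives ES only).
#' @param weight_p Metric weighting exponent: 1 (classic weighted) or 0.
#' @param seed Seed for the permutation stream.
#' @return A list of class `gsea_result`: `es`, `nes`, `p`, `n_hits`,
#'   `n_perm`, `seed`.
#' @export
gsea_preranked <- function(ranked, geneset, n_perm = 1000L, weight_p = 1,
                           seed = 1L) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene
    metric <- ranked$rho
  } else {
    genes <- names(ranked)
    metric <- as.numeric(ranked)
  }
  stopifnot(weight_p %in% c(0, 1))
  n <- length(genes)
  hit <- genes %in% geneset
  m <- sum(hit)
  if (m < 2L || m > n - 2L) stop("effective geneset size must lie in [2, N - 2]")
  if (n_perm > 0L && n_perm < 100L) warning("n_perm < 100 gives a coarse null")
  es <- es_walk(hit, metric, weight_p)
  if (n_perm == 0L) {
    return(structure(list(es = es, nes = NA_real_, p = NA_real_, n_hits = m,
                          n_perm = 0L, seed = seed), class = "gsea_result"))
  }
  set.seed(sub_seed(seed, 6L))
  null_es <- vapply(seq_len(n_perm), function(i) {
    h <- logical(n)
    h[sample.int(n, m)] <- TRUE
    es_walk(h, metric, weight_p)
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same) == 0L) {
    nes <- NA_real_
    p <- 1 / (n_perm + 1)
  } else {
    nes <- es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }
  structure(list(es = es, nes = nes, p = p, n_hits = m, n_perm = n_perm,
                 seed = seed), class = "gsea_result")
}

#' Preranked enrichment over a collection of genesets
#'
#' Runs [gsea_preranked()] per set and applies BH correction across sets.
#'
#' @param ranked Ranked list (see [gsea_preranked()]).
#' @param genesets Named list of character vectors.
#' @param ... Passed to [gsea_preranked()].
#' @return Data frame: geneset, n_hits, es, nes, p, q.
#' @export
gsea_genesets <- function(ranked, genesets, ...) {
  res <- lapply(names(genesets), function(nm) {
    g <- gsea_preranked(ranked, genesets[[nm]], ...)
    data.frame(geneset = nm, n_hits = g$n_hits, es = g$es, nes = g$nes,
               p = g$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
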