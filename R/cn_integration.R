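# Copy-number driver decision tree: a gene is a candidate module driver when
# both its copy-number calls and its expression correlate significantly (BH
# q < alpha, same sign) with the module eigengene; candidates are then tested
# for module over-representation.

#' Candidate copy-number drivers of a module
#'
#' Per gene, Spearman correlations of CN vs eigengene and expression vs
#' eigengene over case-matched samples; BH correction within each family.
#' A candidate must pass both significance gates with concordant signs (a
#' gene whose CN and expression point opposite ways is not CN-driven);
#' direction maps the CN correlation sign to gain/loss. Constant-CN genes are
#' excluded with a reported count.
#'
#' @param cn Genes x samples integer call matrix (-2..2).
#' @param expr Genes x samples expression matrix.
#' @param me_row Named numeric vector (module eigengene).
#' @param alpha BH q-value threshold for both gates (default 0.05).
#' @return Data frame (one row per tested gene): gene, rho_cn, p_cn, q_cn,
#'   rho_expr, p_expr, q_expr, candidate, direction. Attributes
#'   `n_constant_cn` (excluded genes), `n_discordant` (both gates passed but
#'   signs opposed), `n_samples`.
#' @export
candidate_drivers <- function(cn, expr, me_row, alpha = 0.05) {
  samples <- Reduce(intersect, list(colnames(cn), colnames(expr), names(me_row)))
  if (length(samples) < 8L) stop("need >= 8 case-matched samples")
  genes <- intersect(rownames(cn), rownames(expr))
  if (length(genes) == 0L) stop("no shared genes between CN and expression")
  cnm <- cn[genes, samples, drop = FALSE]
  exm <- expr[genes, samples, drop = FALSE]
  me <- me_row[samples]

  cn_sd <- apply(cnm, 1L, stats::sd)
  constant <- cn_sd == 0
  tested <- genes[!constant]
  me_rank <- rank(me)
  n <- length(samples)

  rho_p <- function(mat) {
    rk <- t(apply(mat, 1L, rank))
    rho <- as.numeric(stats::cor(t(rk), me_rank))
    p <- vapply(rho, cor_t_pvalue, numeric(1), n = n)
    list(rho = rho, p = p)
  }
  cn_res <- rho_p(cnm[tested, , drop = FALSE])
  ex_res <- rho_p(exm[tested, , drop = FALSE])
  q_cn <- stats::p.adjust(cn_res$p, method = "BH")
  q_expr <- stats::p.adjust(ex_res$p, method = "BH")
  both_sig <- q_cn < alpha & q_expr < alpha
  concordant <- cn_res$rho * ex_res$rho > 0
  out <- data.frame(gene = tested,
                    rho_cn = cn_res$rho, p_cn = cn_res$p, q_cn = q_cn,
                    rho_expr = ex_res$rho, p_expr = ex_res$p, q_expr = q_expr,
                    candidate = both_sig & concordant,
                    direction = ifelse(cn_res$rho > 0, "gain", "loss"),
                    stringsAsFactors = FALSE)
  attr(out, "n_constant_cn") <- sum(constant)
  attr(out, "n_discordant") <- sum(both_sig & !concordant)
  attr(out, "n_samples") <- n
  out
}

#' Module over-representation among positively correlated driver candidates
#'
#' Delegates to [overlap_test()] on (gain candidates) x (module genes) and
#' reports the overlap as a percentage of the candidate list.
#'
#' @param candidates Result of [candidate_drivers()] (or a character vector
#'   of candidate gene ids, all treated as gains).
#' @param module_genes Character vector of module member ids.
#' @param universe Universe size (count) or id vector.
#' @return A list: `test` (an `overlap_test`), `overlap_percent`,
#'   `n_candidates`, `n_module`.
#' @export
driver_module_enrichment <- function(candidates, module_genes, universe) {
  if (is.data.frame(candidates)) {
    cand <- candidates$gene[candidates$candidate & candidates$direction == "gain"]
  } else {
    cand <- unique(candidates)
  }
  if (length(cand) == 0L) stop("empty candidate list")
  test <- overlap_test(cand, module_genes, universe)
  list(test = test,
       overlap_percent = percent_of(length(test$overlap), length(cand)),
       n_candidates = length(cand), n_module = length(unique(module_genes)))
}

#' Percentage reporter
#'
#' `100 * k / n`, rounded to `digits` decimals — the formatting used for
#' overlap and large-segment fractions.
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @param digits Decimals to keep (default 1).
#' @return Numeric percentage.
#' @export
percent_of <- function(k, n, digits = 1L) {
  stopifnot(n > 0)
  round(100 * k / n, digits)
}

#' Descriptive chromosome colocation of driver candidates
#'
#' Counts candidates per chromosome and reports the fraction located on
#' chromosomes carrying at least `min_genes` candidates (a proxy for large
#' recurrent segments). Descriptive only; no segmentation inference.
#'
#' @param candidate_genes Character vector of candidate ids.
#' @param gene_chrom Named character vector mapping gene id to chromosome.
#' @param min_genes Minimum candidates for a chromosome to count as a large
#'   segment (default 10).
#' @return A list: `per_chrom` (table), `large_segment_percent`, `n_large`.
#' @export
segment_colocation <- function(candidate_genes, gene_chrom, min_genes = 10L) {
  chrom <- gene_chrom[candidate_genes]
  tab <- sort(table(chrom), decreasing = TRUE)
  large <- names(tab)[tab >= min_genes]
  n_large <- sum(chrom %in% large)
  list(per_chrom = tab,
       large_segment_percent = percent_of(n_large, length(candidate_genes)),
       n_large = n_large)
}
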