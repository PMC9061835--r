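# Promoter methylation pipeline: exclusion-flag probe filtering, promoter
# MAD normalization, gene-level promoter summaries with missingness filters,
# module-eigengene x promoter Spearman correlation with clustering and
# silhouette validation, and region-category / solo-WCpGW association.

#' Remove probes carrying exclusion flags
#'
#' Drops probes flagged as sex-chromosomal, multi-mapping, SNP-adjacent or
#' non-CpG, reporting counts per reason.
#'
#' @param beta Probes x samples beta-value matrix.
#' @param ann Probe annotation data frame (see [generate_methylation()] for
#'   the column contract). Every probe in `beta` must be annotated.
#' @return A list: `beta` (filtered matrix), `report` (named counts: per
#'   reason, removed, retained).
#' @export
filter_probes <- function(beta, ann) {
  missing <- setdiff(rownames(beta), ann$probe_id)
  if (length(missing)) {
    stop("unannotated probes: ", paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) " ..." else "")
  }
  ann <- ann[match(rownames(beta), ann$probe_id), ]
  flags <- c("flag_xy", "flag_multimap", "flag_snp", "flag_noncg")
  flagged <- as.matrix(ann[, flags]) == 1L
  any_flag <- rowSums(flagged) > 0L
  report <- c(colSums(flagged), removed = sum(any_flag),
              retained = sum(!any_flag))
  storage.mode(report) <- "integer"
  list(beta = beta[!any_flag, , drop = FALSE], report = report)
}

promoter_ids <- function(ann) {
  ann$probe_id[ann$region_group %in% PROMOTER_GROUPS]
}

#' MAD-style normalization of promoter probe beta-values
#'
#' Corrects the bimodal beta distribution of promoter probes
#' (TSS1500/TSS200/5'UTR). Per sample `s`, the reference level `G_s` is the
#' median beta over all promoter probes; per probe `p`, the offset is the
#' median over samples of `beta_ps - G_s`; the normalized value is
#' `beta_ps - offset_p`. The inner median is a per-sample reference level and
#' the outer a probe-specific location offset, which preserves cross-sample
#' variation per probe while removing probe-level location bias.
#'
#' @param beta Probes x samples beta matrix (missing values allowed; probes
#'   entirely missing in a sample are excluded from that sample's reference
#'   median).
#' @param ann Probe annotation.
#' @return Normalized promoter-probe matrix with attributes
#'   `sample_reference` (`G_s`) and `probe_offset`.
#' @export
promoter_mad_normalize <- function(beta, ann) {
  if (ncol(beta) < 2L) stop("need >= 2 samples")
  probes <- intersect(rownames(beta), promoter_ids(ann))
  if (length(probes) == 0L) stop("no promoter probes present")
  b <- beta[probes, , drop = FALSE]
  g <- apply(b, 2L, stats::median, na.rm = TRUE)
  centered <- sweep(b, 2L, g)
  offset <- apply(centered, 1L, stats::median, na.rm = TRUE)
  out <- sweep(b, 1L, offset)
  attr(out, "sample_reference") <- g
  attr(out, "probe_offset") <- offset
  out
}

#' Gene-level promoter summaries with missingness filters
#'
#' Per gene, the mean of its (normalized) promoter probes per sample. Genes
#' with more than `max_missing_probes` probes containing missing data, or with
#' more than `max_missing_sample_frac` of samples unobserved after averaging,
#' are dropped with a logged reason.
#'
#' @param norm Normalized promoter probe matrix (from
#'   [promoter_mad_normalize()]).
#' @param ann Probe annotation.
#' @param max_missing_probes Maximum tolerated probes with missing data per
#'   gene (default 2).
#' @param max_missing_sample_frac Maximum tolerated fraction of missing
#'   samples per gene (default 0.02).
#' @return A list: `profile` (genes x samples), `probe_count` (named), and
#'   `dropped` (data frame gene/reason).
#' @export
summarize_gene_promoters <- function(norm, ann, max_missing_probes = 2L,
                                     max_missing_sample_frac = 0.02) {
  ann <- ann[match(rownames(norm), ann$probe_id), ]
  genes <- unique(ann$gene)
  rows <- list(); counts <- integer(0); dropped <- list()
  for (g in genes) {
    probes <- ann$probe_id[ann$gene == g]
    sub <- norm[probes, , drop = FALSE]
    n_missing_probes <- sum(apply(sub, 1L, anyNA))
    if (n_missing_probes > max_missing_probes) {
      dropped[[g]] <- "missing_probes"
      next
    }
    v <- colMeans(sub, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    if (mean(is.na(v)) > max_missing_sample_frac) {
      dropped[[g]] <- "missing_samples"
      next
    }
    rows[[g]] <- v
    counts[g] <- length(probes)
  }
  if (length(rows) == 0L) stop("no genes survive the missingness filters")
  profile <- do.call(rbind, rows)
  dropped_df <- data.frame(gene = names(dropped),
                           reason = unlist(dropped, use.names = FALSE),
                           stringsAsFactors = FALSE)
  list(profile = profile, probe_count = counts, dropped = dropped_df)
}

#' Spearman correlation of promoter profiles with module eigengenes
#'
#' @param me Eigengene matrix (modules x samples) or an [eigengenes()]
#'   result.
#' @param profile Gene promoter profile matrix (genes x samples) or the
#'   result of [summarize_gene_promoters()].
#' @return Genes x modules Spearman correlation matrix (pairwise-complete).
#' @export
me_promoter_correlation <- function(me, profile) {
  if (is.list(me)) me <- me$me
  if (is.list(profile)) profile <- profile$profile
  shared <- intersect(colnames(me), colnames(profile))
  if (length(shared) < 8L) stop("need >= 8 shared samples")
  p <- profile[, shared, drop = FALSE]
  m <- me[, shared, drop = FALSE]
  out <- matrix(NA_real_, nrow = nrow(p), ncol = nrow(m),
                dimnames = list(rownames(p), rownames(m)))
  for (j in seq_len(nrow(m))) {
    for (i in seq_len(nrow(p))) {
      out[i, j] <- spearman_assoc(p[i, ], m[j, ])$rho
    }
  }
  out
}

#' Cluster genes by their eigengene-correlation profiles
#'
#' Hierarchical clustering (Euclidean distance, average linkage) of the gene
#' rows of a correlation matrix, cut to `k` clusters or at height `h`, with
#' silhouette validation on the same distance. Singleton clusters get
#' silhouette 0 by convention, as do degenerate (all-identical) inputs.
#'
#' @param corr Genes x modules correlation matrix (>= 3 genes).
#' @param k Number of clusters (exclusive with `h`).
#' @param h Cut height (used when `k` is NULL).
#' @return A list: `labels`, `silhouette` (per gene), `mean_silhouette`
#'   (per cluster), `hclust`.
#' @export
cluster_correlation_profiles <- function(corr, k = NULL, h = NULL) {
  if (nrow(corr) < 3L) stop("need >= 3 genes")
  if (!is.null(k) && k > nrow(corr)) stop("k exceeds the number of genes")
  d <- stats::dist(corr)
  hc <- stats::hclust(d, method = "average")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k)
  else stats::cutree(hc, h = h %||% stats::median(hc$height))
  if (length(unique(labels)) < 2L || max(d) == 0) {
    sil <- stats::setNames(rep(0, nrow(corr)), rownames(corr))
  } else {
    sw <- cluster::silhouette(labels, d)
    sil <- stats::setNames(sw[, "sil_width"], rownames(corr))
    sil[!is.finite(sil)] <- 0
  }
  mean_sil <- tapply(sil, labels, mean)
  list(labels = labels, silhouette = sil, mean_silhouette = mean_sil,
       hclust = hc)
}

#' Region-category and solo-WCpGW association with an eigengene
#'
#' For every region-group x CGI-relation stratum, plus the solo-WCpGW
#' stratum: the per-sample mean beta over the stratum's probes is correlated
#' (Spearman) with the eigengene; BH correction across strata. Strata with
#' `q` below `flag_threshold` (default 1e-7, a conventional stringent mark
#' for genome-scale methylation scans) are flagged. Empty strata are reported
#' as missing, not errors.
#'
#' @param me_row Named numeric vector (one eigengene).
#' @param beta Probes x samples beta matrix (typically pre-filtered).
#' @param ann Probe annotation.
#' @param flag_threshold q-value significance mark.
#' @return Data frame: category, region_group, cgi_relation, n_probes, rho,
#'   p, q, flagged.
#' @export
region_category_association <- function(me_row, beta, ann,
                                        flag_threshold = 1e-7) {
  ann <- ann[match(rownames(beta), ann$probe_id), ]
  shared <- intersect(colnames(beta), names(me_row))
  if (length(shared) < 8L) stop("need >= 8 shared samples")
  b <- beta[, shared, drop = FALSE]
  me <- me_row[shared]
  strata <- expand.grid(region_group = REGION_GROUPS,
                        cgi_relation = CGI_RELATIONS,
                        stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- ann$region_group == strata$region_group[i] &
      ann$cgi_relation == strata$cgi_relation[i]
    stratum_row(paste(strata$region_group[i], strata$cgi_relation[i], sep = "."),
                strata$region_group[i], strata$cgi_relation[i], sel, b, me)
  })
  res <- c(res, list(stratum_row("solo_WCpGW", NA_character_, NA_character_,
                                 ann$flag_solowcpgw == 1L, b, me)))
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- !is.na(out$q) & out$q < flag_threshold
  out
}

stratum_row <- function(name, rg, cr, sel, b, me) {
  n <- sum(sel)
  if (n == 0L) {
    return(data.frame(category = name, region_group = rg, cgi_relation = cr,
                      n_probes = 0L, rho = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  v <- colMeans(b[sel, , drop = FALSE], na.rm = TRUE)
  sa <- spearman_assoc(v, me)
  data.frame(category = name, region_group = rg, cgi_relation = cr,
             n_probes = n, rho = sa$rho, p = sa$p, stringsAsFactors = FALSE)
}
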