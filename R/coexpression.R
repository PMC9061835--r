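# Signed weighted co-expression network construction: correlation ->
# soft-thresholded signed adjacency -> topological overlap -> average-linkage
# module detection with eigengene merging -> module eigengenes, membership
# (kME) and connectivity (kTotal/kWithin/kOut).

#' Network construction configuration
#'
#' @param soft_power Soft power used by the pipeline; 12 is the conventional
#'   default for signed networks. Set to `NULL` to select it with
#'   [select_soft_threshold()] instead.
#' @param beta_candidates Integer soft powers scanned by
#'   [select_soft_threshold()].
#' @param scale_free_r2 Target scale-free topology fit R^2 (default 0.85).
#' @param min_module_size Clusters smaller than this are left unassigned
#'   (label 0).
#' @param cut_height Static cut height on the 1-TOM dendrogram. 0.95 is the
#'   conventional static cut for signed-TOM trees.
#' @param merge_dissimilarity Modules whose eigengene dissimilarity
#'   `1 - cor(ME_a, ME_b)` falls below this are merged (default 0.25).
#' @param correlation Correlation method; only `"pearson"` is implemented (the
#'   knob is reserved).
#' @return A list of class `network_config`.
#' @export
network_config <- function(soft_power = 12L, beta_candidates = 1:20,
                           scale_free_r2 = 0.85,
                           min_module_size = 30L, cut_height = 0.95,
                           merge_dissimilarity = 0.25,
                           correlation = "pearson") {
  stopifnot(all(beta_candidates >= 1), scale_free_r2 > 0, scale_free_r2 <= 1,
            cut_height > 0, cut_height <= 1,
            is.null(soft_power) || soft_power >= 1)
  correlation <- match.arg(correlation, "pearson")
  structure(list(soft_power = if (!is.null(soft_power)) as.integer(soft_power),
                 beta_candidates = as.integer(beta_candidates),
                 scale_free_r2 = scale_free_r2,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height,
                 merge_dissimilarity = merge_dissimilarity,
                 correlation = correlation),
            class = "network_config")
}

#' Pairwise gene correlation matrix
#'
#' Pearson correlation of every gene pair across samples. Zero-variance genes
#' are dropped with a warning listing their ids.
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlate <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3L) stop("need >= 3 samples for correlation")
  v <- apply(expr, 1L, stats::sd)
  if (all(v == 0)) stop("all genes have zero variance")
  if (any(v == 0)) {
    warning("dropping zero-variance genes: ",
            paste(rownames(expr)[v == 0], collapse = ", "))
    expr <- expr[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  diag(r) <- 1
  r
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + r_ij) / 2)^beta`, so perfectly anti-correlated genes get
#' adjacency 0 and perfectly correlated genes 1. The diagonal is set to 0 for
#' connectivity sums.
#'
#' @param cor_mat Correlation matrix.
#' @param beta Soft power (integer >= 1).
#' @return Adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
signed_adjacency <- function(cor_mat, beta = 6L) {
  stopifnot(beta >= 1)
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 0
  a
}

scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(signif(k, 10))) < 2L) {
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  kmean <- tapply(k, bin, mean)
  keep <- counts > 0 & !is.na(kmean) & kmean > 0
  if (sum(keep) < 3L) return(list(r2 = NA_real_, slope = NA_real_))
  x <- log10(kmean[keep])
  y <- log10(counts[keep] / sum(counts))
  fit <- stats::lm(y ~ x)
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]))
}

#' Select the soft power by the scale-free topology criterion
#'
#' For each candidate power the signed adjacency is formed, connectivities are
#' binned on log10 scale, and `log10 p(k)` is regressed on `log10 k`. The
#' smallest power reaching the target R^2 with a negative slope is returned;
#' if none qualifies, the largest candidate is returned with a warning.
#'
#' @param cor_mat Correlation matrix (>= 20 genes for a meaningful degree
#'   distribution).
#' @param config A [network_config()].
#' @return A list with `beta`, `fits` (data frame of power, r2, slope, mean
#'   connectivity) and `converged` (FALSE when the fallback fired).
#' @export
select_soft_threshold <- function(cor_mat, config = network_config()) {
  if (length(config$beta_candidates) == 0L) stop("empty beta candidate list")
  if (nrow(cor_mat) < 20L) stop("need >= 20 genes for a degree distribution")
  fits <- lapply(config$beta_candidates, function(b) {
    a <- signed_adjacency(cor_mat, b)
    k <- rowSums(a)
    f <- scale_free_fit(k)
    data.frame(beta = b, r2 = f$r2, slope = f$slope, mean_k = mean(k))
  })
  fits <- do.call(rbind, fits)
  ok <- !is.na(fits$r2) & fits$r2 >= config$scale_free_r2 &
    !is.na(fits$slope) & fits$slope < 0
  if (any(ok)) {
    beta <- fits$beta[which(ok)[1L]]
    converged <- TRUE
  } else {
    beta <- max(config$beta_candidates)
    converged <- FALSE
    warning("no candidate power reached the scale-free fit target; ",
            "returning the largest candidate (", beta, ")")
  }
  list(beta = beta, fits = fits, converged = converged)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is defined
#' as 1. Reflects net connection weight, combining the direct edge with
#' shared-neighbour weight.
#'
#' @param adj Symmetric adjacency matrix with zero diagonal.
#' @return TOM matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  stopifnot(isSymmetric(unname(adj)), all(diag(adj) == 0))
  l <- adj %*% adj
  k <- rowSums(adj)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect modules by average-linkage clustering of 1-TOM
#'
#' The 1-TOM dissimilarity tree is cut at a fixed height, clusters below
#' `min_module_size` are relabelled 0 (unassigned), and modules whose
#' eigengene dissimilarity falls below `merge_dissimilarity` are merged
#' iteratively until stable. Labels are renumbered by descending size.
#'
#' @param tom TOM matrix.
#' @param expr Expression matrix (needed to compute eigengenes for the merge
#'   step).
#' @param config A [network_config()].
#' @return A list with `labels` (named integer vector, 0 = unassigned),
#'   `sizes`, `n_merges`, and the `hclust` tree.
#' @export
detect_modules <- function(tom, expr, config = network_config()) {
  stopifnot(identical(rownames(tom), rownames(expr)))
  d <- 1 - tom
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(hc, h = config$cut_height)
  tab <- table(labels)
  small <- as.integer(names(tab)[tab < config$min_module_size])
  labels[labels %in% small] <- 0L
  labels <- renumber_labels(labels)
  names(labels) <- rownames(tom)

  n_merges <- 0L
  repeat {
    mods <- setdiff(sort(unique(labels)), 0L)
    if (length(mods) < 2L) break
    me <- eigengenes(expr, labels)$me
    cm <- stats::cor(t(me))
    diss <- 1 - cm
    diag(diss) <- Inf
    idx <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    if (diss[idx[1L], idx[2L]] >= config$merge_dissimilarity) break
    a <- mods[min(idx)]; b <- mods[max(idx)]
    labels[labels == b] <- a
    labels <- renumber_labels(labels)
    n_merges <- n_merges + 1L
  }
  labels <- renumber_labels(labels)
  list(labels = labels, sizes = table(labels), n_merges = n_merges, hclust = hc)
}

# renumber module labels by descending size (ties: previous numbering),
# keeping 0 for unassigned
renumber_labels <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  if (length(mods) == 0L) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), numeric(1))
  ord <- mods[order(-sizes, mods)]
  new <- labels
  for (i in seq_along(ord)) new[labels == ord[i]] <- i
  new
}

#' Module eigengenes
#'
#' Member genes are standardized across samples and the first principal
#' component of the samples-by-genes submatrix is taken as the module
#' eigengene (unit norm over samples), oriented so that its mean correlation
#' with member genes is non-negative. Per-module variance explained is
#' reported.
#'
#' @param expr Expression matrix.
#' @param labels Named module labels (0 = unassigned) or the result of
#'   [detect_modules()].
#' @return A list with `me` (modules x samples matrix, rows `M1`, `M2`, ...)
#'   and `var_explained`.
#' @export
eigengenes <- function(expr, labels) {
  if (is.list(labels)) labels <- labels$labels
  stopifnot(!is.null(names(labels)))
  mods <- setdiff(sort(unique(labels)), 0L)
  if (length(mods) == 0L) stop("no assigned modules")
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(sprintf("M%d", mods), colnames(expr)))
  varexp <- numeric(length(mods))
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    x <- expr[members, , drop = FALSE]
    if (nrow(x) == 1L) {
      warning("module ", mods[i], " has a single gene; ME is its standardized profile")
      v <- as.numeric(scale(as.numeric(x)))
      me[i, ] <- v / sqrt(sum(v^2))
      varexp[i] <- 1
      next
    }
    xs <- t(scale(t(x)))  # standardize each gene across samples
    sv <- svd(t(xs), nu = 1L, nv = 0L)
    v <- sv$u[, 1L]
    if (mean(stats::cor(v, t(x))) < 0) v <- -v
    me[i, ] <- v
    varexp[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  names(varexp) <- rownames(me)
  list(me = me, var_explained = varexp)
}

#' Module membership (kME) table
#'
#' Pearson correlation of each gene with each module eigengene, a two-sided
#' t-test p-value on `n - 2` degrees of freedom, and a per-module BH q-value
#' across genes.
#'
#' @param expr Expression matrix.
#' @param me Eigengene result from [eigengenes()] or a modules x samples
#'   matrix.
#' @return Long data frame: gene, module, kme, p, q.
#' @export
module_membership <- function(expr, me) {
  if (is.list(me)) me <- me$me
  shared <- intersect(colnames(expr), colnames(me))
  if (length(shared) < 4L) stop("need >= 4 shared samples for kME p-values")
  expr <- expr[, shared, drop = FALSE]
  me <- me[, shared, drop = FALSE]
  n <- length(shared)
  out <- do.call(rbind, lapply(rownames(me), function(m) {
    kme <- as.numeric(stats::cor(t(expr), me[m, ]))
    p <- vapply(kme, cor_t_pvalue, numeric(1), n = n)
    data.frame(gene = rownames(expr), module = m, kme = kme, p = p,
               q = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Gene connectivity within and outside its module
#'
#' `kTotal_i = sum_j a_ij`, `kWithin_i` sums over same-module genes, and
#' `kOut = kTotal - kWithin`. Unassigned genes (label 0) get `kWithin = 0`
#' by convention.
#'
#' @param adj Adjacency matrix with zero diagonal.
#' @param labels Named module labels or a [detect_modules()] result.
#' @return Data frame: gene, module, kTotal, kWithin, kOut.
#' @export
connectivity <- function(adj, labels) {
  if (is.list(labels)) labels <- labels$labels
  stopifnot(identical(rownames(adj), names(labels)))
  ktotal <- rowSums(adj)
  kwithin <- vapply(seq_along(labels), function(i) {
    if (labels[i] == 0L) return(0)
    same <- labels == labels[i]
    same[i] <- FALSE
    sum(adj[i, same])
  }, numeric(1))
  data.frame(gene = names(labels), module = as.integer(labels),
             kTotal = ktotal, kWithin = kwithin, kOut = ktotal - kwithin,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample module expression fractions
#'
#' Each eigengene is shifted by its cohort minimum and, per sample, divided by
#' the sum across modules, giving fractions in `[0, 1]` that sum to 1. A
#' threshold classifier (`fraction >= cutoff` = "high") supports module-based
#' case classification.
#'
#' @param me Eigengene matrix (modules x samples) or an [eigengenes()] result.
#' @return Matrix of fractions with the same dimnames.
#' @export
module_fractions <- function(me) {
  if (is.list(me)) me <- me$me
  shifted <- sweep(me, 1L, apply(me, 1L, min))
  tot <- colSums(shifted)
  frac <- sweep(shifted, 2L, ifelse(tot == 0, 1, tot), "/")
  degenerate <- tot == 0
  if (any(degenerate)) frac[, degenerate] <- 1 / nrow(me)
  frac
}

#' Classify samples as module-high by a fraction cutoff
#'
#' @param fractions Result of [module_fractions()].
#' @param cutoff High/low threshold on the module fraction (default 0.33).
#' @return Logical matrix, TRUE where the sample is "high" for the module.
#' @export
classify_module_high <- function(fractions, cutoff = 0.33) {
  fractions >= cutoff
}
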