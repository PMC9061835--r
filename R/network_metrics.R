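# Hub identification on a module's weighted graph: shortest-path betweenness
# (on edge lengths), eigenvector centrality (on edge weights), cosine
# similarity substructure, and greedy-modularity community detection.

#' Build a weighted graph from a TOM (or any similarity) matrix
#'
#' Edges with weight >= `epsilon` are retained; self-edges are removed. Edge
#' lengths follow `length_mode`: `one_minus` (`1 - w`, the default: high
#' overlap = short path) or `reciprocal` (`1 / w`).
#'
#' @param tom Symmetric similarity matrix (diagonal ignored).
#' @param length_mode `"one_minus"` or `"reciprocal"`.
#' @param epsilon Weight floor for sparsification.
#' @return A list of class `weighted_graph`: `nodes`, `edges` (from, to,
#'   weight, length), `weights` (matrix with zero diagonal).
#' @export
build_graph <- function(tom, length_mode = c("one_minus", "reciprocal"),
                        epsilon = 0) {
  length_mode <- match.arg(length_mode)
  stopifnot(isSymmetric(unname(tom)))
  w <- tom
  diag(w) <- 0
  nodes <- rownames(w) %||% as.character(seq_len(nrow(w)))
  dimnames(w) <- list(nodes, nodes)
  ut <- which(upper.tri(w) & w >= epsilon & w > 0, arr.ind = TRUE)
  if (nrow(ut) == 0L) stop("no edges retained: epsilon >= max weight")
  weight <- w[ut]
  len <- switch(length_mode,
                one_minus = pmax(1 - weight, 1e-12),
                reciprocal = 1 / weight)
  edges <- data.frame(from = nodes[ut[, 1L]], to = nodes[ut[, 2L]],
                      weight = weight, length = len, stringsAsFactors = FALSE)
  keep <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  keep[cbind(ut[, 1L], ut[, 2L])] <- weight
  keep <- keep + t(keep)
  structure(list(nodes = nodes, edges = edges, weights = keep,
                 length_mode = length_mode, epsilon = epsilon),
            class = "weighted_graph")
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Unnormalized shortest-path betweenness centrality
#'
#' Shortest paths use edge lengths; each unordered pair is counted once and
#' tied shortest paths share credit fractionally.
#'
#' @param graph A [build_graph()] result.
#' @return Named numeric vector over all nodes (isolated nodes get 0).
#' @export
graph_betweenness <- function(graph) {
  g <- as_igraph(graph)
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = igraph::E(g)$length, normalized = FALSE)
  out <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  out[names(b)] <- as.numeric(b)
  out
}

#' Eigenvector centrality on edge weights
#'
#' Leading eigenvector of the (symmetric, nonnegative) weight matrix of the
#' largest connected component; nodes outside that component get 0. With
#' `scale = TRUE` the maximum is 1.
#'
#' @param graph A [build_graph()] result.
#' @param scale Scale so the maximum centrality is 1.
#' @return Named numeric vector.
#' @export
graph_eigencentrality <- function(graph, scale = TRUE) {
  w <- graph$weights
  if (any(w < 0)) stop("eigencentrality needs nonnegative weights")
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  members <- graph$nodes[graph$nodes %in% names(comp$membership)[comp$membership == biggest]]
  out <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  wm <- w[members, members, drop = FALSE]
  ev <- eigen(wm, symmetric = TRUE)
  v <- abs(ev$vectors[, 1L])  # Perron vector of a nonnegative symmetric matrix
  if (scale) {
    if (max(v) > 0) v <- v / max(v)
  }
  out[members] <- v
  out
}

#' Rank hub genes
#'
#' Descending `kWithin`; ties broken by eigencentrality, then betweenness,
#' then gene id (stable, documented order).
#'
#' @param centrality Data frame with columns `gene`, `kWithin`,
#'   `eigencentrality`, `betweenness`.
#' @param top_k Number of genes to return (`top_k > n` returns the full
#'   list; 0 returns an empty vector).
#' @return Character vector of gene ids.
#' @export
hub_rank <- function(centrality, top_k = 10L) {
  stopifnot(nrow(centrality) > 0L)
  ord <- order(-centrality$kWithin, -centrality$eigencentrality,
               -centrality$betweenness, centrality$gene)
  utils::head(centrality$gene[ord], max(top_k, 0L))
}

#' Centrality table for one module
#'
#' Combines intramodular connectivity (from the signed adjacency) with
#' betweenness and eigencentrality computed on the module's TOM subgraph.
#'
#' @param adj Signed adjacency matrix (all genes).
#' @param tom TOM matrix (all genes).
#' @param labels Module labels or a [detect_modules()] result.
#' @param module Module label to analyse.
#' @param epsilon Edge weight floor for the module graph.
#' @return Data frame: gene, kWithin, eigencentrality, betweenness.
#' @export
module_centrality <- function(adj, tom, labels, module, epsilon = 0) {
  if (is.list(labels)) labels <- labels$labels
  genes <- names(labels)[labels == module]
  if (length(genes) < 2L) stop("module has fewer than 2 genes")
  g <- build_graph(tom[genes, genes], "one_minus", epsilon)
  am <- adj[genes, genes]
  diag(am) <- 0
  data.frame(gene = genes,
             kWithin = rowSums(am),
             eigencentrality = as.numeric(graph_eigencentrality(g)[genes]),
             betweenness = as.numeric(graph_betweenness(g)[genes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cosine similarity between profile rows
#'
#' `s_ij = <x_i, x_j> / (||x_i|| ||x_j||)`. Zero-norm profiles yield rows of
#' 0 with a warning; the diagonal is defined as 1.
#'
#' @param x Matrix whose rows are profiles (>= 2 columns).
#' @return Symmetric similarity matrix in `[-1, 1]` with unit diagonal.
#' @export
cosine_similarity <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    warning("zero-norm profiles set to similarity 0: ",
            paste(rownames(x)[norms == 0], collapse = ", "))
  }
  safe <- ifelse(norms == 0, 1, norms)
  s <- (x %*% t(x)) / outer(safe, safe)
  s[norms == 0, ] <- 0
  s[, norms == 0] <- 0
  diag(s) <- 1
  s
}

#' Greedy modularity community detection
#'
#' Agglomerative merging of communities by maximal modularity gain on edge
#' weights, deterministic given input order, with
#' `Q = sum_c (e_c - a_c^2)` over weight fractions. Merging stops when no
#' merge increases Q. With no edges every node is its own community and
#' `Q = 0`.
#'
#' @param graph A [build_graph()] result.
#' @return A list with `membership` (named integer vector), `Q`, and the
#'   per-merge Q trace `q_trace`.
#' @export
detect_communities <- function(graph) {
  w <- graph$weights
  n <- nrow(w)
  if (n < 2L) stop("need >= 2 nodes")
  m2 <- sum(w)
  if (m2 == 0) {
    return(list(membership = stats::setNames(seq_len(n), graph$nodes),
                Q = 0, q_trace = numeric(0)))
  }
  # community-level weight matrix and degree fractions
  ew <- w / m2           # e matrix: ew[c,d] summed over members, both directions
  a <- rowSums(ew)
  active <- rep(TRUE, n)
  member_of <- seq_len(n)
  q_now <- sum(diag(ew)) - sum(a^2)
  q_trace <- numeric(0)
  repeat {
    ids <- which(active)
    if (length(ids) < 2L) break
    # candidate merges: connected community pairs
    sub <- ew[ids, ids, drop = FALSE]
    gain <- 2 * (sub - outer(a[ids], a[ids]))
    gain[lower.tri(gain, diag = TRUE)] <- -Inf
    gain[sub <= 0] <- -Inf
    best <- which.max(gain)
    if (!is.finite(gain[best]) || gain[best] <= 0) break
    ij <- arrayInd(best, dim(gain))
    ci <- ids[ij[1L]]; cj <- ids[ij[2L]]
    # merge cj into ci
    ew[ci, ] <- ew[ci, ] + ew[cj, ]
    ew[, ci] <- ew[, ci] + ew[, cj]
    ew[cj, ] <- 0; ew[, cj] <- 0
    a[ci] <- a[ci] + a[cj]; a[cj] <- 0
    active[cj] <- FALSE
    member_of[member_of == cj] <- ci
    q_new <- q_now + gain[best]
    stopifnot(q_new >= q_now - 1e-12)  # Q never decreases during agglomeration
    q_now <- q_new
    q_trace <- c(q_trace, q_now)
  }
  membership <- as.integer(factor(member_of, levels = unique(member_of)))
  list(membership = stats::setNames(membership, graph$nodes),
       Q = q_now, q_trace = q_trace)
}
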