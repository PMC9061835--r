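# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: enumeration and longhand formulas, never calls into the
# code paths they verify.

# all simple paths between two nodes of a small weighted graph; returns
# betweenness credit per node by exhaustive shortest-path enumeration
brute_betweenness <- function(w, lengths) {
  n <- nrow(w)
  credit <- stats::setNames(numeric(n), rownames(w))
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(to))
    out <- list()
    for (nb in which(w[from, ] > 0)) {
      if (nb %in% visited) next
      for (p in all_paths(nb, to, c(visited, nb))) {
        out[[length(out) + 1L]] <- c(from, p)
      }
    }
    out
  }
  path_len <- function(p) {
    sum(vapply(seq_len(length(p) - 1L),
               function(i) lengths[p[i], p[i + 1L]], numeric(1)))
  }
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_paths(s, t, s)
      if (length(paths) == 0L) next
      lens <- vapply(paths, path_len, numeric(1))
      shortest <- paths[abs(lens - min(lens)) < 1e-9]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        credit[interior] <- credit[interior] + 1 / length(shortest)
      }
    }
  }
  credit
}

# leading eigenvector of a small covariance matrix by longhand power iteration
power_iteration_pc1 <- function(m, iters = 5000L) {
  v <- rep(1, nrow(m)) / sqrt(nrow(m))
  for (i in seq_len(iters)) {
    v_new <- m %*% v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < 1e-14) break
    v <- as.numeric(v_new)
  }
  as.numeric(v)
}

# longhand chi-square for a 2x2 table
longhand_chisq <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# exact two-sided Mann-Whitney p by enumeration of group assignments,
# written independently of the package implementation
enumerate_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- ustat(x, y)
  splits <- utils::combn(length(pool), n1)
  us <- apply(splits, 2L, function(i) ustat(pool[i], pool[-i]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# random symmetric weight matrix for small-graph property tests
random_weight_matrix <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  edge <- stats::runif(sum(ut)) < p_edge
  vals <- stats::runif(sum(ut), 0.1, 1)
  w[ut] <- ifelse(edge, vals, 0)
  w <- w + t(w)
  dimnames(w) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  w
}
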