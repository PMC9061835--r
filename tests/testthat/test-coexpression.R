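# Network construction contracts: correlation, signed adjacency, TOM,
# module detection, eigengenes, membership, connectivity, fractions.

toy_expr <- function() {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 5, 9), c = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  m
}

test_that("correlation handles duplicates, negation, and the longhand value", {
  m <- toy_expr()
  cc <- correlate(rbind(m, a2 = m["a", ]))
  expect_equal(cc["a", "a2"], 1)
  expect_equal(cc["a", "c"], -1)
  # frozen from the longhand Pearson formula: 11 / sqrt(130)
  expect_equal(cc["a", "b"], 11 / sqrt(130), tolerance = 1e-12)
  expect_equal(cc["a", "b"], 0.96476382, tolerance = 1e-7)
  expect_error(correlate(m[, 1:2]), ">= 3 samples")
  expect_warning(cc2 <- correlate(rbind(m, flat = rep(5, 4))), "zero-variance")
  expect_false("flat" %in% rownames(cc2))
  expect_error(suppressWarnings(correlate(matrix(3, 2, 4,
    dimnames = list(c("x", "y"), paste0("s", 1:4))))), "zero variance")
})

test_that("signed adjacency follows the closed form and is monotone in r", {
  r <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(signed_adjacency(r, 6)["a", "b"], 0.5^6)
  grid <- seq(-1, 1, by = 0.05)
  for (beta in c(1L, 6L, 12L)) {
    a <- ((1 + grid) / 2)^beta
    expect_true(all(diff(a) >= 0))
    expect_equal(a[1L], 0)
    expect_equal(a[length(a)], 1)
  }
})

test_that("soft threshold selection matches a longhand scale-free regression", {
  sim <- ref_sim()
  cm <- ref_network()$cor[1:120, 1:120]
  sel <- suppressWarnings(select_soft_threshold(cm, network_config(beta_candidates = c(2L, 6L))))
  # oracle: recompute the binned log-log regression for beta = 6 longhand
  a <- signed_adjacency(cm, 6L)
  k <- rowSums(a)
  breaks <- seq(min(k), max(k), length.out = 11L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  counts <- tabulate(bin, 10L)
  kmean <- tapply(k, bin, mean)
  keep <- counts > 0 & kmean > 0
  fit <- stats::lm(log10(counts[keep] / sum(counts)) ~ log10(kmean[keep]))
  expect_equal(sel$fits$r2[sel$fits$beta == 6L], summary(fit)$r.squared,
               tolerance = 1e-10)
  # determinism of the selection
  sel2 <- suppressWarnings(select_soft_threshold(cm, network_config(beta_candidates = c(2L, 6L))))
  expect_identical(sel$beta, sel2$beta)
  # degenerate all-identical network falls back with a warning
  ones <- matrix(1, 25, 25, dimnames = list(paste0("g", 1:25), paste0("g", 1:25)))
  expect_warning(s3 <- select_soft_threshold(ones, network_config(beta_candidates = 1:4)),
                 "largest candidate")
  expect_identical(s3$beta, 4L)
})

test_that("TOM matches hand-evaluated cases and is bounded on random adjacencies", {
  nm <- function(m) { dimnames(m) <- list(paste0("g", 1:nrow(m)), paste0("g", 1:nrow(m))); m }
  # complete graph, all weights 1
  a <- nm(matrix(1, 4, 4)); diag(a) <- 0
  tom <- topological_overlap(a)
  expect_true(all(abs(tom - 1) < 1e-12))
  # isolated pair
  a <- nm(matrix(0, 4, 4)); a[1, 2] <- a[2, 1] <- 0.5
  expect_equal(topological_overlap(a)[1, 2], 0.5)
  # triangle
  a <- nm(matrix(0, 3, 3)); a[upper.tri(a)] <- 0.5; a <- a + t(a)
  expect_equal(topological_overlap(a)[1, 2], 0.75 / 1.5)
  # property: bounds and symmetry on random adjacency matrices
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:12, 1L)
    r <- matrix(stats::runif(n * n, -1, 1), n)
    r <- (r + t(r)) / 2; diag(r) <- 1
    dimnames(r) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tom <- topological_overlap(signed_adjacency(r, 6L))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_lt(max(abs(tom - t(tom))), 1e-12)
  }
})

test_that("module detection separates constructed blocks and respects min size", {
  set.seed(4)
  e1 <- stats::rnorm(30); e2 <- stats::rnorm(30)
  x <- rbind(t(replicate(12, e1 + stats::rnorm(30, sd = 1e-3))),
             t(replicate(12, e2 + stats::rnorm(30, sd = 1e-3))))
  dimnames(x) <- list(sprintf("g%02d", 1:24), sprintf("s%02d", 1:30))
  tom <- topological_overlap(signed_adjacency(correlate(x), 6L))
  part <- detect_modules(tom, x, network_config(min_module_size = 5L))
  truth <- rep(1:2, each = 12L)
  expect_equal(adjusted_rand_index(part$labels, truth), 1)
  expect_identical(length(unique(part$labels)), 2L)
  # min_module_size larger than n: everything unassigned
  part0 <- detect_modules(tom, x, network_config(min_module_size = 50L))
  expect_true(all(part0$labels == 0L))
})

test_that("planted three-module simulation is recovered with high ARI", {
  sim <- ref_sim()
  part <- ref_network()$part
  ari <- adjusted_rand_index(part$labels, sim$truth$module)
  expect_gte(ari, 0.9)
  # cross-check the in-package ARI against the mclust oracle
  expect_equal(ari, mclust::adjustedRandIndex(part$labels, sim$truth$module),
               tolerance = 1e-12)
  # determinism: full rerun gives the identical partition and ME table
  cm <- correlate(sim$expr)
  adj <- signed_adjacency(cm, network_config()$soft_power)
  tom <- topological_overlap(adj)
  part2 <- detect_modules(tom, sim$expr, network_config(min_module_size = 10L))
  expect_identical(part$labels, part2$labels)
  expect_identical(ref_network()$me$me, eigengenes(sim$expr, part2$labels)$me)
})

test_that("eigengenes match a power-iteration oracle and orient to members", {
  set.seed(8)
  x <- rbind(g1 = stats::rnorm(20), g2 = stats::rnorm(20), g3 = stats::rnorm(20))
  x[2, ] <- x[1, ] * 0.8 + stats::rnorm(20, sd = 0.3)
  x[3, ] <- x[1, ] * 0.6 + stats::rnorm(20, sd = 0.3)
  colnames(x) <- paste0("s", 1:20)
  labels <- stats::setNames(rep(1L, 3L), rownames(x))
  me <- eigengenes(x, labels)
  # oracle: leading eigenvector of the sample-sample covariance via power iteration
  xs <- t(scale(t(x)))
  pc <- power_iteration_pc1(t(xs) %*% xs)
  pc <- pc / sqrt(sum(pc^2))
  if (stats::cor(pc, x[1, ]) < 0) pc <- -pc
  expect_equal(unname(me$me[1, ]), pc, tolerance = 1e-8)
  expect_equal(sum(me$me[1, ]^2), 1, tolerance = 1e-12)
  # orientation: mean member correlation is positive, and flips with members
  expect_gt(mean(stats::cor(me$me[1, ], t(x))), 0)
  me_flip <- eigengenes(-x, labels)
  expect_equal(unname(me_flip$me[1, ]), -unname(me$me[1, ]), tolerance = 1e-8)
  # identical genes: |cor(ME, gene)| = 1
  xx <- rbind(a = x[1, ], b = x[1, ])
  me2 <- eigengenes(xx, stats::setNames(c(1L, 1L), c("a", "b")))
  expect_equal(abs(stats::cor(me2$me[1, ], x[1, ])), 1, tolerance = 1e-12)
  expect_gt(stats::cor(me2$me[1, ], x[1, ]), 0)
})

test_that("eigengene variance explained beats random unit vectors on small modules", {
  sim <- ref_sim()
  labels <- sim$truth$module
  genes <- names(labels)[labels == 2L][1:8]
  x <- sim$expr[genes, ]
  me <- eigengenes(x, stats::setNames(rep(1L, 8L), genes))
  xs <- t(scale(t(x)))
  var_of <- function(v) sum((xs %*% v)^2)
  best <- var_of(as.numeric(me$me[1, ]))
  set.seed(21)
  for (i in 1:1000) {
    v <- stats::rnorm(ncol(x)); v <- v / sqrt(sum(v^2))
    expect_lte(var_of(v), best + 1e-9)
  }
})

test_that("kME membership reproduces the t-distribution oracle", {
  sim <- ref_sim()
  net <- ref_network()
  mm <- module_membership(sim$expr[1:40, ], net$me)
  expect_true(all(mm$kme >= -1 & mm$kme <= 1))
  expect_true(all(mm$q >= mm$p - 1e-15))
  # r = 0.5 at n = 100: t = 5.7155, p = 1.18e-7
  expect_equal(cor_t_pvalue(0.5, 100L), 1.180492e-07, tolerance = 1e-5)
  # gene identical to the ME
  x <- rbind(hit = net$me$me[1, ], other = sim$expr[200, ])
  mm2 <- module_membership(x, net$me)
  expect_equal(mm2$kme[mm2$gene == "hit" & mm2$module == "M1"], 1, tolerance = 1e-9)
  expect_lt(mm2$p[mm2$gene == "hit" & mm2$module == "M1"], 1e-200)
  expect_error(module_membership(sim$expr[1:5, 1:3], net$me), ">= 4")
})

test_that("connectivity decomposes into within and out parts", {
  nm <- c("a", "b", "c", "d", "e")
  a <- matrix(0, 5, 5, dimnames = list(nm, nm))
  a["a", c("b", "c", "d", "e")] <- 0.2
  a[c("b", "c", "d", "e"), "a"] <- 0.2
  labels <- stats::setNames(c(1L, 1L, 1L, 2L, 0L), nm)
  ct <- connectivity(a, labels)
  hub <- ct[ct$gene == "a", ]
  expect_equal(hub$kTotal, 0.8)
  expect_equal(hub$kWithin, 0.4)
  expect_equal(hub$kOut, 0.4)
  expect_equal(ct$kWithin[ct$gene == "e"], 0)  # unassigned convention
  expect_true(all(abs(ct$kTotal - ct$kWithin - ct$kOut) < 1e-9))
  # complete graph: kTotal = kWithin = n - 1
  a1 <- matrix(1, 5, 5, dimnames = list(nm, nm)); diag(a1) <- 0
  ct1 <- connectivity(a1, stats::setNames(rep(1L, 5L), nm))
  expect_true(all(ct1$kTotal == 4 & ct1$kWithin == 4 & ct1$kOut == 0))
})

test_that("module fractions are simplex-valued and classify by threshold", {
  me <- ref_network()$me
  fr <- module_fractions(me)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(unname(colSums(fr)), rep(1, ncol(fr)), tolerance = 1e-12)
  # two-module arithmetic case: shifted values (0.2, 0.6) -> (0.25, 0.75)
  m <- rbind(M1 = c(0, 0.2), M2 = c(0, 0.6))
  colnames(m) <- c("smin", "s1")
  expect_equal(unname(module_fractions(m)[, "s1"]), c(0.25, 0.75))
  # single module: fraction 1 everywhere
  m1 <- matrix(stats::rnorm(5), 1, dimnames = list("M1", paste0("s", 1:5)))
  expect_true(all(module_fractions(m1) == 1))
  cls <- classify_module_high(fr, 0.33)
  expect_type(cls, "logical")
  expect_identical(dim(cls), dim(fr))
})
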