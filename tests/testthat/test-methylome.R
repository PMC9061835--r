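# Probe filtering, MAD normalization, promoter summaries, ME-promoter
# correlation, cluster/silhouette, and regional association.

tiny_ann <- function(probes, region = "TSS200", gene = "G1") {
  data.frame(probe_id = probes, chrom = "chr1",
             pos = seq_along(probes), gene = gene,
             region_group = region, cgi_relation = "Island",
             flag_xy = 0L, flag_multimap = 0L, flag_snp = 0L, flag_noncg = 0L,
             flag_solowcpgw = 0L, stringsAsFactors = FALSE)
}

test_that("probe filtering removes flag unions with a per-reason report", {
  probes <- sprintf("cg%03d", 1:100)
  ann <- tiny_ann(probes)
  ann$flag_xy[1:10] <- 1L
  ann$flag_snp[9:13] <- 1L  # 2 overlap the XY set
  beta <- matrix(stats::runif(100 * 4), 100, 4,
                 dimnames = list(probes, paste0("s", 1:4)))
  res <- filter_probes(beta, ann)
  expect_identical(nrow(res$beta), 87L)
  expect_identical(unname(res$report["flag_xy"]), 10L)
  expect_identical(unname(res$report["flag_snp"]), 5L)
  expect_identical(unname(res$report["removed"]), 13L)
  # no flags: identity; all flags: empty
  res0 <- filter_probes(beta, tiny_ann(probes))
  expect_identical(res0$beta, beta)
  ann_all <- tiny_ann(probes); ann_all$flag_noncg <- 1L
  expect_identical(nrow(filter_probes(beta, ann_all)$beta), 0L)
  expect_error(filter_probes(beta, ann[-1, ]), "unannotated")
})

test_that("MAD normalization matches the worked example and its invariances", {
  b <- rbind(p1 = c(0.2, 0.4, 0.6), p2 = c(0.8, 0.8, 0.8))
  colnames(b) <- paste0("s", 1:3)
  ann <- tiny_ann(rownames(b))
  norm <- promoter_mad_normalize(b, ann)
  expect_equal(unname(attr(norm, "sample_reference")), c(0.5, 0.6, 0.7))
  expect_equal(unname(norm["p1", ]), c(0.4, 0.6, 0.8))
  expect_equal(unname(norm["p2", ]), c(0.6, 0.6, 0.6))
  # single promoter probe: reference equals the probe, offset 0, identity
  b1 <- b["p1", , drop = FALSE]
  n1 <- promoter_mad_normalize(b1, ann)
  expect_equal(as.numeric(n1), as.numeric(b1))
  # location invariance: shifting a non-median probe moves only its offset
  b3 <- rbind(p1 = c(0.1, 0.2, 0.3), p2 = c(0.4, 0.5, 0.6), p3 = c(0.7, 0.8, 0.9))
  colnames(b3) <- paste0("s", 1:3)
  ann3 <- tiny_ann(rownames(b3))
  n_base <- promoter_mad_normalize(b3, ann3)
  b3_shift <- b3; b3_shift["p3", ] <- b3_shift["p3", ] + 0.05
  n_shift <- promoter_mad_normalize(b3_shift, ann3)
  expect_equal(as.numeric(n_shift), as.numeric(n_base), tolerance = 1e-12)
  expect_equal(attr(n_shift, "probe_offset")[["p3"]],
               attr(n_base, "probe_offset")[["p3"]] + 0.05, tolerance = 1e-12)
  # idempotent on additive probe + sample structure
  set.seed(18)
  base <- sample(c(0.1, 0.8), 15, TRUE)
  samp <- stats::rnorm(11, sd = 0.1)
  bb <- outer(base, rep(1, 11)) + outer(rep(1, 15), samp)
  dimnames(bb) <- list(sprintf("p%02d", 1:15), sprintf("s%02d", 1:11))
  nn <- promoter_mad_normalize(bb, tiny_ann(rownames(bb)))
  nn2 <- promoter_mad_normalize(unclass(nn), tiny_ann(rownames(bb)))
  expect_equal(as.numeric(nn2), as.numeric(nn), tolerance = 1e-12)
  expect_equal(unname(attr(nn2, "probe_offset")), rep(0, 15), tolerance = 1e-12)
  expect_error(promoter_mad_normalize(b, tiny_ann(rownames(b), region = "Body")),
               "no promoter")
})

test_that("gene promoter summaries enforce both missingness filters", {
  probes <- sprintf("cg%02d", 1:30)
  genes <- c(rep("G01", 3L), rep("G02", 2L), rep(sprintf("G%02d", 3:9), each = 3L),
             rep("G10", 4L))
  ann <- tiny_ann(probes, gene = genes)
  set.seed(22)
  norm <- matrix(stats::runif(30 * 50), 30, 50,
                 dimnames = list(probes, sprintf("s%02d", 1:50)))
  # G01: all 3 probes carry missing values -> dropped (> 2 missing probes)
  norm[1:3, 5] <- NA
  # G02: both probes missing in 2 of 50 samples (4% > 2%) -> dropped
  norm[4:5, 1:2] <- NA
  res <- summarize_gene_promoters(norm, ann)
  expect_identical(nrow(res$profile), 8L)
  expect_identical(sort(res$dropped$gene), c("G01", "G02"))
  expect_identical(res$dropped$reason[res$dropped$gene == "G01"], "missing_probes")
  expect_identical(res$dropped$reason[res$dropped$gene == "G02"], "missing_samples")
  # retained gene equals its probe mean
  g3 <- ann$probe_id[ann$gene == "G03"]
  expect_equal(unname(res$profile["G03", ]), unname(colMeans(norm[g3, ])))
  expect_identical(unname(res$probe_count["G03"]), 3L)
})

test_that("ME-promoter correlation hits exact endpoints and the null band", {
  sim <- ref_sim()
  me <- ref_network()$me
  # profile equal to -ME of module 1 gives column value -1
  prof <- rbind(anti = -me$me["M1", ], noise = stats::rnorm(120))
  colnames(prof) <- colnames(me$me)
  cm <- me_promoter_correlation(me, prof)
  expect_equal(cm["anti", "M1"], -1)
  expect_error(me_promoter_correlation(me, prof[, 1:5]), ">= 8")
  # permuted sample labels: null calibration, 95% of |rho| < 2/sqrt(n)
  filt <- filter_probes(sim$beta, sim$annotation)
  norm <- promoter_mad_normalize(filt$beta, sim$annotation)
  prof_full <- summarize_gene_promoters(norm, sim$annotation)$profile
  set.seed(40)
  perm <- prof_full[1:150, sample(ncol(prof_full))]
  colnames(perm) <- colnames(prof_full)
  cm_perm <- me_promoter_correlation(me, perm)
  expect_gte(mean(abs(cm_perm) < 2 / sqrt(120)), 0.95)
})

test_that("planted promoter coupling is recovered at the planted strength", {
  sim <- ref_sim()
  filt <- filter_probes(sim$beta, sim$annotation)
  norm <- promoter_mad_normalize(filt$beta, sim$annotation)
  prof <- summarize_gene_promoters(norm, sim$annotation)
  cm <- me_promoter_correlation(list(me = rbind(M1 = recovered_me_row(1L))), prof)
  coupled <- intersect(sim$truth$coupled_genes$gene, rownames(cm))
  expect_lt(abs(mean(cm[coupled, "M1"]) - (-0.6)), 0.15)
})

test_that("correlation-profile clustering separates planted blocks", {
  set.seed(26)
  block <- rbind(matrix(stats::rnorm(20 * 3, mean = -0.7, sd = 0.05), 20),
                 matrix(stats::rnorm(20 * 3, mean = 0.4, sd = 0.05), 20))
  dimnames(block) <- list(sprintf("G%02d", 1:40), c("M1", "M2", "M3"))
  cl <- cluster_correlation_profiles(block, k = 2L)
  expect_equal(adjusted_rand_index(cl$labels, rep(1:2, each = 20L)), 1)
  expect_gt(mean(cl$silhouette), 0.5)
  # degenerate identical rows: silhouette defined as 0
  same <- matrix(0.3, 5, 3, dimnames = list(paste0("g", 1:5), paste0("M", 1:3)))
  cl0 <- cluster_correlation_profiles(same, k = 2L)
  expect_true(all(cl0$silhouette == 0))
  expect_error(cluster_correlation_profiles(block, k = 100L), "k exceeds")
})

test_that("hypomethylation-coupled cluster is enriched for planted hubs", {
  sim <- ref_sim()
  filt <- filter_probes(sim$beta, sim$annotation)
  norm <- promoter_mad_normalize(filt$beta, sim$annotation)
  prof <- summarize_gene_promoters(norm, sim$annotation)
  cm <- me_promoter_correlation(ref_network()$me, prof)
  cl <- cluster_correlation_profiles(cm, k = 3L)
  rec_col <- sprintf("M%d", recovered_module(1L))
  means <- tapply(cm[, rec_col], cl$labels, mean)
  hypo <- names(means)[which.min(means)]
  hypo_genes <- names(cl$labels)[cl$labels == as.integer(hypo)]
  m1 <- names(sim$truth$module)[sim$truth$module == 1L]
  ot <- overlap_test(hypo_genes, m1, nrow(cm))
  expect_lt(ot$p_chisq, 0.05)
  expect_gt(length(ot$overlap) / length(hypo_genes),
            length(m1) / nrow(cm))
})

test_that("regional association flags shore promoters, spares solo-WCpGW, nulls permute away", {
  sim <- ref_sim()
  filt <- filter_probes(sim$beta, sim$annotation)
  e <- sim$truth$eigengenes[1L, ]
  assoc <- region_category_association(e, filt$beta, sim$annotation)
  obs <- assoc[!is.na(assoc$rho), ]
  top <- obs[which.min(obs$rho), ]
  expect_identical(top$cgi_relation, "Shore")
  expect_true(top$region_group %in% c("TSS1500", "TSS200", "5UTR"))
  expect_lt(abs(obs$rho[obs$category == "solo_WCpGW"]), 0.2)
  expect_true(top$flagged)
  # permuted eigengene: nothing flagged at q < 1e-7
  set.seed(44)
  e_perm <- stats::setNames(sample(e), names(e))
  assoc_perm <- region_category_association(e_perm, filt$beta, sim$annotation)
  expect_false(any(assoc_perm$flagged))
})

test_that("category association strengthens monotonically with planted coupling", {
  rhos <- vapply(c(0, 1, 2, 4), function(cc) {
    cfg <- sim_config(seed = 6L, meth = meth_spec(coupling_strength = cc))
    ex <- generate_expression(cfg)
    me <- generate_methylation(cfg, ex$truth)
    sel <- me$annotation$cgi_relation == "Shore" &
      me$annotation$region_group %in% c("TSS1500", "TSS200", "5UTR")
    v <- colMeans(me$beta[sel, , drop = FALSE])
    spearman_assoc(v, ex$truth$eigengenes[1L, ])$rho
  }, numeric(1))
  expect_true(all(diff(rhos) < 0))
})

test_that("coupled module is the unique module with genome-wide promoter anti-correlation", {
  sim <- ref_sim()
  filt <- filter_probes(sim$beta, sim$annotation)
  norm <- promoter_mad_normalize(filt$beta, sim$annotation)
  prof <- summarize_gene_promoters(norm, sim$annotation)
  cm <- me_promoter_correlation(ref_network()$me, prof)
  rec_col <- sprintf("M%d", recovered_module(1L))
  col_means <- colMeans(cm, na.rm = TRUE)
  expect_identical(names(which.min(col_means)), rec_col)
  expect_lt(col_means[rec_col], -0.05)
  expect_true(all(abs(col_means[setdiff(names(col_means), rec_col)]) <
                    abs(col_means[rec_col])))
})
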