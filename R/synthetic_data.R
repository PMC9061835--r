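# Seeded synthetic-cohort generator. A latent-factor model plants the
# statistical structure the downstream analysis assumes: modular expression
# with hub gradients, bimodal promoter methylation anti-correlated with one
# module's latent eigengene (strongest at CGI shores), integer copy-number
# calls partly coupled to that eigengene and to their own gene's expression,
# and genesets overlapping the planted module. Ground truth is returned for
# parameter-recovery tests.

#' Methylation layer specification
#'
#' Coupled-gene probes follow `beta = plogis(b0 - c * e_S + eta)` where `e_S`
#' is the latent eigengene of `coupled_module`; all other probes drop the
#' coupling term. `b0` is drawn from two logit intercept modes, giving the
#' genome-wide bimodal beta-value distribution.
#'
#' @param probes_per_gene Promoter probes simulated per gene (1-6).
#' @param coupled_gene_fraction Fraction of the coupled module's genes whose
#'   promoters are methylation-coupled.
#' @param coupling_strength Logit-scale coupling coefficient `c >= 0`; the
#'   anti-correlation sign is encoded in the model, not the parameter.
#' @param coupled_module Index of the module whose eigengene drives coupling.
#' @param shore_fraction Probability that a coupled probe is annotated as a
#'   CGI shore (the remainder fall in islands).
#' @param baseline_modes Two logit intercepts for the unmethylated and
#'   methylated baseline modes.
#' @param noise_sd_logit Logit-scale probe noise sd. The default is calibrated
#'   so that, at `coupling_strength = 4` with 3 probes per gene, the planted
#'   gene-level promoter/eigengene Spearman correlation is about -0.6.
#' @param flag_rates Named rates for the four exclusion flags
#'   (`xy`, `multimap`, `snp`, `noncg`).
#' @param solo_fraction Fraction of uncoupled non-promoter probes flagged as
#'   solo-WCpGW (late-replicating loci; uncoupled by construction).
#' @param na_fraction Fraction of beta values set missing (pre-filter
#'   missingness).
#' @return A list of class `meth_spec`.
#' @export
meth_spec <- function(probes_per_gene = 3L,
                      coupled_gene_fraction = 0.5,
                      coupling_strength = 4,
                      coupled_module = 1L,
                      shore_fraction = 0.7,
                      baseline_modes = c(-2, 2),
                      noise_sd_logit = 7,
                      flag_rates = c(xy = 0.03, multimap = 0.03, snp = 0.03, noncg = 0.01),
                      solo_fraction = 0.1,
                      na_fraction = 0) {
  stopifnot(probes_per_gene >= 1L, probes_per_gene <= 6L,
            coupled_gene_fraction >= 0, coupled_gene_fraction <= 1,
            shore_fraction >= 0, shore_fraction <= 1,
            length(baseline_modes) == 2L, noise_sd_logit >= 0)
  structure(list(probes_per_gene = as.integer(probes_per_gene),
                 coupled_gene_fraction = coupled_gene_fraction,
                 coupling_strength = coupling_strength,
                 coupled_module = as.integer(coupled_module),
                 shore_fraction = shore_fraction,
                 baseline_modes = baseline_modes,
                 noise_sd_logit = noise_sd_logit,
                 flag_rates = flag_rates,
                 solo_fraction = solo_fraction,
                 na_fraction = na_fraction),
            class = "meth_spec")
}

#' Copy-number layer specification
#'
#' Driver genes receive `cn = round(clip(sign * gamma * e_S + zeta, -2, 2))`
#' and their expression rows gain an additive `delta * cn` term; non-drivers
#' get integer calls independent of the eigengene.
#'
#' @param n_drivers Number of planted driver genes.
#' @param gamma Coupling of driver CN to the focal eigengene.
#' @param delta Additive effect of a driver's CN on its own expression.
#' @param gain_fraction Fraction of drivers planted as gains (the rest are
#'   losses, i.e. negative coupling).
#' @param latent_sd Gaussian sd of the driver CN latent before rounding.
#' @param background_sd Gaussian sd of the non-driver CN latent.
#' @return A list of class `cn_spec`.
#' @export
cn_spec <- function(n_drivers = 20L, gamma = 1.5, delta = 0.8,
                    gain_fraction = 0.7, latent_sd = 0.5, background_sd = 0.7) {
  stopifnot(n_drivers >= 0L, latent_sd >= 0, background_sd >= 0,
            gain_fraction >= 0, gain_fraction <= 1)
  structure(list(n_drivers = as.integer(n_drivers), gamma = gamma, delta = delta,
                 gain_fraction = gain_fraction, latent_sd = latent_sd,
                 background_sd = background_sd),
            class = "cn_spec")
}

#' Geneset layer specification
#'
#' @param size Geneset size.
#' @param module_overlap_fraction Fraction of the set drawn from the coupled
#'   module (`round(fraction * size)`, capped at the module size).
#' @return A list of class `geneset_spec`.
#' @export
geneset_spec <- function(size = 200L, module_overlap_fraction = 0.25) {
  stopifnot(size >= 1L, module_overlap_fraction >= 0)
  if (module_overlap_fraction > 1) stop("module_overlap_fraction must be <= 1")
  structure(list(size = as.integer(size),
                 module_overlap_fraction = module_overlap_fraction),
            class = "geneset_spec")
}

#' Simulation configuration
#'
#' The defaults are the reference study conditions used throughout the test
#' suite: three modules of 50 genes with loadings in `[0.6, 0.95]` and noise
#' sd 0.6, 200 background genes, and 120 samples.
#'
#' @param seed Master seed; one hierarchical sub-stream per generator.
#' @param n_samples Number of samples.
#' @param modules List of module specs, each `list(size, loading_range,
#'   noise_sd)`.
#' @param n_background Number of unstructured background genes.
#' @param meth A [meth_spec()].
#' @param cn A [cn_spec()].
#' @param genesets A [geneset_spec()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 120L,
                       modules = rep(list(list(size = 50L,
                                               loading_range = c(0.6, 0.95),
                                               noise_sd = 0.6)), 3L),
                       n_background = 200L,
                       meth = meth_spec(),
                       cn = cn_spec(),
                       genesets = geneset_spec()) {
  cfg <- structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                        modules = modules, n_background = as.integer(n_background),
                        meth = meth, cn = cn, genesets = genesets),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 0L || config$n_background < 0L) {
    stop("counts must be >= 0")
  }
  for (m in config$modules) {
    lr <- m$loading_range
    stopifnot(length(lr) == 2L, lr[1] <= lr[2])
    if (any(lr <= 0) || any(lr > 1)) stop("loading_range must lie in (0, 1]")
    if (m$size == 0L && any(lr > 0)) {
      stop("module size 0 with a nonzero loading range is a configuration error")
    }
    if (m$noise_sd < 0) stop("noise_sd must be >= 0")
  }
  if (config$meth$coupling_strength > 0) {
    size_s <- config$modules[[config$meth$coupled_module]]$size
    if (config$meth$coupled_gene_fraction * size_s < 1) {
      stop("coupled_gene_fraction * module size must be >= 1 when coupling_strength > 0")
    }
  }
  invisible(config)
}

#' Generate modular expression data with planted hub gradients
#'
#' For gene g in module m, `x_gs = w_g * e_ms + eps` with
#' `eps ~ Normal(0, noise_sd)` and `w_g ~ Uniform(loading_range)`, so
#' high-loading genes are planted hubs. Background genes are pure
#' `Normal(0, 1)`. Latent eigengenes are standardized to zero mean and unit
#' variance per module.
#'
#' @param config A [sim_config()].
#' @return A list with `expr` (genes x samples matrix) and `truth` (module
#'   labels with 0 = background, loadings, latent eigengene matrix).
#' @export
generate_expression <- function(config) {
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, 1L))
  nmod <- length(config$modules)
  sizes <- vapply(config$modules, function(m) as.integer(m$size), integer(1))
  n_genes <- sum(sizes) + config$n_background
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  labels <- c(rep(seq_len(nmod), sizes), rep(0L, config$n_background))
  names(labels) <- genes

  e <- matrix(stats::rnorm(nmod * config$n_samples), nrow = nmod)
  e <- t(scale(t(e)))  # zero mean, unit variance per module
  dimnames(e) <- list(sprintf("M%d", seq_len(nmod)), samples)

  loadings <- rep(NA_real_, n_genes)
  names(loadings) <- genes
  x <- matrix(0, nrow = n_genes, ncol = config$n_samples,
              dimnames = list(genes, samples))
  row <- 1L
  for (m in seq_len(nmod)) {
    spec <- config$modules[[m]]
    if (spec$size == 0L) next
    w <- stats::runif(spec$size, spec$loading_range[1], spec$loading_range[2])
    idx <- row:(row + spec$size - 1L)
    loadings[idx] <- w
    noise <- matrix(stats::rnorm(spec$size * config$n_samples, sd = spec$noise_sd),
                    nrow = spec$size)
    x[idx, ] <- outer(w, e[m, ]) + noise
    row <- row + spec$size
  }
  if (config$n_background > 0L) {
    idx <- (sum(sizes) + 1L):n_genes
    x[idx, ] <- matrix(stats::rnorm(config$n_background * config$n_samples),
                       nrow = config$n_background)
  }
  truth <- list(module = labels, loadings = loadings, eigengenes = e,
                coupled_genes = NULL, drivers = NULL, genesets = NULL,
                seed = config$seed)
  list(expr = x, truth = truth)
}

REGION_GROUPS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR", "IGR")
CGI_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
PROMOTER_GROUPS <- c("TSS1500", "TSS200", "5UTR")

#' Generate bimodal promoter methylation coupled to one module's eigengene
#'
#' Probes of coupled genes follow `beta = plogis(b0 - c * e_S + eta)`; all
#' other probes `beta = plogis(b0 + eta)`. Intercepts `b0` are drawn from the
#' two baseline modes (unmethylated for promoter probes, methylated elsewhere,
#' each with 80% probability), giving a bimodal genome-wide distribution.
#' Coupled probes are promoter probes annotated as CGI shores with probability
#' `shore_fraction` (islands otherwise); solo-WCpGW flags are confined to
#' uncoupled non-promoter probes.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [generate_expression()].
#' @return A list with `beta` (probes x samples), `annotation` (probe
#'   annotation data frame), and the updated `truth` (coupled genes with
#'   planted sign -1).
#' @export
generate_methylation <- function(config, truth) {
  ms <- config$meth
  if (ms$coupling_strength < 0) {
    stop("coupling_strength must be >= 0; the anti-correlation sign is encoded in the model")
  }
  stopifnot(!is.null(truth$eigengenes))
  set.seed(sub_seed(config$seed, 2L))
  genes <- names(truth$module)
  samples <- colnames(truth$eigengenes)
  e_s <- truth$eigengenes[ms$coupled_module, ]

  module_genes <- genes[truth$module == ms$coupled_module]
  n_coupled <- round(ms$coupled_gene_fraction * length(module_genes))
  coupled_genes <- if (n_coupled > 0L) sort(sample(module_genes, n_coupled)) else character(0)

  k <- ms$probes_per_gene
  probe_gene <- rep(genes, each = k)
  n_probes <- length(probe_gene)
  probe_id <- sprintf("cg%06d", seq_len(n_probes))
  coupled_probe <- probe_gene %in% coupled_genes

  region_group <- character(n_probes)
  cgi_relation <- character(n_probes)
  nc <- sum(coupled_probe)
  region_group[coupled_probe] <- sample(PROMOTER_GROUPS, nc, replace = TRUE,
                                        prob = c(0.40, 0.35, 0.25))
  cgi_relation[coupled_probe] <- ifelse(stats::runif(nc) < ms$shore_fraction,
                                        "Shore", "Island")
  nu <- n_probes - nc
  region_group[!coupled_probe] <- sample(REGION_GROUPS, nu, replace = TRUE,
                                         prob = c(0.12, 0.10, 0.08, 0.05, 0.35, 0.10, 0.20))
  cgi_relation[!coupled_probe] <- sample(CGI_RELATIONS, nu, replace = TRUE,
                                         prob = c(0.30, 0.25, 0.15, 0.30))

  promoter <- region_group %in% PROMOTER_GROUPS
  low_mode <- ifelse(promoter, stats::runif(n_probes) < 0.8, stats::runif(n_probes) < 0.2)
  b0 <- ifelse(low_mode, ms$baseline_modes[1], ms$baseline_modes[2]) +
    stats::rnorm(n_probes, sd = 0.25)

  flags <- sapply(c("xy", "multimap", "snp", "noncg"), function(f) {
    as.integer(stats::runif(n_probes) < ms$flag_rates[[f]])
  })
  solo <- integer(n_probes)
  solo_pool <- which(!coupled_probe & !promoter)
  n_solo <- round(ms$solo_fraction * length(solo_pool))
  if (n_solo > 0L) solo[sample(solo_pool, n_solo)] <- 1L

  chrom <- paste0("chr", sample(1:22, n_probes, replace = TRUE))
  chrom[flags[, "xy"] == 1L] <- sample(c("chrX", "chrY"), sum(flags[, "xy"]),
                                       replace = TRUE, prob = c(0.8, 0.2))
  annotation <- data.frame(probe_id = probe_id, chrom = chrom,
                           pos = seq_len(n_probes) * 997L + 10000L,
                           gene = probe_gene, region_group = region_group,
                           cgi_relation = cgi_relation,
                           flag_xy = flags[, "xy"], flag_multimap = flags[, "multimap"],
                           flag_snp = flags[, "snp"], flag_noncg = flags[, "noncg"],
                           flag_solowcpgw = solo, stringsAsFactors = FALSE)

  eta <- matrix(stats::rnorm(n_probes * length(samples), sd = ms$noise_sd_logit),
                nrow = n_probes)
  lin <- b0 + eta
  if (any(coupled_probe)) {
    lin[coupled_probe, ] <- lin[coupled_probe, , drop = FALSE] -
      ms$coupling_strength * matrix(e_s, nrow = sum(coupled_probe),
                                    ncol = length(samples), byrow = TRUE)
  }
  beta <- stats::plogis(lin)
  dimnames(beta) <- list(probe_id, samples)
  if (ms$na_fraction > 0) {
    nna <- round(ms$na_fraction * length(beta))
    beta[sample(length(beta), nna)] <- NA_real_
  }
  truth$coupled_genes <- if (length(coupled_genes)) {
    data.frame(gene = coupled_genes, sign = -1L, stringsAsFactors = FALSE)
  } else NULL
  list(beta = beta, annotation = annotation, truth = truth)
}

#' Generate GISTIC-style integer copy-number calls with planted drivers
#'
#' Driver genes: `cn = round(clip(sign * gamma * e_S + zeta, -2, 2))`;
#' non-drivers get calls independent of the eigengene. Driver expression rows
#' receive an additive `delta * cn` term; the modified expression matrix is
#' returned alongside.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [generate_expression()].
#' @param expr Expression matrix from [generate_expression()].
#' @return A list with `cn` (integer matrix in -2..2), `expr` (expression with
#'   driver dosage effects applied), and updated `truth` (drivers with planted
#'   direction).
#' @export
generate_copy_number <- function(config, truth, expr) {
  cs <- config$cn
  genes <- rownames(expr)
  if (cs$n_drivers > length(genes)) stop("n_drivers exceeds the number of genes")
  set.seed(sub_seed(config$seed, 3L))
  samples <- colnames(expr)
  e_s <- truth$eigengenes[config$meth$coupled_module, ]

  clip_round <- function(x) as.integer(round(pmin(2, pmax(-2, x))))
  cn <- matrix(clip_round(stats::rnorm(length(genes) * length(samples),
                                       sd = cs$background_sd)),
               nrow = length(genes), dimnames = list(genes, samples))
  drivers <- character(0)
  if (cs$n_drivers > 0L) {
    drivers <- sort(sample(genes, cs$n_drivers))
    sign_g <- ifelse(stats::runif(cs$n_drivers) < cs$gain_fraction, 1, -1)
    for (i in seq_along(drivers)) {
      zeta <- stats::rnorm(length(samples), sd = cs$latent_sd)
      cn[drivers[i], ] <- clip_round(sign_g[i] * cs$gamma * e_s + zeta)
    }
    expr[drivers, ] <- expr[drivers, , drop = FALSE] +
      cs$delta * cn[drivers, , drop = FALSE]
    truth$drivers <- data.frame(gene = drivers,
                                direction = ifelse(sign_g > 0, "gain", "loss"),
                                stringsAsFactors = FALSE)
  } else {
    truth$drivers <- data.frame(gene = character(0), direction = character(0),
                                stringsAsFactors = FALSE)
  }
  list(cn = cn, expr = expr, truth = truth)
}

#' Generate genesets overlapping the planted module
#'
#' One set overlaps the coupled module by `round(fraction * size)` members
#' (capped at the module size), the remainder drawn from non-module genes; a
#' second fully random control set is included.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [generate_expression()].
#' @return A list with `sets` (named list: `planted_set`, `random_set`) and
#'   updated `truth`.
#' @export
generate_genesets <- function(config, truth) {
  gs <- config$genesets
  universe <- names(truth$module)
  if (gs$size > length(universe)) stop("geneset size exceeds the gene universe")
  set.seed(sub_seed(config$seed, 4L))
  module_genes <- universe[truth$module == config$meth$coupled_module]
  n_ov <- min(round(gs$module_overlap_fraction * gs$size), length(module_genes), gs$size)
  planted <- sort(c(sample(module_genes, n_ov),
                    sample(setdiff(universe, module_genes), gs$size - n_ov)))
  random_set <- sort(sample(universe, gs$size))
  sets <- list(planted_set = planted, random_set = random_set)
  truth$genesets <- sets
  list(sets = sets, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Runs the expression, methylation, copy-number and geneset generators under
#' one hierarchically split seed.
#'
#' @param config A [sim_config()].
#' @return A list: `expr` (base expression), `expr_cn` (expression with driver
#'   dosage effects), `beta`, `annotation`, `cn`, `genesets`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  ex <- generate_expression(config)
  me <- generate_methylation(config, ex$truth)
  cn <- generate_copy_number(config, me$truth, ex$expr)
  gs <- generate_genesets(config, cn$truth)
  list(expr = ex$expr, expr_cn = cn$expr, beta = me$beta,
       annotation = me$annotation, cn = cn$cn, genesets = gs$sets,
       truth = gs$truth, config = config)
}

#' Write a simulated cohort to an output directory
#'
#' Emits expression/beta/CN TSVs, probe annotation TSV, genesets GMT, and a
#' JSON truth file; every table carries the seed in its header comment.
#'
#' @param sim Result of [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("seed: %d", sim$config$seed), "generator: modulomics simulate")
  paths <- c(
    expr = write_matrix_tsv(sim$expr, file.path(outdir, "expression.tsv"), hdr, "gene"),
    expr_cn = write_matrix_tsv(sim$expr_cn, file.path(outdir, "expression_cn.tsv"), hdr, "gene"),
    beta = write_matrix_tsv(sim$beta, file.path(outdir, "beta.tsv"), hdr, "probe_id"),
    annotation = write_table_tsv(sim$annotation, file.path(outdir, "probe_annotation.tsv"), hdr),
    cn = write_matrix_tsv(sim$cn, file.path(outdir, "cn.tsv"), hdr, "gene"),
    genesets = write_gmt(sim$genesets, file.path(outdir, "genesets.gmt")),
    truth = local({
      p <- file.path(outdir, "truth.json")
      jsonlite::write_json(list(
        module = as.list(sim$truth$module),
        coupled_genes = sim$truth$coupled_genes,
        drivers = sim$truth$drivers,
        genesets = sim$truth$genesets,
        eigengenes = sim$truth$eigengenes,
        seed = sim$config$seed
      ), p, auto_unbox = TRUE, digits = NA)
      p
    })
  )
  invisible(paths)
}
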