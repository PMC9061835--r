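# Orchestration: sample filtering, stage sequencing, commented-TSV round
# trips, and a reproducibility manifest (input/output digests + seed).

#' Filter samples by a metadata column cutoff
#'
#' Retains samples whose value in `column` is `>= cutoff` (e.g. tumour purity
#' >= 0.6). The retained id set is meant to be applied uniformly to all
#' matrices of a cohort.
#'
#' @param metadata Data frame with a `sample` id column (or row names).
#' @param column Metadata column to threshold.
#' @param cutoff Minimum retained value.
#' @return Character vector of retained sample ids.
#' @export
filter_samples <- function(metadata, column, cutoff) {
  if (!column %in% names(metadata)) stop("missing metadata column: ", column)
  ids <- if ("sample" %in% names(metadata)) metadata$sample else rownames(metadata)
  keep <- !is.na(metadata[[column]]) & metadata[[column]] >= cutoff
  message(sprintf("filter_samples: %d of %d samples retained (%s >= %g)",
                  sum(keep), length(ids), column, cutoff))
  ids[keep]
}

#' Pipeline configuration
#'
#' Collects paths, thresholds and the seed for [run_pipeline()]. Missing
#' optional inputs (`beta`, `cn`, `gmt`, `covariates`, `metadata`) disable
#' the corresponding stages.
#'
#' @param expr Expression TSV path, or NULL to simulate.
#' @param outdir Output directory.
#' @param seed Master seed, recorded in every output header.
#' @param simulate Logical: generate the cohort with [simulate_cohort()]
#'   (then all layers come from the generator).
#' @param beta,annotation,cn,gmt,covariates,metadata Optional input TSV/GMT
#'   paths.
#' @param network A [network_config()].
#' @param focal_module Module label analysed by the metrics/methylome/CN
#'   stages; defaults to the largest module.
#' @param purity_column,purity_cutoff Sample filter applied when `metadata`
#'   is given (defaults: `purity`, 0.6).
#' @param alpha BH threshold for the CN driver gates.
#' @param flag_threshold q mark for region-category association.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr = NULL, outdir = "modulomics_out", seed = 1L,
                            simulate = is.null(expr),
                            beta = NULL, annotation = NULL, cn = NULL,
                            gmt = NULL, covariates = NULL, metadata = NULL,
                            network = network_config(),
                            focal_module = NULL,
                            purity_column = "purity", purity_cutoff = 0.6,
                            alpha = 0.05, flag_threshold = 1e-7) {
  structure(list(expr = expr, outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, beta = beta, annotation = annotation,
                 cn = cn, gmt = gmt, covariates = covariates,
                 metadata = metadata, network = network,
                 focal_module = focal_module, purity_column = purity_column,
                 purity_cutoff = purity_cutoff, alpha = alpha,
                 flag_threshold = flag_threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `network:` keys
#' mirror [network_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("expr", "beta", "annotation", "cn", "gmt", "covariates", "metadata")) {
    if (!is.null(y[[f]]) && !file.exists(y[[f]])) {
      stop("configured input does not exist: ", y[[f]])
    }
  }
  net <- do.call(network_config, y$network %||% list())
  args <- y[setdiff(names(y), "network")]
  do.call(pipeline_config, c(args, list(network = net)))
}

# digest of the scientific configuration; the output directory is excluded so
# that the same analysis written elsewhere reproduces identical file digests
config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config[setdiff(names(config), "outdir")]
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

md5_named <- function(paths) {
  if (length(paths) == 0L) return(list())
  md5 <- tools::md5sum(unlist(paths))
  names(md5) <- names(paths)
  as.list(md5)
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulate -> load -> sample filter -> network ->
#' module metrics -> geneset scoring -> methylome integration -> CN drivers
#' -> covariate association. Every output TSV carries the seed and a config
#' digest in its header comment; the run manifest lists the md5 digest of
#' every input and output, so reruns with the same config reproduce
#' identical digests.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (named list), invisibly; written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  hdr <- c(sprintf("seed: %d", config$seed), sprintf("config: %s", digest))
  outputs <- character(0)
  emit_mat <- function(mat, name, id_name = "id") {
    p <- file.path(config$outdir, name)
    write_matrix_tsv(mat, p, hdr, id_name)
    outputs[[name]] <<- p
  }
  emit_df <- function(df, name) {
    p <- file.path(config$outdir, name)
    write_table_tsv(df, p, hdr)
    outputs[[name]] <<- p
  }

  inputs <- character(0)
  sim <- NULL
  if (isTRUE(config$simulate)) {
    sim <- tryCatch(simulate_cohort(sim_config(seed = config$seed)),
                    error = function(e) stage_stop("simulate", conditionMessage(e)))
    write_simulation(sim, file.path(config$outdir, "simulated"))
    expr <- sim$expr_cn
    beta <- sim$beta; ann <- sim$annotation; cn <- sim$cn
    genesets <- sim$genesets
    covariates <- NULL
  } else {
    load_stage <- function(what, reader, path) {
      if (is.null(path)) return(NULL)
      inputs[[what]] <<- path
      tryCatch(reader(path),
               error = function(e) stage_stop("load", what, ": ", conditionMessage(e)))
    }
    expr <- load_stage("expr", read_matrix_tsv, config$expr)
    if (is.null(expr)) stage_stop("load", "an expression matrix is required")
    beta <- load_stage("beta", read_matrix_tsv, config$beta)
    ann <- load_stage("annotation", read_table_tsv, config$annotation)
    cn <- load_stage("cn", read_matrix_tsv, config$cn)
    genesets <- load_stage("gmt", read_gmt, config$gmt)
    covariates <- load_stage("covariates", read_table_tsv, config$covariates)
  }

  if (!is.null(config$metadata) && !isTRUE(config$simulate)) {
    meta <- read_table_tsv(config$metadata)
    inputs[["metadata"]] <- config$metadata
    keep <- tryCatch(
      filter_samples(meta, config$purity_column, config$purity_cutoff),
      error = function(e) stage_stop("sample_filter", conditionMessage(e)))
    keep <- intersect(colnames(expr), keep)
    if (length(keep) == 0L) stage_stop("sample_filter", "no samples pass the cutoff")
    expr <- expr[, keep, drop = FALSE]
    if (!is.null(beta)) beta <- beta[, intersect(colnames(beta), keep), drop = FALSE]
    if (!is.null(cn)) cn <- cn[, intersect(colnames(cn), keep), drop = FALSE]
  }

  net <- tryCatch({
    cm <- correlate(expr)
    sel <- if (is.null(config$network$soft_power)) {
      select_soft_threshold(cm, config$network)
    } else {
      list(beta = config$network$soft_power, converged = NA)
    }
    adj <- signed_adjacency(cm, sel$beta)
    tom <- topological_overlap(adj)
    part <- detect_modules(tom, expr[rownames(tom), , drop = FALSE], config$network)
    me <- eigengenes(expr[rownames(tom), , drop = FALSE], part$labels)
    list(cor = cm, beta_power = sel, adj = adj, tom = tom, part = part, me = me)
  }, error = function(e) stage_stop("network", conditionMessage(e)))

  emit_df(data.frame(gene = names(net$part$labels),
                     module = as.integer(net$part$labels)), "partition.tsv")
  emit_mat(net$me$me, "module_eigengenes.tsv", "module")
  emit_df(module_membership(expr[rownames(net$tom), ], net$me), "membership.tsv")
  emit_df(connectivity(net$adj, net$part$labels), "connectivity.tsv")
  emit_mat(module_fractions(net$me), "module_fractions.tsv", "module")

  focal <- config$focal_module %||% {
    mods <- setdiff(unique(net$part$labels), 0L)
    if (length(mods) == 0L) stage_stop("metrics", "no modules detected")
    mods[which.max(vapply(mods, function(m) sum(net$part$labels == m), numeric(1)))]
  }
  focal_me <- net$me$me[sprintf("M%d", focal), ]

  metrics <- tryCatch({
    cent <- module_centrality(net$adj, net$tom, net$part$labels, focal)
    genes <- cent$gene
    graph <- build_graph(net$tom[genes, genes], "one_minus", 0)
    comm <- detect_communities(graph)
    cosim <- cosine_similarity(net$cor[genes, , drop = FALSE])
    list(cent = cent, comm = comm, cosim = cosim)
  }, error = function(e) stage_stop("metrics", conditionMessage(e)))
  emit_df(metrics$cent, "centrality.tsv")
  emit_df(data.frame(gene = names(metrics$comm$membership),
                     community = as.integer(metrics$comm$membership)),
          "communities.tsv")
  emit_mat(metrics$cosim, "cosine_similarity.tsv", "gene")

  if (!is.null(genesets)) {
    sc <- tryCatch({
      scores <- score_samples(expr, genesets)
      ranked <- rank_by_me_correlation(expr, focal_me)
      enr <- gsea_genesets(ranked, genesets, n_perm = 1000L, seed = config$seed)
      list(scores = scores, ranked = ranked, enr = enr)
    }, error = function(e) stage_stop("scoring", conditionMessage(e)))
    emit_mat(sc$scores, "geneset_scores.tsv", "sample")
    emit_df(sc$ranked, "ranked_list.tsv")
    emit_df(sc$enr, "gsea.tsv")
  }

  if (!is.null(beta) && !is.null(ann)) {
    meth <- tryCatch({
      filt <- filter_probes(beta, ann)
      norm <- promoter_mad_normalize(filt$beta, ann)
      prof <- summarize_gene_promoters(norm, ann)
      corr <- me_promoter_correlation(net$me, prof)
      clus <- cluster_correlation_profiles(corr, k = min(3L, nrow(corr)))
      assoc <- region_category_association(focal_me, filt$beta, ann,
                                           config$flag_threshold)
      list(filt = filt, prof = prof, corr = corr, clus = clus, assoc = assoc)
    }, error = function(e) stage_stop("methylome", conditionMessage(e)))
    emit_mat(meth$prof$profile, "promoter_profile.tsv", "gene")
    emit_mat(meth$corr, "me_promoter_correlation.tsv", "gene")
    emit_df(data.frame(gene = names(meth$clus$labels),
                       cluster = as.integer(meth$clus$labels),
                       silhouette = as.numeric(meth$clus$silhouette)),
            "promoter_clusters.tsv")
    emit_df(meth$assoc, "region_association.tsv")
  }

  if (!is.null(cn)) {
    cnres <- tryCatch({
      cand <- candidate_drivers(cn, expr, focal_me, config$alpha)
      module_genes <- names(net$part$labels)[net$part$labels == focal]
      enr <- if (any(cand$candidate & cand$direction == "gain")) {
        driver_module_enrichment(cand, module_genes, nrow(expr))
      } else NULL
      list(cand = cand, enr = enr)
    }, error = function(e) stage_stop("cn_drivers", conditionMessage(e)))
    emit_df(cnres$cand, "cn_candidates.tsv")
    if (!is.null(cnres$enr)) {
      emit_df(data.frame(
        overlap = length(cnres$enr$test$overlap),
        n_candidates = cnres$enr$n_candidates,
        overlap_percent = cnres$enr$overlap_percent,
        chisq = cnres$enr$test$chisq, p = cnres$enr$test$p_chisq),
        "cn_enrichment.tsv")
    }
  }

  if (!is.null(covariates)) {
    assoc <- tryCatch(me_covariate_association(focal_me, covariates),
                      error = function(e) stage_stop("associate", conditionMessage(e)))
    emit_df(assoc, "covariate_association.tsv")
  }

  manifest <- list(
    seed = config$seed,
    config_digest = digest,
    focal_module = focal,
    soft_power = net$beta_power$beta,
    inputs = md5_named(inputs),
    outputs = md5_named(outputs)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
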