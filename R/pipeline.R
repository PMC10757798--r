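#' Pipeline run configuration
#'
#' Collects and validates every tunable of the end-to-end pipeline. When
#' `k`/`l` are supplied the scree stage is skipped and those component
#' counts are used directly.
#'
#' @param input path to an LFC matrix file, or an [lfc_matrix()] object.
#' @param delimiter field separator for matrix I/O, default tab.
#' @param clip_bound symmetric clipping bound, default 6.
#' @param clip_first clip raw LFCs before standardization (default FALSE:
#'   standardize, then clip).
#' @param scree_grid integer vector of candidate component counts, or
#'   `NULL` for the default even grid up to `min(dim, 100)`.
#' @param sensitivity kneedle sensitivity, default 1.
#' @param alpha_extract normality alpha for cluster trimming, default 0.05.
#' @param alpha_assoc FDR threshold on association q-values, default 0.05.
#' @param z_min minimum |Z| of a significant coefficient, default 2.
#' @param floor_n minimum remainder size during trimming, default 20.
#' @param seed top-level integer seed; every random stage derives its own
#'   seed from it.
#' @param k,l optional fixed component counts overriding the scree.
#' @param gmt optional path to a GMT gene-set collection for enrichment.
#' @param min_set_size smallest gene set tested for enrichment, default 10.
#' @param out_dir optional directory for run artifacts.
#' @param max_iter,tol FastICA iteration cap and tolerance.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, delimiter = "\t", clip_bound = 6,
                       clip_first = FALSE, scree_grid = NULL,
                       sensitivity = 1, alpha_extract = 0.05,
                       alpha_assoc = 0.05, z_min = 2, floor_n = 20L,
                       seed = 0L, k = NULL, l = NULL, gmt = NULL,
                       min_set_size = 10L, out_dir = NULL,
                       max_iter = 200L, tol = 1e-6) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1)
      stop(sprintf("'%s' must be a single number in (0, 1)", nm))
  }
  chk_prob(alpha_extract, "alpha_extract")
  chk_prob(alpha_assoc, "alpha_assoc")
  if (clip_bound <= 0) stop("'clip_bound' must be positive")
  if (z_min < 0) stop("'z_min' must be non-negative")
  if (sensitivity <= 0) stop("'sensitivity' must be positive")
  if (!is.null(k) && k < 1) stop("'k' must be a positive integer")
  if (!is.null(l) && l < 1) stop("'l' must be a positive integer")
  structure(list(input = input, delimiter = delimiter,
                 clip_bound = clip_bound, clip_first = isTRUE(clip_first),
                 scree_grid = scree_grid, sensitivity = sensitivity,
                 alpha_extract = alpha_extract, alpha_assoc = alpha_assoc,
                 z_min = z_min, floor_n = as.integer(floor_n),
                 seed = as.integer(seed),
                 k = if (is.null(k)) NULL else as.integer(k),
                 l = if (is.null(l)) NULL else as.integer(l),
                 gmt = gmt, min_set_size = as.integer(min_set_size),
                 out_dir = out_dir, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full Dual ICA pipeline
#'
#' Executes, in order: preprocessing (per-condition standardization and
#' clipping), K^2 scree and knee-based component selection on the matrix
#' and on its transpose (skipped where `k`/`l` are fixed in the config),
#' the dual ICA decomposition, signed-cluster extraction on every
#' component of both signal matrices, orphan-condition assignment, the
#' melted-regression association with Wald/BH/Z significance, interacting
#' module assembly, and (when a GMT collection is configured) Fisher's
#' exact enrichment of the gene clusters. When `out_dir` is set, every
#' stage's artifact is written as labeled TSV/GMT/JSON plus a `manifest.json`
#' recording package version, seed, configuration and its hash.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the preprocessed matrix, screes, chosen
#'   `k`/`l`, both decompositions, cluster lists, the
#'   `association_result`, significant pairs, modules, heatmap ordering,
#'   and the enrichment table (or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  M_raw <- .stage("read_input",
    if (inherits(config$input, "lfc_matrix")) config$input
    else read_lfc_matrix(config$input, config$delimiter))
  M <- .stage("preprocess",
    preprocess(M_raw, bound = config$clip_bound,
               clip_first = config$clip_first))

  scree_cond <- scree_gene <- NULL
  k <- config$k; l <- config$l
  if (is.null(k)) {
    scree_cond <- .stage("scree_conditions",
      k2_scree(M$values, r_grid = config$scree_grid,
               seed = derive_seed(config$seed, 101L),
               max_iter = config$max_iter, tol = config$tol))
    k <- .stage("choose_k",
                choose_components(scree_cond, config$sensitivity))
  }
  if (is.null(l)) {
    scree_gene <- .stage("scree_genes",
      k2_scree(t(M$values), r_grid = config$scree_grid,
               seed = derive_seed(config$seed, 202L),
               max_iter = config$max_iter, tol = config$tol))
    l <- .stage("choose_l",
                choose_components(scree_gene, config$sensitivity))
  }

  decomp <- .stage("dual_decompose",
    dual_decompose(M, k = k, l = l, seed = config$seed,
                   max_iter = config$max_iter, tol = config$tol))
  gene_clusters <- .stage("extract_gene_clusters",
    extract_all(decomp$condition_decomp, axis = "gene",
                alpha = config$alpha_extract, floor_n = config$floor_n))
  condition_clusters <- .stage("extract_condition_clusters",
    extract_all(decomp$gene_decomp, axis = "condition",
                alpha = config$alpha_extract, floor_n = config$floor_n))
  condition_clusters <- .stage("assign_orphan_conditions",
    assign_orphan_conditions(decomp$gene_decomp, condition_clusters))

  assoc <- .stage("association",
    regression_association(decomp$condition_decomp$signal,
                           decomp$gene_decomp$signal, M,
                           alpha = config$alpha_assoc,
                           z_min = config$z_min))
  sig <- significant_pairs(assoc)
  modules <- .stage("build_modules",
    build_modules(sig, gene_clusters, condition_clusters, assoc, M))
  ordering <- if (length(modules)) reorder_for_heatmap(M, modules) else NULL

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    enrichment <- .stage("enrichment", {
      collection <- read_gmt(config$gmt, universe = gene_ids(M))
      enrich_all(gene_clusters, collection,
                 min_set_size = config$min_set_size,
                 alpha = config$alpha_assoc)
    })
  }

  result <- list(matrix = M, scree_conditions = scree_cond,
                 scree_genes = scree_gene, k = k, l = l,
                 condition_decomp = decomp$condition_decomp,
                 gene_decomp = decomp$gene_decomp,
                 gene_clusters = gene_clusters,
                 condition_clusters = condition_clusters,
                 association = assoc, significant = sig,
                 modules = modules, ordering = ordering,
                 enrichment = enrichment, config = config)
  if (!is.null(config$out_dir))
    .stage("write_artifacts", write_run_artifacts(result, config$out_dir))
  invisible(result)
}

# Serialize all pipeline artifacts of one run into a directory.
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  cfg <- result$config
  write_lfc_matrix(result$matrix, f("matrix_preprocessed.tsv"),
                   cfg$delimiter)
  tsv <- function(df, name) utils::write.table(
    df, f(name), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$scree_conditions))
    tsv(as.data.frame(result$scree_conditions, chosen = result$k),
        "scree_conditions.tsv")
  if (!is.null(result$scree_genes))
    tsv(as.data.frame(result$scree_genes, chosen = result$l),
        "scree_genes.tsv")
  wmat <- function(mat, name) utils::write.table(
    data.frame(id = rownames(mat), mat, check.names = FALSE),
    f(name), sep = "\t", quote = FALSE, row.names = FALSE)
  wmat(result$condition_decomp$signal, "G_signal.tsv")
  wmat(result$condition_decomp$mixing, "A_mixing.tsv")
  wmat(result$gene_decomp$signal, "C_signal.tsv")
  wmat(result$gene_decomp$mixing, "B_mixing.tsv")
  tsv(clusters_as_data_frame(c(result$gene_clusters,
                               result$condition_clusters)), "clusters.tsv")
  write_clusters_gmt(result$gene_clusters, f("gene_clusters.gmt"))
  tsv(as.data.frame(result$association), "associations.tsv")
  tsv(modules_as_data_frame(result$modules), "modules.tsv")
  jsonlite::write_json(
    lapply(result$modules, function(mo) mo[c(
      "gene_cluster_label", "condition_cluster_label", "gene_ids",
      "condition_ids", "mean_lfc", "coefficient", "wald_p", "q_value",
      "z_score")]),
    f("modules.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$enrichment))
    tsv(result$enrichment, "enrichment.tsv")
  if (!is.null(result$ordering)) {
    tsv(result$ordering$annotations, "module_annotations.tsv")
    plot_modules_heatmap(result$matrix, result$ordering, f("heatmap.png"))
  }
  cfg_plain <- unclass(cfg)
  cfg_plain$input <- if (inherits(cfg$input, "lfc_matrix"))
    "<in-memory lfc_matrix>" else cfg$input
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "dualica",
    version = as.character(utils::packageVersion("dualica")),
    r_version = R.version.string,
    seed = cfg$seed, k = result$k, l = result$l,
    n_genes = nrow(result$matrix$values),
    n_conditions = ncol(result$matrix$values),
    n_gene_clusters = length(result$gene_clusters),
    n_condition_clusters = length(result$condition_clusters),
    n_significant_pairs = nrow(result$significant),
    n_modules = length(result$modules),
    config = cfg_plain,
    config_hash = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
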