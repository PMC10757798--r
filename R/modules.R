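#' Build interacting modules from significant IC pairs
#'
#' For every significant (condition IC i, gene IC j) pair, instantiates one
#' interacting module per non-empty sign combination of the gene clusters
#' extracted from IC i (Gi+, Gi-) and the condition clusters extracted from
#' IC j (Cj+, Cj-) -- up to four modules per pair. All sign combinations are
#' emitted (not only coefficient-concordant ones): overlapping condition
#' sets legitimately pair with both up- and down-regulated gene sets, and
#' the block mean LFC records which way each combination goes. A pair with
#' no extracted cluster on one side contributes nothing and is skipped with
#' a warning.
#'
#' @param sig data.frame of significant pairs from [significant_pairs()].
#' @param gene_clusters list of gene-axis `signed_cluster`s (from the
#'   condition-IC decomposition).
#' @param condition_clusters list of condition-axis `signed_cluster`s (from
#'   the gene-IC decomposition, after orphan assignment).
#' @param result the `association_result` the pairs came from.
#' @param M the preprocessed [lfc_matrix()] (or the raw one, if block means
#'   on the raw LFC scale are wanted).
#' @return List of `interacting_module` objects. Each has the two cluster
#'   labels, member id vectors, `mean_lfc` over the gene x condition block,
#'   and the parent cell's `coefficient`, `outer_product`, `wald_p`,
#'   `q_value`, `z_score`.
#' @export
build_modules <- function(sig, gene_clusters, condition_clusters, result, M) {
  stopifnot(inherits(result, "association_result"))
  V <- if (inherits(M, "lfc_matrix")) M$values else M
  by_ic <- function(clusters, ic)
    Filter(function(cl) cl$source_ic == ic, clusters)
  modules <- list()
  for (r in seq_len(nrow(sig))) {
    i <- sig$condition_ic[r]; j <- sig$gene_ic[r]
    gcl <- by_ic(gene_clusters, i)
    ccl <- by_ic(condition_clusters, j)
    if (!length(gcl) || !length(ccl)) {
      warning(sprintf(
        "significant pair (conditionIC %d, geneIC %d) has no extracted %s cluster; skipped",
        i, j, if (!length(gcl)) "gene" else "condition"), call. = FALSE)
      next
    }
    for (g in gcl) for (cc in ccl) {
      block <- V[g$member_ids, cc$member_ids, drop = FALSE]
      modules[[length(modules) + 1L]] <- structure(list(
        gene_cluster_label = cluster_label(g),
        condition_cluster_label = cluster_label(cc),
        condition_ic = i, gene_ic = j,
        gene_ids = g$member_ids, condition_ids = cc$member_ids,
        mean_lfc = mean(block),
        coefficient = result$coefficients[i, j],
        outer_product = result$outer_products[i, j],
        wald_p = result$wald_p[i, j],
        q_value = result$q_values[i, j],
        z_score = result$z_scores[i, j]), class = "interacting_module")
    }
  }
  modules
}

#' @export
print.interacting_module <- function(x, ...) {
  cat(sprintf("%s x %s: %d genes x %d conditions, mean LFC %+.3f (q=%.3g)\n",
              x$condition_cluster_label, x$gene_cluster_label,
              length(x$gene_ids), length(x$condition_ids),
              x$mean_lfc, x$q_value))
  invisible(x)
}

#' Mean LFC over a module's gene x condition block
#'
#' @param module an `interacting_module`.
#' @param M an [lfc_matrix()] containing all module members.
#' @return Arithmetic mean of `M[genes, conditions]`.
#' @export
module_mean_lfc <- function(module, M) {
  V <- if (inherits(M, "lfc_matrix")) M$values else M
  bad_g <- setdiff(module$gene_ids, rownames(V))
  bad_c <- setdiff(module$condition_ids, colnames(V))
  if (length(bad_g) || length(bad_c))
    stop("module member(s) absent from matrix: ",
         paste(c(bad_g, bad_c), collapse = ", "))
  mean(V[module$gene_ids, module$condition_ids, drop = FALSE])
}

#' Tabulate interacting modules
#'
#' @param modules list of `interacting_module` objects.
#' @return One row per module; member lists are comma-joined strings.
#' @export
modules_as_data_frame <- function(modules) {
  if (!length(modules))
    return(data.frame(module = character(), condition_cluster = character(),
                      gene_cluster = character(), n_genes = integer(),
                      n_conditions = integer(), mean_lfc = numeric(),
                      coefficient = numeric(), wald_p = numeric(),
                      q_value = numeric(), z_score = numeric(),
                      genes = character(), conditions = character()))
  do.call(rbind, lapply(modules, function(mo) {
    data.frame(
      module = paste0(mo$condition_cluster_label, "x", mo$gene_cluster_label),
      condition_cluster = mo$condition_cluster_label,
      gene_cluster = mo$gene_cluster_label,
      n_genes = length(mo$gene_ids),
      n_conditions = length(mo$condition_ids),
      mean_lfc = mo$mean_lfc, coefficient = mo$coefficient,
      wald_p = mo$wald_p, q_value = mo$q_value, z_score = mo$z_score,
      genes = paste(mo$gene_ids, collapse = ","),
      conditions = paste(mo$condition_ids, collapse = ","),
      stringsAsFactors = FALSE)
  }))
}

#' Row/column ordering that groups module members for a heatmap
#'
#' Genes are grouped by gene-cluster membership in module order
#' (first-module-first, stable): each gene is placed at its first
#' occurrence, so overlapping members appear once, under the first module
#' that contains them; the overlap itself is recorded in the annotations.
#' Genes and conditions in no module are appended afterwards in their
#' original order. Annotations record, per module, the row and column index
#' spans of its members in the new ordering, for outlining significant
#' blocks.
#'
#' @param M an [lfc_matrix()].
#' @param modules non-empty list of `interacting_module`s.
#' @return List with `gene_order` and `condition_order` (character vectors
#'   covering all of M) and `annotations`: a data.frame with one row per
#'   module (`module`, `significant` placeholder columns `gene_rows` /
#'   `condition_cols` as comma-joined index strings, and `n_overlap_genes`,
#'   `n_overlap_conditions` counting members already placed by earlier
#'   modules).
#' @export
reorder_for_heatmap <- function(M, modules) {
  if (!length(modules)) stop("need at least one module to reorder")
  V <- if (inherits(M, "lfc_matrix")) M$values else M
  gene_order <- character(0)
  cond_order <- character(0)
  ann <- vector("list", length(modules))
  for (idx in seq_along(modules)) {
    mo <- modules[[idx]]
    new_g <- setdiff(mo$gene_ids, gene_order)
    new_c <- setdiff(mo$condition_ids, cond_order)
    gene_order <- c(gene_order, new_g)
    cond_order <- c(cond_order, new_c)
    ann[[idx]] <- list(module = paste0(mo$condition_cluster_label, "x",
                                       mo$gene_cluster_label),
                       gene_ids = mo$gene_ids,
                       condition_ids = mo$condition_ids,
                       n_overlap_genes = length(mo$gene_ids) - length(new_g),
                       n_overlap_conditions =
                         length(mo$condition_ids) - length(new_c))
  }
  gene_order <- c(gene_order, setdiff(rownames(V), gene_order))
  cond_order <- c(cond_order, setdiff(colnames(V), cond_order))
  annotations <- do.call(rbind, lapply(ann, function(a) {
    data.frame(module = a$module,
               gene_rows = paste(match(a$gene_ids, gene_order),
                                 collapse = ","),
               condition_cols = paste(match(a$condition_ids, cond_order),
                                      collapse = ","),
               n_overlap_genes = a$n_overlap_genes,
               n_overlap_conditions = a$n_overlap_conditions,
               stringsAsFactors = FALSE)
  }))
  list(gene_order = gene_order, condition_order = cond_order,
       annotations = annotations)
}

#' Render the reordered LFC matrix as a heatmap image
#'
#' Convenience wrapper around [pheatmap::pheatmap()] (if installed): plots
#' the matrix in module order without re-clustering, with gaps at module
#' boundaries. Intended for quick inspection of the reordered block
#' structure; returns silently if the graphics device or pheatmap is
#' unavailable.
#'
#' @param M an [lfc_matrix()].
#' @param ordering result of [reorder_for_heatmap()].
#' @param file output image path (png extension).
#' @param max_genes cap on rows drawn (most-module-relevant first).
#' @return The file path invisibly, or `NULL` if plotting was unavailable.
#' @export
plot_modules_heatmap <- function(M, ordering, file, max_genes = 500L) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) return(invisible(NULL))
  V <- if (inherits(M, "lfc_matrix")) M$values else M
  g <- utils::head(ordering$gene_order, max_genes)
  out <- tryCatch({
    pheatmap::pheatmap(V[g, ordering$condition_order, drop = FALSE],
                       cluster_rows = FALSE, cluster_cols = FALSE,
                       show_rownames = length(g) <= 60,
                       fontsize_col = 6, filename = file, silent = TRUE)
    file
  }, error = function(e) NULL)
  invisible(out)
}
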