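#' Specify one planted module for the synthetic generator
#'
#' @param n_genes,n_conditions block dimensions (used when explicit member
#'   indices are not given).
#' @param delta signed mean shift added to every cell of the block, in the
#'   same units as the background noise SD.
#' @param genes,conditions optional explicit integer indices of the block's
#'   rows/columns, enabling overlapping designs; default `NULL` lets
#'   [generate_lfc()] place disjoint consecutive blocks.
#' @return A `planted_module_spec` list.
#' @export
planted_module <- function(n_genes, n_conditions, delta,
                           genes = NULL, conditions = NULL) {
  if (delta == 0) stop("planted effect 'delta' must be nonzero")
  if (is.null(genes) && n_genes < 1L) stop("planted gene set must be nonempty")
  if (is.null(conditions) && n_conditions < 1L)
    stop("planted condition set must be nonempty")
  structure(list(n_genes = if (is.null(genes)) as.integer(n_genes)
                           else length(genes),
                 n_conditions = if (is.null(conditions))
                   as.integer(n_conditions) else length(conditions),
                 delta = delta, genes = genes, conditions = conditions),
            class = "planted_module_spec")
}

#' Default planted design: three disjoint 50-gene x 10-condition blocks
#'
#' The stock validation scenario: blocks of 50 genes x 10 conditions with
#' mean shifts +3, -3, +3 against unit-variance background -- strong,
#' coordinated dys-regulation of a small gene set in a small condition set,
#' the structure the dual decomposition is designed to find.
#'
#' @return List of three [planted_module()] specs.
#' @export
default_planted_modules <- function() {
  list(planted_module(50L, 10L, +3),
       planted_module(50L, 10L, -3),
       planted_module(50L, 10L, +3))
}

#' Generate a synthetic LFC matrix with planted interacting modules
#'
#' Background cells are i.i.d. Gaussian noise `N(0, sigma^2)`; each planted
#' module adds its signed mean shift `delta` to every cell of its gene x
#' condition block (shifts from overlapping modules add). Because the
#' background is Gaussian, the planted blocks are the only non-Gaussian
#' structure in the matrix -- exactly what the K^2 machinery of the
#' pipeline detects. Modules without explicit member indices are placed on
#' disjoint consecutive index ranges. Gene ids are `g0001...`, condition
#' ids `c001...`; generation is deterministic per seed.
#'
#' The default dimensions (many genes, few conditions) mirror the aspect
#' ratio of real bulk LFC compendia.
#'
#' @param n_genes,n_conditions matrix dimensions, default 1000 x 60.
#' @param modules list of [planted_module()] specs (may be empty for pure
#'   noise); default [default_planted_modules()].
#' @param sigma background noise SD, default 1.
#' @param seed integer seed.
#' @return List with `matrix` (a raw [lfc_matrix()]) and `truth`
#'   (`planted_truth`: per-module gene/condition id sets and deltas, plus
#'   `sigma` and `seed`).
#' @export
generate_lfc <- function(n_genes = 1000L, n_conditions = 60L,
                         modules = default_planted_modules(), sigma = 1,
                         seed = 0L) {
  if (sigma <= 0) stop("'sigma' must be positive")
  n_genes <- as.integer(n_genes); n_conditions <- as.integer(n_conditions)
  gids <- sprintf("g%04d", seq_len(n_genes))
  cids <- sprintf("c%03d", seq_len(n_conditions))
  vals <- .with_seed(seed,
    matrix(stats::rnorm(n_genes * n_conditions, sd = sigma),
           n_genes, n_conditions))
  dimnames(vals) <- list(gids, cids)
  next_g <- 1L; next_c <- 1L
  truth_modules <- list()
  for (spec in modules) {
    g_idx <- spec$genes
    if (is.null(g_idx)) {
      g_idx <- seq.int(next_g, length.out = spec$n_genes)
      next_g <- next_g + spec$n_genes
    }
    c_idx <- spec$conditions
    if (is.null(c_idx)) {
      c_idx <- seq.int(next_c, length.out = spec$n_conditions)
      next_c <- next_c + spec$n_conditions
    }
    if (max(g_idx) > n_genes || max(c_idx) > n_conditions)
      stop("planted module exceeds matrix dimensions")
    vals[g_idx, c_idx] <- vals[g_idx, c_idx] + spec$delta
    truth_modules[[length(truth_modules) + 1L]] <-
      list(genes = gids[g_idx], conditions = cids[c_idx],
           delta = spec$delta)
  }
  list(matrix = lfc_matrix(vals, preprocessed = FALSE),
       truth = structure(list(modules = truth_modules, sigma = sigma,
                              seed = as.integer(seed)),
                         class = "planted_truth"))
}

#' Jaccard index of two sets
#' @param a,b character vectors.
#' @return `|a intersect b| / |a union b|` (0 if both empty).
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Score recovery of planted modules by emitted interacting modules
#'
#' For each planted module, finds the emitted module with the highest mean
#' of gene-axis and condition-axis Jaccard indices. An emitted module (and
#' the significant IC pair it came from) counts as a true positive when
#' both of its Jaccards against some planted module reach
#' `match_threshold`; recall is the fraction of planted modules matched by
#' at least one emitted module, precision the fraction of significant IC
#' pairs that produced at least one matching module.
#'
#' @param truth a `planted_truth` from [generate_lfc()].
#' @param modules list of `interacting_module`s from [build_modules()].
#' @param match_threshold minimum per-axis Jaccard for a match, default
#'   0.25 (tolerates sign-split clusters and orphan-diluted condition
#'   sets while still requiring genuine overlap on both axes).
#' @return List with `per_module` (data.frame: planted index, delta, best
#'   gene/condition Jaccard, best mean Jaccard, matched flag),
#'   `mean_gene_jaccard`, `mean_condition_jaccard`, `recall`, `precision`,
#'   `n_planted`, `n_emitted`, `n_significant_pairs`.
#' @export
recovery_scores <- function(truth, modules, match_threshold = 0.25) {
  stopifnot(inherits(truth, "planted_truth"))
  n_planted <- length(truth$modules)
  pair_of <- vapply(modules, function(mo)
    paste(mo$condition_ic, mo$gene_ic), character(1))
  per <- lapply(seq_len(n_planted), function(t) {
    tm <- truth$modules[[t]]
    if (!length(modules))
      return(data.frame(planted = t, delta = tm$delta, gene_jaccard = 0,
                        condition_jaccard = 0, mean_jaccard = 0,
                        matched = FALSE, best_module = NA_character_))
    jg <- vapply(modules, function(mo) jaccard(mo$gene_ids, tm$genes),
                 numeric(1))
    jc <- vapply(modules, function(mo)
      jaccard(mo$condition_ids, tm$conditions), numeric(1))
    best <- which.max((jg + jc) / 2)
    data.frame(planted = t, delta = tm$delta, gene_jaccard = jg[best],
               condition_jaccard = jc[best],
               mean_jaccard = (jg[best] + jc[best]) / 2,
               matched = any(jg >= match_threshold & jc >= match_threshold),
               best_module = paste0(modules[[best]]$condition_cluster_label,
                                    "x",
                                    modules[[best]]$gene_cluster_label))
  })
  per <- do.call(rbind, per)
  module_is_tp <- vapply(modules, function(mo) {
    any(vapply(truth$modules, function(tm)
      jaccard(mo$gene_ids, tm$genes) >= match_threshold &&
        jaccard(mo$condition_ids, tm$conditions) >= match_threshold,
      logical(1)))
  }, logical(1))
  pairs <- unique(pair_of)
  tp_pairs <- unique(pair_of[module_is_tp])
  list(per_module = per,
       mean_gene_jaccard = if (n_planted) mean(per$gene_jaccard) else NA_real_,
       mean_condition_jaccard = if (n_planted) mean(per$condition_jaccard)
                                else NA_real_,
       recall = if (n_planted) mean(per$matched) else NA_real_,
       precision = if (length(pairs)) length(tp_pairs) / length(pairs)
                   else NA_real_,
       n_planted = n_planted, n_emitted = length(modules),
       n_significant_pairs = length(pairs))
}
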