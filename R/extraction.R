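#' Signed cluster constructor
#'
#' A signed cluster is the set of items (genes or conditions) trimmed from
#' one tail of an independent component during K^2-based extraction, e.g.
#' "G8+" for genes with positive coefficients on condition IC 8, or "C9-"
#' for conditions with negative coefficients on gene IC 9. Members are kept
#' in extraction order (most extreme first) together with the signal-matrix
#' coefficient they carried. Conditions added later by the orphan rule are
#' flagged and exempt from the same-sign invariant.
#'
#' @param source_ic integer index of the IC the cluster came from.
#' @param sign `"+"` or `"-"`.
#' @param axis `"gene"` or `"condition"`.
#' @param member_ids character vector of member labels.
#' @param member_coefficients numeric coefficients at extraction time.
#' @param orphan logical vector flagging orphan-assigned members.
#' @return Object of class `signed_cluster`.
#' @export
signed_cluster <- function(source_ic, sign, axis, member_ids,
                           member_coefficients,
                           orphan = rep(FALSE, length(member_ids))) {
  sign <- match.arg(sign, c("+", "-"))
  axis <- match.arg(axis, c("gene", "condition"))
  if (anyDuplicated(member_ids))
    stop("duplicate member ids within a cluster")
  if (length(member_ids) != length(member_coefficients))
    stop("ids and coefficients differ in length")
  core <- member_coefficients[!orphan]
  if (length(core) &&
      any(if (sign == "+") core < 0 else core > 0))
    stop("extracted member coefficients must share the cluster sign")
  structure(list(source_ic = as.integer(source_ic), sign = sign, axis = axis,
                 member_ids = as.character(member_ids),
                 member_coefficients = as.numeric(member_coefficients),
                 orphan = orphan),
            class = "signed_cluster")
}

#' @rdname signed_cluster
#' @param x a `signed_cluster`.
#' @export
cluster_label <- function(x) {
  stopifnot(inherits(x, "signed_cluster"))
  paste0(if (x$axis == "gene") "G" else "C", x$source_ic, x$sign)
}

#' @export
print.signed_cluster <- function(x, ...) {
  cat(sprintf("signed_cluster %s: %d members (%d orphan-assigned)\n",
              cluster_label(x), length(x$member_ids), sum(x$orphan)))
  invisible(x)
}

#' Extract signed clusters from one independent component
#'
#' Greedy tail-trimming: while the D'Agostino K^2 p-value of the remaining
#' coefficients is below `alpha`, the coefficient with the largest absolute
#' value is removed and appended to the positive or negative cluster
#' according to its sign; the loop stops as soon as the remainder looks
#' normal (p >= alpha) or the remainder would shrink below `floor_n`
#' (the K^2 test is unreliable on very small samples). Either cluster may
#' come out empty -- a normally distributed component yields two empty
#' clusters, a one-sided tail yields one.
#'
#' Ties in absolute coefficient are broken by lower vector index, making the
#' extraction fully deterministic.
#'
#' @param coefficients named numeric vector (one IC column of a signal
#'   matrix), length >= 8.
#' @param alpha normality significance level for stopping, default 0.05.
#' @param floor_n minimum size the remainder may reach, default 20.
#' @param source_ic,axis metadata stored on the returned clusters.
#' @return List with `positive` and `negative` (`signed_cluster`) and
#'   `trace`: a list with `removed_count`, `p_trajectory` (p after each
#'   removal), `initial_p`, `final_p`, and `floor_hit` (TRUE if trimming was
#'   stopped by the size floor while still non-normal).
#' @export
extract_clusters_from_ic <- function(coefficients, alpha = 0.05,
                                     floor_n = 20L, source_ic = 1L,
                                     axis = c("gene", "condition")) {
  axis <- match.arg(axis)
  if (length(coefficients) < 8L)
    stop("need at least 8 coefficients to test normality")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (is.null(names(coefficients)))
    names(coefficients) <- as.character(seq_along(coefficients))
  remaining <- coefficients
  pos_ids <- neg_ids <- character(0)
  pos_coef <- neg_coef <- numeric(0)
  initial_p <- dagostino_k2(remaining)$p
  p <- initial_p
  p_traj <- numeric(0)
  while (p < alpha && length(remaining) > floor_n) {
    i <- which.max(abs(remaining))  # ties: lowest index wins
    v <- remaining[[i]]
    if (v >= 0) {
      pos_ids <- c(pos_ids, names(remaining)[i]); pos_coef <- c(pos_coef, v)
    } else {
      neg_ids <- c(neg_ids, names(remaining)[i]); neg_coef <- c(neg_coef, v)
    }
    remaining <- remaining[-i]
    p <- dagostino_k2(remaining)$p
    p_traj <- c(p_traj, p)
  }
  floor_hit <- p < alpha
  if (floor_hit)
    warning(sprintf(
      "IC %d: size floor %d reached with K2 p=%.3g still below alpha=%g; keeping clusters extracted so far",
      source_ic, floor_n, p, alpha), call. = FALSE)
  list(
    positive = signed_cluster(source_ic, "+", axis, pos_ids, pos_coef),
    negative = signed_cluster(source_ic, "-", axis, neg_ids, neg_coef),
    trace = list(removed_count = length(pos_ids) + length(neg_ids),
                 p_trajectory = p_traj, initial_p = initial_p, final_p = p,
                 floor_hit = floor_hit)
  )
}

#' Extract signed clusters from every component of a decomposition
#'
#' Applies [extract_clusters_from_ic()] to each signal-matrix column and
#' collects the non-empty clusters, at most two per IC. Gene clusters are
#' extracted from the condition-IC decomposition of M (signal G), condition
#' clusters from the gene-IC decomposition of t(M) (signal C).
#'
#' @param decomp an `ica_decomposition`.
#' @param axis `"gene"` or `"condition"`: what the signal rows are.
#' @param alpha,floor_n passed to [extract_clusters_from_ic()].
#' @return List of `signed_cluster` objects (empty clusters dropped), with
#'   attribute `traces` holding the per-IC extraction traces.
#' @export
extract_all <- function(decomp, axis = c("gene", "condition"), alpha = 0.05,
                        floor_n = 20L) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  axis <- match.arg(axis)
  clusters <- list()
  traces <- list()
  for (i in seq_len(decomp$n_components)) {
    res <- extract_clusters_from_ic(decomp$signal[, i], alpha = alpha,
                                    floor_n = floor_n, source_ic = i,
                                    axis = axis)
    traces[[i]] <- res$trace
    if (length(res$positive$member_ids))
      clusters[[length(clusters) + 1L]] <- res$positive
    if (length(res$negative$member_ids))
      clusters[[length(clusters) + 1L]] <- res$negative
  }
  attr(clusters, "traces") <- traces
  clusters
}

#' Assign unclustered conditions to their strongest component
#'
#' Any condition left out of every condition cluster after K^2 extraction is
#' attached to the IC on which it has the largest absolute coefficient, on
#' the side matching that coefficient's sign -- creating the signed cluster
#' if it does not exist yet. Each orphan joins exactly one cluster and is
#' flagged `orphan`. This rule applies to conditions only; genes with no
#' signal on any IC legitimately remain unclustered.
#'
#' @param gene_decomp the `ica_decomposition` of t(M) whose signal matrix C
#'   (conditions x gene-ICs) the clusters were extracted from.
#' @param clusters list of condition-axis `signed_cluster`s.
#' @return The cluster list with every condition present in at least one
#'   cluster.
#' @export
assign_orphan_conditions <- function(gene_decomp, clusters) {
  stopifnot(inherits(gene_decomp, "ica_decomposition"))
  if (length(clusters) && any(vapply(clusters, `[[`, "", "axis") != "condition"))
    stop("clusters must be condition-axis clusters")
  C <- gene_decomp$signal
  clustered <- unique(unlist(lapply(clusters, `[[`, "member_ids")))
  orphans <- setdiff(rownames(C), clustered)
  for (cond in orphans) {
    coefs <- C[cond, ]
    ic <- which.max(abs(coefs))
    sgn <- if (coefs[[ic]] >= 0) "+" else "-"
    hit <- which(vapply(clusters, function(cl)
      cl$source_ic == ic && cl$sign == sgn, logical(1)))
    if (length(hit)) {
      cl <- clusters[[hit[1L]]]
      cl$member_ids <- c(cl$member_ids, cond)
      cl$member_coefficients <- c(cl$member_coefficients, coefs[[ic]])
      cl$orphan <- c(cl$orphan, TRUE)
      clusters[[hit[1L]]] <- cl
    } else {
      clusters[[length(clusters) + 1L]] <-
        signed_cluster(ic, sgn, "condition", cond, coefs[[ic]], orphan = TRUE)
    }
  }
  clusters
}

#' Tabulate a list of signed clusters
#'
#' @param clusters list of `signed_cluster` objects.
#' @return data.frame with columns `axis`, `ic_index`, `sign`, `label`,
#'   `member_id`, `coefficient`, `orphan_flag` (one row per membership).
#' @export
clusters_as_data_frame <- function(clusters) {
  if (!length(clusters))
    return(data.frame(axis = character(), ic_index = integer(),
                      sign = character(), label = character(),
                      member_id = character(), coefficient = numeric(),
                      orphan_flag = logical()))
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(axis = cl$axis, ic_index = cl$source_ic, sign = cl$sign,
               label = cluster_label(cl), member_id = cl$member_ids,
               coefficient = cl$member_coefficients, orphan_flag = cl$orphan,
               stringsAsFactors = FALSE)
  }))
}

#' Write gene clusters as a GMT gene-set file
#'
#' One line per cluster: label, a short description, then the member gene
#' ids, tab-separated -- directly usable with external enrichment tools.
#'
#' @param clusters list of gene-axis `signed_cluster`s.
#' @param path output path.
#' @export
write_clusters_gmt <- function(clusters, path) {
  lines <- vapply(clusters, function(cl) {
    paste(c(cluster_label(cl),
            sprintf("%s cluster from IC %d", cl$axis, cl$source_ic),
            cl$member_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
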