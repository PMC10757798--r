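#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene ids. Duplicate members within a set are
#' dropped with a warning; a line with fewer than three fields is a hard
#' error reporting the line number.
#'
#' @param path path to a GMT file.
#' @param universe optional character vector of all assayable gene ids; if
#'   `NULL` the universe is inferred as the union of all set members.
#' @return Object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: expected name, description and >= 1 member", ln))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate member(s) dropped",
                      ln, fields[1L], sum(duplicated(members))),
              call. = FALSE)
      members <- unique(members)
    }
    sets[[fields[1L]]] <- members
  }
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param sets named list of character member vectors.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names")
  if (is.null(universe)) {
    universe <- unique(unlist(sets, use.names = FALSE))
  } else {
    universe <- unique(as.character(universe))
    dropped <- sum(vapply(sets, function(s) sum(!s %in% universe),
                          integer(1)))
    if (dropped > 0)
      warning(sprintf("%d set member(s) outside the universe dropped",
                      dropped), call. = FALSE)
    sets <- lapply(sets, intersect, y = universe)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Fisher's exact enrichment of a gene cluster in one gene set
#'
#' One-sided (greater) Fisher's exact test on the 2x2 table of cluster
#' membership against set membership over the gene universe. Reports the
#' fold enrichment `es = (overlap/|cluster|) / (|set|/|universe|)`
#' (observed over expected overlap fraction), the conditional-MLE odds
#' ratio, and the percentage of the gene set captured by the cluster.
#'
#' @param cluster character vector of cluster gene ids (subset of universe).
#' @param gene_set character vector of set gene ids (subset of universe).
#' @param universe character vector of all gene ids.
#' @return One-row data.frame with `overlap_count`, `cluster_size`,
#'   `set_size`, `universe_size`, `es`, `odds_ratio`, `p`, `overlap_pct`.
#' @export
fisher_enrichment <- function(cluster, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  cluster <- unique(intersect(as.character(cluster), universe))
  gene_set <- unique(intersect(as.character(gene_set), universe))
  a <- length(intersect(cluster, gene_set))
  b <- length(cluster) - a
  cc <- length(gene_set) - a
  d <- length(universe) - a - b - cc
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L),
                           alternative = "greater")
  es <- if (length(cluster) && length(gene_set))
    (a / length(cluster)) / (length(gene_set) / length(universe))
  else NA_real_
  data.frame(overlap_count = a, cluster_size = length(cluster),
             set_size = length(gene_set), universe_size = length(universe),
             es = es, odds_ratio = unname(ft$estimate), p = ft$p.value,
             overlap_pct = if (length(gene_set)) 100 * a / length(gene_set)
                           else NA_real_)
}

#' Enrichment of all gene clusters against a gene-set collection
#'
#' Runs [fisher_enrichment()] for every cluster against every collection
#' set with at least `min_set_size` members (after harmonization to the
#' universe), applies Benjamini-Hochberg correction across the full
#' cluster x set family of tests, and sorts by q-value.
#'
#' @param clusters list of gene-axis `signed_cluster`s.
#' @param collection a `gene_set_collection`.
#' @param min_set_size smallest set tested, default 10 (smaller sets carry
#'   too little signal for a stable enrichment call).
#' @param alpha FDR threshold used for the `significant` flag, default 0.05.
#' @return data.frame, one row per cluster x eligible set, with `cluster`,
#'   `set`, the [fisher_enrichment()] columns, `q` and `significant`,
#'   ordered by increasing q.
#' @export
enrich_all <- function(clusters, collection, min_set_size = 10L,
                       alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (min_set_size < 1L) stop("'min_set_size' must be >= 1")
  eligible <- Filter(function(s) length(s) >= min_set_size, collection$sets)
  if (!length(eligible) || !length(clusters)) {
    return(data.frame(cluster = character(), set = character(),
                      overlap_count = integer(), cluster_size = integer(),
                      set_size = integer(), universe_size = integer(),
                      es = numeric(), odds_ratio = numeric(), p = numeric(),
                      overlap_pct = numeric(), q = numeric(),
                      significant = logical()))
  }
  rows <- list()
  for (cl in clusters) {
    for (set_name in names(eligible)) {
      rec <- fisher_enrichment(cl$member_ids, eligible[[set_name]],
                               collection$universe)
      rec <- cbind(data.frame(cluster = cluster_label(cl), set = set_name,
                              stringsAsFactors = FALSE), rec)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out[order(out$q, out$p), ]
}
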