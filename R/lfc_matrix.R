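#' Labeled log-fold-change matrix
#'
#' Container for a genes x conditions matrix of log2 fold-changes, as produced
#' upstream by differential-expression tools (one LFC column per condition,
#' replicates already collapsed). Row and column labels must be unique and all
#' entries finite; missing values are a hard error because the downstream
#' decompositions assume a complete matrix.
#'
#' @param values numeric matrix, genes in rows, conditions in columns.
#' @param gene_ids,condition_ids character vectors of unique labels; default
#'   taken from `dimnames(values)`.
#' @param preprocessed logical flag recording whether column standardization
#'   and clipping have been applied (see [preprocess()]).
#' @param clip_bound the symmetric clipping bound used, or `NA` if none.
#' @return An object of class `lfc_matrix`: a list with elements `values`
#'   (labeled numeric matrix), `preprocessed`, and `clip_bound`.
#' @export
lfc_matrix <- function(values, gene_ids = rownames(values),
                       condition_ids = colnames(values),
                       preprocessed = FALSE, clip_bound = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(gene_ids) || is.null(condition_ids))
    stop("gene and condition labels are required")
  gene_ids <- as.character(gene_ids)
  condition_ids <- as.character(condition_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of 'gene_ids' does not match number of rows")
  if (length(condition_ids) != ncol(values))
    stop("length of 'condition_ids' does not match number of columns")
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g))
    stop("duplicate gene label(s): ", paste(unique(dup_g), collapse = ", "))
  dup_c <- condition_ids[duplicated(condition_ids)]
  if (length(dup_c))
    stop("duplicate condition label(s): ", paste(unique(dup_c), collapse = ", "))
  if (anyNA(values))
    stop("missing value(s) in LFC matrix; complete data required")
  if (any(!is.finite(values)))
    stop("non-finite value(s) in LFC matrix")
  dimnames(values) <- list(gene_ids, condition_ids)
  structure(list(values = values, preprocessed = isTRUE(preprocessed),
                 clip_bound = clip_bound),
            class = "lfc_matrix")
}

#' @export
print.lfc_matrix <- function(x, ...) {
  cat(sprintf("lfc_matrix: %d genes x %d conditions (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$preprocessed)
                sprintf("preprocessed, clip bound %g", x$clip_bound)
              else "raw"))
  invisible(x)
}

#' @export
dim.lfc_matrix <- function(x) dim(x$values)

#' @rdname lfc_matrix
#' @param M an `lfc_matrix`.
#' @export
gene_ids <- function(M) rownames(M$values)

#' @rdname lfc_matrix
#' @export
condition_ids <- function(M) colnames(M$values)

#' Read a labeled LFC matrix from a delimited text file
#'
#' Expects the first row to hold condition labels and the first column gene
#' labels, with a fully numeric body. Duplicated labels, non-numeric cells and
#' missing cells (empty or `NA`) are hard errors naming the offending
#' row/column -- nothing is silently imputed.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter field separator, default tab.
#' @return An [lfc_matrix()] with `preprocessed = FALSE`, row and column order
#'   preserved from the file.
#' @export
read_lfc_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "", row.names = NULL,
                          na.strings = character(0))
  if (ncol(df) < 2) stop("expected at least one condition column in ", path)
  genes <- df[[1L]]
  conds <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  parsed <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(parsed), arr.ind = TRUE)
  if (nrow(bad)) {
    g <- genes[bad[1L, 1L]]
    cn <- conds[bad[1L, 2L]]
    raw <- body[bad[1L, 1L], bad[1L, 2L]]
    if (is.na(raw) || raw %in% c("", "NA", "NaN", "na"))
      stop(sprintf("missing value at gene '%s', condition '%s'", g, cn))
    stop(sprintf("non-numeric value '%s' at gene '%s', condition '%s'",
                 raw, g, cn))
  }
  dimnames(parsed) <- list(genes, conds)
  lfc_matrix(parsed, preprocessed = FALSE)
}

#' Write an LFC matrix to a delimited text file
#'
#' Inverse of [read_lfc_matrix()]: first column `gene_id`, remaining columns
#' the conditions, values printed at full precision so that read -> write ->
#' read round-trips exactly.
#'
#' @param M an [lfc_matrix()].
#' @param path output file path.
#' @param delimiter field separator, default tab.
#' @export
write_lfc_matrix <- function(M, path, delimiter = "\t") {
  stopifnot(inherits(M, "lfc_matrix"))
  df <- data.frame(gene_id = rownames(M$values), M$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize each condition column to mean 0, sample SD 1
#'
#' The sample (n-1) standard deviation is used, so re-standardizing an already
#' standardized matrix is a no-op to floating-point precision. A column with
#' zero variance cannot be standardized and raises an error naming the
#' condition.
#'
#' @param M an [lfc_matrix()].
#' @return An `lfc_matrix` with standardized columns.
#' @export
standardize_columns <- function(M) {
  stopifnot(inherits(M, "lfc_matrix"))
  sds <- apply(M$values, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance (degenerate) condition column(s): ",
         paste(colnames(M$values)[sds == 0], collapse = ", "))
  out <- scale(M$values, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  lfc_matrix(out, preprocessed = M$preprocessed, clip_bound = M$clip_bound)
}

#' Clip matrix entries symmetrically at +/- bound
#'
#' Entries above `bound` are set to `bound`, below `-bound` to `-bound`;
#' entries already inside the interval are untouched bit-for-bit. The default
#' bound of 6 reflects the range most LFC compendia occupy; values beyond it
#' are rare outliers that bias the decompositions.
#'
#' @param M an [lfc_matrix()].
#' @param bound positive clipping bound, default 6.
#' @export
clip_values <- function(M, bound = 6) {
  stopifnot(inherits(M, "lfc_matrix"))
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0)
    stop("'bound' must be a single positive number")
  v <- M$values
  v[v > bound] <- bound
  v[v < -bound] <- -bound
  lfc_matrix(v, preprocessed = M$preprocessed, clip_bound = bound)
}

#' Preprocess an LFC matrix: per-condition standardization, then clipping
#'
#' Columns are standardized first and the standardized values clipped at
#' `+/- bound` second. Set `clip_first = TRUE` to clip raw LFCs before
#' standardization instead (in which case columns are exactly standard
#' afterwards but extreme raw values are truncated on their original scale).
#'
#' @param M a raw [lfc_matrix()].
#' @param bound positive clipping bound, default 6.
#' @param clip_first clip raw values before standardizing instead of after.
#' @return An `lfc_matrix` with `preprocessed = TRUE`.
#' @export
preprocess <- function(M, bound = 6, clip_first = FALSE) {
  stopifnot(inherits(M, "lfc_matrix"))
  out <- if (clip_first) standardize_columns(clip_values(M, bound))
         else clip_values(standardize_columns(M), bound)
  lfc_matrix(out$values, preprocessed = TRUE, clip_bound = bound)
}
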