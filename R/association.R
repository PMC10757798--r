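#' Outer-product association between one condition IC and one gene IC
#'
#' The association of condition IC i (a gene-loading vector Gi, length n)
#' with gene IC j (a condition-loading vector Cj, length m) over the LFC
#' matrix M is `sum over a,b of Gi[a] * Cj[b] * M[a,b]` -- the outer product
#' of the two loading vectors pointwise-multiplied with M and summed. It
#' up-weights LFC entries where both loadings are simultaneously extreme,
#' and is proportional to the corresponding coefficient of the melted linear
#' regression (see [regression_association()]).
#'
#' @param Gi numeric vector, length `nrow(M)`.
#' @param Cj numeric vector, length `ncol(M)`.
#' @param M an [lfc_matrix()] or bare numeric matrix.
#' @return A single number.
#' @export
outer_product_association <- function(Gi, Cj, M) {
  V <- if (inherits(M, "lfc_matrix")) M$values else M
  if (length(Gi) != nrow(V) || length(Cj) != ncol(V))
    stop(sprintf("dimension mismatch: |Gi|=%d, |Cj|=%d vs M %d x %d",
                 length(Gi), length(Cj), nrow(V), ncol(V)))
  sum(outer(as.numeric(Gi), as.numeric(Cj)) * V)
}

#' Full k x l association matrix between condition ICs and gene ICs
#'
#' Entry (i, j) is [outer_product_association()] of G's column i with C's
#' column j; computed as the bilinear form `t(G) %*% M %*% C`.
#'
#' @param G signal matrix of the condition-IC decomposition (n x k).
#' @param C signal matrix of the gene-IC decomposition (m x l).
#' @param M an [lfc_matrix()] or bare numeric matrix (n x m).
#' @return k x l numeric matrix.
#' @export
association_matrix <- function(G, C, M) {
  V <- if (inherits(M, "lfc_matrix")) M$values else M
  if (nrow(G) != nrow(V) || nrow(C) != ncol(V))
    stop("dimension mismatch between signal matrices and LFC matrix")
  out <- crossprod(G, V %*% C)
  dimnames(out) <- list(colnames(G), colnames(C))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] with `method = "BH"`), with input validation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length, each >= the corresponding p.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Melted-regression association with Wald tests, BH and Z filtering
#'
#' Fits, by ordinary least squares, the melted model
#' `LFC[g,c] = beta0 + sum_ij theta_ij * G[g,i] * C[c,j]`
#' over all n*m gene-condition cells, with one product covariate per
#' (condition IC i, gene IC j) pair plus an intercept. Because IC loadings
#' are centered and mutually uncorrelated, each fitted theta_ij is
#' proportional to the outer-product association of the pair, but the
#' regression additionally yields Wald p-values (estimate / standard error
#' against a standard normal -- with n*m observations vastly exceeding the
#' parameter count the normal and t references are indistinguishable).
#' The p-values are BH-adjusted across all k*l pairs, and a practical
#' effect-size filter is applied: theta values are standardized against the
#' root-mean-square of all k*l coefficients (a zero-centered scale, so the
#' filter is invariant to ICA's arbitrary component signs) and only pairs
#' with `|Z| >= z_min` can be significant. A pair is flagged significant iff
#' `q < alpha` AND `|Z| >= z_min`.
#'
#' The fit uses the normal equations, which the product structure of the
#' design collapses to Kronecker form: `t(X) %*% X` for the covariate block
#' is `kronecker(t(C) %*% C, t(G) %*% G)`, so the melted design matrix is
#' never materialized and the fit is exact OLS at any n*m.
#'
#' @param G condition-IC signal matrix (n x k, unit-variance columns).
#' @param C gene-IC signal matrix (m x l, unit-variance columns).
#' @param M a preprocessed [lfc_matrix()] (or bare matrix).
#' @param alpha FDR threshold on q-values, default 0.05.
#' @param z_min minimum absolute coefficient Z-score, default 2.
#' @return Object of class `association_result`: list with k x l matrices
#'   `coefficients`, `outer_products`, `wald_p`, `q_values`, `z_scores`,
#'   `std_errors`, logical `significant`, scalar `intercept`, and the
#'   thresholds used.
#' @export
regression_association <- function(G, C, M, alpha = 0.05, z_min = 2) {
  V <- if (inherits(M, "lfc_matrix")) M$values else M
  if (nrow(G) != nrow(V) || nrow(C) != ncol(V))
    stop("dimension mismatch between signal matrices and LFC matrix")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (z_min < 0) stop("'z_min' must be non-negative")
  n <- nrow(V); m <- ncol(V); k <- ncol(G); l <- ncol(C)
  N <- as.numeric(n) * m
  p_cov <- k * l

  GtG <- crossprod(G); CtC <- crossprod(C)
  xtx_cov <- kronecker(CtC, GtG)             # (i,j) vec'd column-major
  x0x <- as.vector(outer(colSums(G), colSums(C)))
  XtX <- rbind(c(N, x0x), cbind(x0x, xtx_cov))
  GtMC <- crossprod(G, V %*% C)
  Xty <- c(sum(V), as.vector(GtMC))

  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) {
    cors <- stats::cov2cor(xtx_cov / N)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ]
    pair <- function(idx) sprintf("(conditionIC %d, geneIC %d)",
                                  (idx - 1L) %% k + 1L, (idx - 1L) %/% k + 1L)
    stop(sprintf(
      "design matrix is rank-deficient; covariates %s and %s are collinear (|r|=%.4f)",
      pair(worst[1L]), pair(worst[2L]), max(abs(cors))))
  }
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  rss <- sum(V^2) - sum(beta * Xty)
  sigma2 <- max(rss, 0) / (N - p_cov - 1)
  se <- sqrt(diag(chol2inv(R)) * sigma2)

  theta <- matrix(beta[-1L], k, l)
  se_m <- matrix(se[-1L], k, l)
  wald <- theta / se_m
  wald_p <- matrix(2 * stats::pnorm(-abs(wald)), k, l)
  q <- matrix(bh_adjust(as.vector(wald_p)), k, l)
  # effect-size Z against the coefficient population, standardized about
  # zero (RMS scale): component signs are arbitrary in ICA, and a
  # mean-centered z-score would let a sign flip move the significance
  # mask; the RMS scale is exactly flip-invariant and agrees with the
  # mean/sd scale as mean(theta) -> 0
  rms <- sqrt(mean(theta^2))
  z <- if (rms == 0) theta * 0 else theta / rms
  sig <- q < alpha & abs(z) >= z_min
  dn <- list(colnames(G), colnames(C))
  dimnames(theta) <- dimnames(wald_p) <- dimnames(q) <- dimnames(z) <-
    dimnames(sig) <- dimnames(se_m) <- dn
  op <- GtMC
  dimnames(op) <- dn
  structure(list(coefficients = theta, outer_products = op,
                 wald_p = wald_p, q_values = q, z_scores = z,
                 std_errors = se_m, significant = sig,
                 intercept = beta[1L], alpha = alpha, z_min = z_min),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "association_result: %d condition ICs x %d gene ICs, %d significant (q < %g, |Z| >= %g)\n",
    nrow(x$coefficients), ncol(x$coefficients), sum(x$significant),
    x$alpha, x$z_min))
  invisible(x)
}

#' Significant (condition IC, gene IC) pairs
#'
#' @param result an `association_result`.
#' @return data.frame with columns `condition_ic`, `gene_ic` (integer
#'   indices, sorted), plus the cell's `coefficient`, `wald_p`, `q_value`
#'   and `z_score`.
#' @export
significant_pairs <- function(result) {
  stopifnot(inherits(result, "association_result"))
  idx <- which(result$significant, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(condition_ic = as.integer(idx[, 1L]),
             gene_ic = as.integer(idx[, 2L]),
             coefficient = result$coefficients[idx],
             wald_p = result$wald_p[idx],
             q_value = result$q_values[idx],
             z_score = result$z_scores[idx])
}

#' Tabulate an association result
#'
#' @param x an `association_result`.
#' @param ... unused.
#' @return Long data.frame, one row per (condition IC, gene IC) pair.
#' @export
as.data.frame.association_result <- function(x, ...) {
  k <- nrow(x$coefficients); l <- ncol(x$coefficients)
  data.frame(condition_ic = rep(seq_len(k), l),
             gene_ic = rep(seq_len(l), each = k),
             coefficient = as.vector(x$coefficients),
             outer_product = as.vector(x$outer_products),
             wald_p = as.vector(x$wald_p),
             q_value = as.vector(x$q_values),
             z_score = as.vector(x$z_scores),
             significant = as.vector(x$significant))
}

#' Mean mixing-matrix activity of condition groups per IC
#'
#' Averages the mixing-matrix weights of each named group of conditions on
#' every condition IC -- the "activity" view of how strongly a family of
#' related conditions drives each component.
#'
#' @param A mixing matrix (k ICs x m conditions) with condition column
#'   names, e.g. `decomp$mixing` from the first ICA.
#' @param condition_groups named list of character vectors of condition ids
#'   (a labeled partition or sub-selection of the conditions).
#' @return groups x ICs numeric matrix of mean activities.
#' @export
mixing_activity <- function(A, condition_groups) {
  if (is.null(colnames(A))) stop("mixing matrix must have condition names")
  unknown <- setdiff(unique(unlist(condition_groups)), colnames(A))
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  out <- t(vapply(condition_groups, function(g)
    rowMeans(A[, g, drop = FALSE]), numeric(nrow(A))))
  dimnames(out) <- list(names(condition_groups), rownames(A))
  out
}
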