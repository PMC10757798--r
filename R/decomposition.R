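#' @importFrom ica icafast
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All package randomness flows through this.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministically derive a sub-seed from a top-level seed, kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647)
}

#' Run FastICA on a data matrix
#'
#' Thin, seeded wrapper around the fixed-point FastICA estimator
#' ([ica::icafast()]) with the logcosh contrast and whitening. The input is
#' column-centered internally; the returned signal matrix has its columns
#' rescaled to zero mean and unit sample variance, with the mixing matrix
#' rescaled to compensate, so that `signal %*% mixing` reconstructs the
#' centered input (exactly when `n_components` equals the smaller dimension).
#'
#' ICA is identifiable only up to component permutation and sign; all
#' downstream cluster/association logic in this package is invariant to both.
#' A fixed `seed` makes the run bit-reproducible: the rotation is initialized
#' from a seeded random orthogonal matrix.
#'
#' @param X numeric matrix (observations x features), complete and finite.
#' @param n_components number of components, at most `min(dim(X))`.
#' @param seed integer seed for the random orthogonal initialization.
#' @param max_iter maximum fixed-point iterations (default 200).
#' @param tol convergence tolerance (default 1e-6).
#' @return An object of class `ica_decomposition`: list with `signal`
#'   (n x r, unit-variance columns), `mixing` (r x p), `n_components`,
#'   `seed`, `converged`, `iter`, and `center` (the column means removed).
#' @export
run_ica <- function(X, n_components, seed = 0L, max_iter = 200L, tol = 1e-6) {
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix")
  if (anyNA(X) || any(!is.finite(X))) stop("'X' must be complete and finite")
  r <- as.integer(n_components)
  if (r < 1L || r > min(dim(X)))
    stop(sprintf("n_components must be in [1, %d], got %d", min(dim(X)), r))
  init <- .with_seed(seed, qr.Q(qr(matrix(stats::rnorm(r * r), r, r))))
  fit <- ica::icafast(X, nc = r, center = TRUE, maxit = max_iter, tol = tol,
                      Rmat = init, alg = "par", fun = "logcosh")
  if (!isTRUE(fit$converged))
    warning(sprintf(
      "FastICA did not meet tol=%g within %d iterations (n_components=%d); %s",
      tol, max_iter, r, "components are usable but flagged unconverged"),
      call. = FALSE)
  S <- fit$S
  if (ncol(S) < r) {
    # centering can drop one rank; icafast then returns fewer components
    warning(sprintf("requested %d components but the whitened data supports %d; using %d",
                    r, ncol(S), ncol(S)), call. = FALSE)
    r <- ncol(S)
  }
  sds <- apply(S, 2L, stats::sd)
  sds[sds == 0] <- 1
  S <- sweep(S, 2L, sds, "/")
  Mm <- fit$M  # p x r, except icafast returns 1 x p at nc = 1
  if (ncol(Mm) != r) Mm <- t(Mm)
  A <- t(Mm) * sds  # row i of mixing scaled by the sd moved out of S
  comp <- paste0("IC", seq_len(r))
  dimnames(S) <- list(rownames(X), comp)
  dimnames(A) <- list(comp, colnames(X))
  structure(list(signal = S, mixing = A, n_components = r,
                 seed = as.integer(seed), converged = isTRUE(fit$converged),
                 iter = fit$iter, center = colMeans(X)),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("ica_decomposition: %d x %d signal, %d components (%s)\n",
              nrow(x$signal), ncol(x$signal), x$n_components,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Dual ICA decomposition of an LFC matrix
#'
#' Runs ICA twice: once on the preprocessed genes x conditions matrix M,
#' giving `k` condition ICs (signal G, n x k, over genes; mixing A, k x m),
#' and once on its transpose, giving `l` gene ICs (signal C, m x l, over
#' conditions; mixing B, l x n). Gene clusters are later trimmed from the
#' columns of G, condition clusters from the columns of C.
#'
#' @param M a preprocessed [lfc_matrix()].
#' @param k number of condition ICs.
#' @param l number of gene ICs.
#' @param seed top-level seed; the two runs use seeds derived from it.
#' @inheritParams run_ica
#' @return List with elements `condition_decomp` (G/A) and `gene_decomp`
#'   (C/B), both `ica_decomposition` objects.
#' @export
dual_decompose <- function(M, k, l, seed = 0L, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(M, "lfc_matrix"))
  if (!M$preprocessed)
    warning("LFC matrix is not preprocessed; standardization is recommended",
            call. = FALSE)
  list(
    condition_decomp = run_ica(M$values, k, seed = derive_seed(seed, 1L),
                               max_iter = max_iter, tol = tol),
    gene_decomp = run_ica(t(M$values), l, seed = derive_seed(seed, 2L),
                          max_iter = max_iter, tol = tol)
  )
}

#' Non-Gaussianity scree over a grid of component counts
#'
#' For each candidate component count r, runs ICA at r components and scores
#' every signal column with the D'Agostino omnibus K^2; the scree metric at r
#' aggregates these per-component scores (default: their sum, which rises
#' steeply while genuine non-Gaussian signals are being captured and flattens
#' once only noise components are added). The knee of this curve is the
#' working component count (see [choose_components()]).
#'
#' @param X numeric matrix to decompose.
#' @param r_grid strictly ascending integer vector of candidate counts,
#'   `max(r_grid) <= min(dim(X))`. Default `seq(2, min(dim(X), 100), by = 2)`.
#' @param seed top-level seed; each grid point r uses seed `seed + r`
#'   derivation so runs are independent but reproducible.
#' @param aggregate how to combine per-component K^2 values at each r:
#'   `"sum"` (default), `"mean"`, or `"count"` (number of components with
#'   K^2 p-value below 0.05).
#' @inheritParams run_ica
#' @return Object of class `component_scree`: list with `r_grid`, `metric`,
#'   `per_component_k2` (list of per-r K^2 vectors), `aggregate`, `seed`.
#' @export
k2_scree <- function(X, r_grid = NULL, seed = 0L,
                     aggregate = c("sum", "mean", "count"),
                     max_iter = 200L, tol = 1e-6) {
  aggregate <- match.arg(aggregate)
  if (is.null(r_grid)) r_grid <- seq(2L, min(dim(X), 100L), by = 2L)
  r_grid <- as.integer(r_grid)
  if (is.unsorted(r_grid, strictly = TRUE))
    stop("'r_grid' must be strictly ascending")
  if (max(r_grid) > min(dim(X)))
    stop("max(r_grid) exceeds the smaller matrix dimension")
  per_k2 <- lapply(r_grid, function(r) {
    dec <- suppressWarnings(
      run_ica(X, r, seed = derive_seed(seed, r), max_iter = max_iter,
              tol = tol))
    apply(dec$signal, 2L, function(col) dagostino_k2(col)$k2)
  })
  metric <- vapply(per_k2, function(k2s) {
    switch(aggregate,
           sum = sum(k2s),
           mean = mean(k2s),
           count = sum(stats::pchisq(k2s, 2, lower.tail = FALSE) < 0.05))
  }, numeric(1))
  structure(list(r_grid = r_grid, metric = metric, per_component_k2 = per_k2,
                 aggregate = aggregate, seed = as.integer(seed)),
            class = "component_scree")
}

#' Knee point of a concave increasing curve (kneedle)
#'
#' Implements the kneedle construction: x and y are min-max normalized, the
#' difference curve d = y_norm - x_norm is formed, and the knee is the first
#' local maximum of d whose following values drop below that maximum minus
#' `sensitivity` times the mean normalized x-spacing before another local
#' maximum is reached (or the curve ends). A straight line has a flat
#' difference curve, hence no knee.
#'
#' @param x strictly ascending numeric vector (length >= 3).
#' @param y numeric vector, same length as x.
#' @param sensitivity positive sensitivity S of the original algorithm;
#'   larger values demand a more pronounced knee. Default 1.
#' @return The x-value of the knee, or `NULL` if no knee is found.
#' @export
kneedle <- function(x, y, sensitivity = 1) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("too few points for knee detection (need >= 3)")
  if (is.unsorted(x, strictly = TRUE)) stop("'x' must be strictly ascending")
  if (sensitivity <= 0) stop("'sensitivity' must be positive")
  if (diff(range(y)) == 0) return(NULL)
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  d <- yn - xn
  n <- length(d)
  is_lmax <- vapply(seq_len(n), function(i) {
    i > 1L && i < n && d[i] > d[i - 1L] && d[i] >= d[i + 1L]
  }, logical(1))
  lmx <- which(is_lmax)
  if (!length(lmx)) return(NULL)
  thresh_drop <- sensitivity * mean(diff(xn))
  for (i in lmx) {
    threshold <- d[i] - thresh_drop
    nxt <- lmx[lmx > i]
    stop_at <- if (length(nxt)) nxt[1L] - 1L else n
    if (any(d[(i + 1L):stop_at] < threshold)) return(x[i])
  }
  NULL
}

#' Choose the number of components from a K-squared scree
#'
#' Applies [kneedle()] to the scree curve. If no knee is detected (for
#' example a near-linear scree from structure-free data), falls back to the
#' interior grid point with the largest drop in marginal metric gain --
#' i.e. the r maximizing `gain(r) / gain(next r)` -- and warns, since a
#' kneeless scree means the component count is not well determined.
#'
#' @param scree a `component_scree` from [k2_scree()] (>= 3 grid points).
#' @param sensitivity kneedle sensitivity, default 1.
#' @return A single integer component count.
#' @export
choose_components <- function(scree, sensitivity = 1) {
  stopifnot(inherits(scree, "component_scree"))
  if (length(scree$r_grid) < 3L)
    stop("scree needs at least 3 grid points to locate a knee")
  knee <- kneedle(scree$r_grid, scree$metric, sensitivity = sensitivity)
  if (!is.null(knee)) return(as.integer(knee))
  gains <- diff(scree$metric)
  eps <- max(abs(scree$metric), 1) * 1e-12
  ratios <- gains[-length(gains)] / pmax(gains[-1L], eps)
  pick <- scree$r_grid[which.max(ratios) + 1L]
  warning(sprintf(
    "no knee found on the K2 scree; falling back to r=%d (largest marginal-gain drop)",
    pick), call. = FALSE)
  as.integer(pick)
}

#' @export
print.component_scree <- function(x, ...) {
  cat(sprintf("component_scree (%s of K2): r in [%d, %d], %d points\n",
              x$aggregate, min(x$r_grid), max(x$r_grid), length(x$r_grid)))
  invisible(x)
}

#' Export a scree as a data frame
#'
#' @param x a `component_scree`.
#' @param chosen optional component count to flag (from
#'   [choose_components()]).
#' @param ... unused.
#' @return data.frame with columns `r`, `metric`, `chosen`.
#' @export
as.data.frame.component_scree <- function(x, chosen = NULL, ...) {
  data.frame(r = x$r_grid, metric = x$metric,
             chosen = if (is.null(chosen)) FALSE else x$r_grid == chosen)
}
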