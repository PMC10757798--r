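# Shared fixture builders for the test suite. Everything is generated in
# code so tests are self-contained and deterministic.

# Small labeled LFC matrix with optional values.
toy_lfc <- function(values = NULL, n = 3L, m = 2L) {
  if (is.null(values)) {
    set.seed(1)
    values <- matrix(rnorm(n * m), n, m)
  }
  dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                           paste0("c", seq_len(ncol(values))))
  lfc_matrix(values)
}

# Write a delimited matrix file and return its path.
write_fixture_tsv <- function(lines, delim = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(vapply(lines, paste, "", collapse = delim), path)
  path
}

# Brute-force BH step-up: q_i = min over ranks >= rank(i) of p_(j) * m / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exhaustive one-sided (greater) hypergeometric tail by choose() arithmetic:
# P(X >= a) for overlap X of a size-K set with a size-n cluster drawn from a
# size-N universe.
hyper_tail_brute <- function(a, n_cluster, K_set, N_univ) {
  xs <- max(0L, n_cluster + K_set - N_univ):min(n_cluster, K_set)
  probs <- vapply(xs, function(x)
    exp(lchoose(K_set, x) + lchoose(N_univ - K_set, n_cluster - x) -
          lchoose(N_univ, n_cluster)), numeric(1))
  sum(probs[xs >= a])
}

# Exhaustive search over the kneedle normalized difference curve: the knee
# candidate is the arg max of (y normalized) - (x normalized); used as an
# independent check of where the knee must lie.
difference_curve_argmax <- function(x, y) {
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  x[which.max(yn - xn)]
}

# Independent Laplace sampler (inverse CDF).
rlaplace <- function(n, scale = 1) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

# Best |correlation| assignment between matched columns of two matrices,
# by exhaustive permutation search (fine for <= 5 columns).
best_perm_min_cor <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  cc <- abs(cor(A, B))
  best <- -Inf
  for (p in perms(seq_len(ncol(A)))) {
    sc <- min(cc[cbind(p, seq_len(ncol(B)))])
    if (sc > best) best <- sc
  }
  best
}
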