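test_that("D'Agostino K2 reproduces reference omnibus values", {
  # Expected values computed independently with scipy.stats.normaltest
  # (D'Agostino 1970 skew Z + Anscombe-Glynn 1983 kurtosis Z) and frozen.
  set.seed(42); x1 <- round(rnorm(50), 6)
  r1 <- dagostino_k2(x1)
  expect_equal(r1$k2, 0.6863999832322846, tolerance = 1e-10)
  expect_equal(r1$p, 0.7094963040580308, tolerance = 1e-10)
  expect_equal(r1$z_skew, -0.8283049919519515, tolerance = 1e-10)
  expect_equal(r1$z_kurt, 0.01763018830761702, tolerance = 1e-8)

  set.seed(7); x2 <- round(rexp(30) - 1, 6)
  r2 <- dagostino_k2(x2)
  expect_equal(r2$k2, 18.562045490984417, tolerance = 1e-10)
  expect_equal(r2$p, 9.317577960843234e-05, tolerance = 1e-8)

  r3 <- dagostino_k2(c(2, 8, 0, 4, 1, 9, 9, 0))  # minimum allowed n = 8
  expect_equal(r3$k2, 3.6241771605030615, tolerance = 1e-10)

  expect_error(dagostino_k2(rnorm(7)), "too small")
  expect_error(dagostino_k2(rep(1, 20)), "zero variance")
})

test_that("K2 calibration: near-nominal type-I error on normal data, huge on Laplace", {
  rejected_mild <- 0L
  for (s in 1:200) {
    set.seed(s)
    if (dagostino_k2(rnorm(5000))$p <= 0.001) rejected_mild <- rejected_mild + 1L
  }
  expect_lte(rejected_mild, 2L)  # p > 0.001 in >= 99% of seeds

  set.seed(123)
  expect_lt(dagostino_k2(rlaplace(5000))$p, 1e-6)
})

test_that("FastICA recovers mixed Laplace sources up to sign and permutation", {
  set.seed(5)
  S_true <- cbind(rlaplace(2000), rlaplace(2000), rlaplace(2000))
  A_mix <- matrix(rnorm(9), 3, 3)
  X <- S_true %*% A_mix
  dec <- run_ica(X, 3, seed = 11, max_iter = 500)
  expect_gt(best_perm_min_cor(dec$signal, S_true), 0.95)
  # signal column invariants
  expect_lt(max(abs(colMeans(dec$signal))), 1e-8)
  expect_lt(max(abs(apply(dec$signal, 2, var) - 1)), 1e-6)
  # full-rank reconstruction of the centered input
  Xc <- scale(X, scale = FALSE)
  rel <- norm(Xc - dec$signal %*% dec$mixing, "F") / norm(Xc, "F")
  expect_lt(rel, 1e-6)
})

test_that("run_ica is seed-deterministic and validates n_components", {
  X <- matrix(rnorm(200), 50, 4)
  d1 <- suppressWarnings(run_ica(X, 2, seed = 3))
  d2 <- suppressWarnings(run_ica(X, 2, seed = 3))
  expect_identical(d1$signal, d2$signal)
  expect_identical(d1$mixing, d2$mixing)
  expect_error(run_ica(X, 5, seed = 1), "n_components")
  expect_error(run_ica(matrix(c(1, NA, 2, 3), 2, 2), 1), "finite|complete")
})

test_that("K2 scree rises steeply up to the planted dimension then flattens", {
  set.seed(21)
  n <- 400; m <- 50
  # three strongly non-Gaussian sources mixed into 50 dims + weak noise
  S_true <- cbind(rlaplace(n, 3), rlaplace(n, 3), rlaplace(n, 3))
  S_true[abs(S_true) < 3] <- 0  # sparsify: heavy tails, huge K2
  X <- S_true %*% matrix(rnorm(3 * m), 3, m) + matrix(rnorm(n * m), n, m)
  scree <- suppressWarnings(k2_scree(X, r_grid = 1:8, seed = 2))
  rise <- scree$metric[3] - scree$metric[1]
  tail_rise <- scree$metric[6] - scree$metric[3]
  expect_gt(rise, 5 * max(tail_rise, 1))

  # pure noise: no comparable signal at any r -- the aggregate stays far
  # below the planted-signal plateau (it is not exactly flat: every added
  # component contributes its own small optimizer-inflated K2)
  noise <- suppressWarnings(
    k2_scree(matrix(rnorm(400 * 30), 400, 30), r_grid = c(2, 4, 6, 8),
             seed = 3))
  expect_true(all(noise$metric >= 0))
  expect_true(all(noise$metric < scree$metric[c(2, 4, 6, 8)]))
})

test_that("scree metric is invariant to row and column permutations", {
  set.seed(9)
  X <- matrix(rnorm(60 * 12), 60, 12)
  X[1:10, 1:3] <- X[1:10, 1:3] + 5
  s1 <- suppressWarnings(k2_scree(X, r_grid = c(2, 3), seed = 4))
  Xp <- X[sample(nrow(X)), sample(ncol(X))]
  s2 <- suppressWarnings(k2_scree(Xp, r_grid = c(2, 3), seed = 4))
  # ICA is re-optimized from the permuted data, so agreement is to the
  # optimizer's accuracy, not machine precision
  expect_equal(s1$metric, s2$metric, tolerance = 1e-2)
})

test_that("kneedle finds exact breakpoints and rejects lines", {
  expect_equal(kneedle(1:10, pmin(1:10, 5)), 5)
  expect_null(kneedle(1:10, 2 * (1:10)))
  # smooth concave curve: the knee equals the difference-curve argmax,
  # x = ln(10/(1 - exp(-10))) ~ 2.303, nearest sampled point 2.5
  x <- seq(0, 10, by = 0.5)
  y <- 1 - exp(-x)
  expect_equal(kneedle(x, y), 2.5)
  expect_equal(difference_curve_argmax(x, y), 2.5)
  expect_error(kneedle(1:2, 1:2), "few points")
})

test_that("kneedle agrees with exhaustive difference-curve search on concave curves", {
  for (s in 1:10) {
    set.seed(s)
    brk <- sample(3:8, 1)
    x <- 1:12
    slope <- runif(1, 2, 6)
    y <- pmin(x * slope, brk * slope) + c(0, cumsum(abs(rnorm(11, 0, 0.01))))
    k <- kneedle(x, y)
    expect_equal(k, difference_curve_argmax(x, y))
    expect_equal(k, brk)
  }
})

test_that("choose_components returns the planted dimension and documented fallback", {
  set.seed(33)
  X <- matrix(rnorm(500 * 40), 500, 40)
  for (t in 1:3) {
    X[((t - 1) * 50 + 1):(t * 50), ((t - 1) * 10 + 1):(t * 10)] <-
      X[((t - 1) * 50 + 1):(t * 50), ((t - 1) * 10 + 1):(t * 10)] + 6
  }
  scree <- suppressWarnings(k2_scree(X, r_grid = 1:10, seed = 5))
  chosen <- choose_components(scree)
  expect_true(abs(chosen - 3) <= 1)

  lin <- structure(list(r_grid = c(2L, 4L, 6L, 8L), metric = c(1, 2, 3, 4),
                        per_component_k2 = list(), aggregate = "sum",
                        seed = 0L), class = "component_scree")
  expect_warning(fb <- choose_components(lin), "no knee")
  expect_equal(fb, 4L)

  two <- structure(list(r_grid = c(2L, 4L), metric = c(1, 2),
                        per_component_k2 = list(), aggregate = "sum",
                        seed = 0L), class = "component_scree")
  expect_error(choose_components(two), "3 grid points")
})

test_that("dual_decompose obeys the shape contract and is reproducible", {
  sim <- generate_lfc(n_genes = 120, n_conditions = 30,
                      modules = list(planted_module(20, 6, 4)), seed = 8)
  M <- preprocess(sim$matrix)
  d <- suppressWarnings(dual_decompose(M, k = 5, l = 4, seed = 8))
  expect_equal(dim(d$condition_decomp$signal), c(120L, 5L))
  expect_equal(dim(d$condition_decomp$mixing), c(5L, 30L))
  expect_equal(dim(d$gene_decomp$signal), c(30L, 4L))
  expect_equal(dim(d$gene_decomp$mixing), c(4L, 120L))
  d2 <- suppressWarnings(dual_decompose(M, k = 5, l = 4, seed = 8))
  expect_identical(d$condition_decomp$signal, d2$condition_decomp$signal)
  expect_identical(d$gene_decomp$mixing, d2$gene_decomp$mixing)
})

test_that("a planted gene set surfaces as the top loadings of one condition IC", {
  sim <- generate_lfc(n_genes = 400, n_conditions = 40,
                      modules = list(planted_module(40, 8, 5)), seed = 13)
  M <- preprocess(sim$matrix)
  d <- suppressWarnings(dual_decompose(M, k = 3, l = 3, seed = 13))
  G <- d$condition_decomp$signal
  planted <- sim$truth$modules[[1]]$genes
  jac <- apply(G, 2, function(col) {
    top <- rownames(G)[order(abs(col), decreasing = TRUE)[1:40]]
    jaccard(top, planted)
  })
  expect_gt(max(jac), 0.7)
})
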