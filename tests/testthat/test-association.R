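test_that("outer-product association matches the explicit double-loop sum", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(3:8, 1); m <- sample(2:6, 1)
    Gi <- rnorm(n); Cj <- rnorm(m); V <- matrix(rnorm(n * m), n, m)
    brute <- 0
    for (a in 1:n) for (b in 1:m) brute <- brute + Gi[a] * Cj[b] * V[a, b]
    expect_lt(abs(outer_product_association(Gi, Cj, V) - brute), 1e-10)
  }
})

test_that("outer-product association obeys selector and annihilator identities", {
  set.seed(2)
  V <- matrix(rnorm(24), 6, 4)
  expect_equal(outer_product_association(rnorm(6), rnorm(4),
                                         matrix(0, 6, 4)), 0)
  e3 <- replace(numeric(6), 3, 1); e2 <- replace(numeric(4), 2, 1)
  expect_equal(outer_product_association(e3, e2, V), V[3, 2])
  expect_error(outer_product_association(rnorm(5), rnorm(4), V),
               "dimension mismatch")
})

test_that("association_matrix equals brute force and is permutation invariant", {
  set.seed(4)
  G <- matrix(rnorm(30), 10, 3); C <- matrix(rnorm(16), 8, 2)
  V <- matrix(rnorm(80), 10, 8)
  am <- association_matrix(G, C, V)
  for (i in 1:3) for (j in 1:2)
    expect_lt(abs(am[i, j] - outer_product_association(G[, i], C[, j], V)),
              1e-10)
  perm <- sample(10)
  expect_equal(unname(association_matrix(G[perm, ], C, V[perm, ])),
               unname(am), tolerance = 1e-12)
  # k = l = 1 reduces to the scalar operation
  expect_equal(as.numeric(association_matrix(G[, 1, drop = FALSE],
                                             C[, 1, drop = FALSE], V)),
               outer_product_association(G[, 1], C[, 1], V))
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  set.seed(10)
  for (rep in 1:1000) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("single-covariate regression equals the closed-form OLS slope", {
  # k = l = 1 on a 3x2 matrix: theta is Cov(x, y)/Var(x) for the melted data
  G <- matrix(c(1, 0, -1), 3, 1)
  C <- matrix(c(1, -1), 2, 1)
  V <- matrix(c(2, 0.5, -1, -0.4, 0.1, 1.2), 3, 2)
  x <- as.vector(outer(G[, 1], C[, 1]))
  y <- as.vector(V)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  res <- regression_association(G, C, V)
  expect_equal(as.numeric(res$coefficients), slope, tolerance = 1e-10)
})

test_that("regression coefficients are proportional to outer products", {
  # centered, sample-uncorrelated unit-variance loadings -- the situation
  # ICA signal matrices are in after whitening
  set.seed(6)
  ortho_loadings <- function(n, k) {
    # QR of column-centered noise: columns centered, orthogonal, unit-sd
    Q <- qr.Q(qr(scale(matrix(rnorm(n * k), n, k), scale = FALSE)))
    scale(Q, center = FALSE, scale = apply(Q, 2, sd))
  }
  for (rep in 1:5) {
    n <- 80; m <- 20; k <- 3; l <- 3
    G <- ortho_loadings(n, k)
    C <- ortho_loadings(m, l)
    theta_true <- matrix(rnorm(k * l, sd = 2), k, l)
    V <- G %*% theta_true %*% t(C) + matrix(rnorm(n * m, sd = 0.05), n, m)
    res <- regression_association(G, C, V)
    r <- cor(as.vector(res$coefficients), as.vector(res$outer_products))
    expect_gt(abs(r), 0.999)
    expect_gt(cor(as.vector(res$coefficients), as.vector(theta_true)), 0.999)
  }
})

test_that("regression association scales linearly with the matrix (homogeneity)", {
  set.seed(12)
  G <- scale(matrix(rnorm(60 * 2), 60, 2))
  C <- scale(matrix(rnorm(15 * 2), 15, 2))
  V <- matrix(rnorm(900), 60, 15)
  a1 <- regression_association(G, C, V)
  a3 <- regression_association(G, C, 3 * V)
  expect_equal(a3$coefficients, 3 * a1$coefficients, tolerance = 1e-10)
  expect_equal(a3$outer_products, 3 * a1$outer_products, tolerance = 1e-10)
})

test_that("significance mask is the conjunction of the q and Z thresholds", {
  set.seed(31)
  n <- 100; m <- 25
  sim <- generate_lfc(n_genes = n, n_conditions = m,
                      modules = list(planted_module(20, 6, 5)), seed = 31)
  M <- preprocess(sim$matrix)
  d <- suppressWarnings(dual_decompose(M, k = 4, l = 4, seed = 31))
  res <- regression_association(d$condition_decomp$signal,
                                d$gene_decomp$signal, M)
  expect_identical(res$significant,
                   res$q_values < res$alpha & abs(res$z_scores) >= res$z_min)
  expect_true(all(res$q_values >= res$wald_p))
  expect_true(all(res$q_values >= 0 & res$q_values <= 1))
  sp <- significant_pairs(res)
  expect_equal(nrow(sp), sum(res$significant))
  if (nrow(sp) > 1) {
    expect_true(!is.unsorted(sp$condition_ic))
  }
})

test_that("Wald tests are calibrated when covariates are independent of the noise", {
  # with loadings independent of M, OLS theory applies exactly: raw p
  # roughly uniform, and the BH + Z conjunction almost never fires.
  # (When both signal matrices are estimated from the same noise matrix the
  # decompositions are coupled through its SVD and raw p-values are
  # anticonservative by construction; that behavior is exercised in the
  # end-to-end null-safety acceptance test.)
  ortho <- function(n, k) {
    Q <- qr.Q(qr(scale(matrix(rnorm(n * k), n, k), scale = FALSE)))
    scale(Q, center = FALSE, scale = apply(Q, 2, sd))
  }
  n_sig <- integer(40)
  frac_raw <- numeric(40)
  for (s in 1:40) {
    set.seed(s + 1000)
    V <- matrix(rnorm(200 * 40), 200, 40)
    G <- ortho(200, 5); C <- ortho(40, 5)
    res <- regression_association(G, C, V)
    n_sig[s] <- sum(res$significant)
    frac_raw[s] <- mean(res$wald_p < 0.05)
  }
  expect_gte(mean(n_sig == 0), 0.95)
  expect_gte(mean(frac_raw), 0.001)
  expect_lte(mean(frac_raw), 0.12)
})

test_that("sign-flipping ICA components leaves the significance mask invariant", {
  sim <- generate_lfc(n_genes = 150, n_conditions = 30,
                      modules = list(planted_module(25, 8, 4)), seed = 9)
  M <- preprocess(sim$matrix)
  d <- suppressWarnings(dual_decompose(M, k = 3, l = 3, seed = 9))
  G <- d$condition_decomp$signal; C <- d$gene_decomp$signal
  res1 <- regression_association(G, C, M)
  flip_g <- c(-1, 1, -1); flip_c <- c(1, -1, -1)
  res2 <- regression_association(sweep(G, 2, flip_g, "*"),
                                 sweep(C, 2, flip_c, "*"), M)
  expect_equal(abs(res2$coefficients), abs(res1$coefficients),
               tolerance = 1e-10)
  expect_equal(unname(res2$coefficients),
               unname(res1$coefficients * outer(flip_g, flip_c)),
               tolerance = 1e-10)
  expect_identical(res2$significant, res1$significant)
  expect_equal(res2$wald_p, res1$wald_p, tolerance = 1e-9)
})

test_that("mixing_activity averages mixing weights per condition group", {
  set.seed(14)
  A <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(paste0("IC", 1:3), paste0("c", 1:6)))
  act <- mixing_activity(A, list(g1 = c("c1", "c3"), g2 = c("c2")))
  brute <- rbind((A[, "c1"] + A[, "c3"]) / 2, A[, "c2"])
  expect_equal(unname(act), unname(brute))
  # singleton groups reproduce A's columns
  singles <- mixing_activity(A, list(a = "c4", b = "c5"))
  expect_equal(unname(singles), unname(t(A[, c("c4", "c5")])))
  # identical columns average to the common value
  A2 <- A; A2[, "c2"] <- A2[, "c1"]
  expect_equal(unname(mixing_activity(A2, list(g = c("c1", "c2")))[1, ]),
               unname(A2[, "c1"]))
  expect_error(mixing_activity(A, list(g = "nope")), "unknown condition")
})
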