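test_that("markers collinear with cofactors get NaN p-values", {
  panel <- random_panel(50, 20, seed = 300)
  X <- panel$dosages
  X[, 2] <- X[, 1]                       # duplicate of a cofactor
  set.seed(301)
  y <- rnorm(50) + 0.5 * X[, 5]
  expect_warning(sc <- gwas_scan(y, X, cofactors = 1L), "collinear")
  expect_true(is.nan(sc$p_values[2]))
  expect_true(is.nan(sc$p_values[1]))    # cofactor itself masked
  expect_false(anyNA(sc$p_values[-(1:2)]))
  expect_true(sc$pseudo_h2 >= 0 && sc$pseudo_h2 <= 1)
})

test_that("permuted-phenotype scan is calibrated at the 5% level", {
  cfg <- sim_config(n_samples = 200, n_markers = 200, n_qtl = 10, h2 = 0.5,
                    ld_block = 1, seed = 302)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotype(panel, 10, 0.5, seed = 303)
  set.seed(304)
  y_perm <- sample(sim$phenotype)
  sc <- suppressWarnings(gwas_scan(y_perm, panel))  # near-monomorphic NaNs
  frac <- mean(sc$p_values < 0.05, na.rm = TRUE)
  half <- 2.576 * sqrt(0.05 * 0.95 / 200)   # binomial 99% band
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)
})

test_that("a planted 30%-variance QTL is the top scan hit", {
  hits <- vapply(1:10, function(s) {
    panel <- random_panel(200, 150, seed = 310 + s)
    X <- panel$dosages
    set.seed(410 + s)
    q <- sample.int(150, 1)
    g <- X[, q]
    y <- g + rnorm(200, 0, sqrt(var(g) * 0.7 / 0.3))
    which.min(gwas_scan(y, X)$p_values) == q
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("forward selection recovers independent planted QTLs", {
  rec <- vapply(1:10, function(s) {
    panel <- random_panel(300, 150, seed = 320 + s, p = rep(0.4, 150))
    X <- panel$dosages
    set.seed(420 + s)
    qs <- sample.int(150, 2)
    g <- X[, qs[1]] + X[, qs[2]]
    # each QTL explains ~20% of the phenotypic variance
    y <- g + rnorm(300, 0, sqrt((var(X[, qs[1]]) + var(X[, qs[2]])) * 0.6 / 0.4))
    m <- suppressWarnings(mlmm(y, X, max_qtls = 10))
    all(qs %in% m$qtl_indices)
  }, logical(1))
  expect_gte(mean(rec), 0.9)
})

test_that("forward selection on pure noise selects little and stops", {
  sizes <- vapply(1:15, function(s) {
    cfg <- sim_config(n_samples = 400, n_markers = 200, seed = 3000 + s)
    panel <- simulate_genotypes(cfg)
    sim <- simulate_phenotype(panel, 10, h2 = 0, seed = 4000 + s)
    m <- suppressWarnings(mlmm(sim$phenotype, panel, max_qtls = 10))
    length(m$qtl_indices)
  }, integer(1))
  expect_gte(mean(sizes <= 2), 0.9)
})

test_that("pseudo-heritability is non-increasing along the forward path", {
  mono <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 300, n_markers = 150, n_qtl = 3, h2 = 0.6,
                      ld_block = 1, seed = s)
    panel <- simulate_genotypes(cfg)
    sim <- simulate_phenotype(panel, 3, 0.6, seed = s + 50)
    m <- suppressWarnings(mlmm(sim$phenotype, panel, max_qtls = 8))
    h2s <- vapply(attr(m, "steps"), `[[`, numeric(1), "pseudo_h2")
    all(diff(h2s) <= 1e-8)
  }, logical(1))
  expect_gte(mean(mono), 0.9)
})

test_that("MLMM is deterministic and honors the QTL cap", {
  cfg <- sim_config(n_samples = 120, n_markers = 100, n_qtl = 4, h2 = 0.6,
                    seed = 55)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotype(panel, 4, 0.6, seed = 56)
  m1 <- suppressWarnings(mlmm(sim$phenotype, panel, max_qtls = 6))
  m2 <- suppressWarnings(mlmm(sim$phenotype, panel, max_qtls = 6))
  expect_identical(m1$qtl_indices, m2$qtl_indices)
  expect_identical(m1$theta, m2$theta)
  m0 <- suppressWarnings(mlmm(sim$phenotype, panel, max_qtls = 0))
  expect_length(m0$qtl_indices, 0)
  expect_equal(m0$intercept, mean(sim$phenotype))
  expect_equal(m0$sigma2_e, var(sim$phenotype))
  expect_error(mlmm(sim$phenotype[1:10], panel$dosages[1:10, ],
                    max_qtls = 9), "T - 2")
})

test_that("causal OLS fit matches the normal equations and is unbiased", {
  # exact recovery on noiseless data
  panel <- random_panel(40, 10, seed = 60)
  Q <- panel$dosages[, c(1, 4)]
  y <- 2 * Q[, 1] - 1 * Q[, 2] + 3
  m <- fit_causal_ols(y, Q, qtl_indices = c(1L, 4L))
  expect_equal(unname(m$theta), c(2, -1), tolerance = 1e-10)
  expect_equal(unname(m$intercept), 3, tolerance = 1e-10)
  expect_lte(m$sigma2_e, 1e-16)

  # seeded 3-QTL simulation vs brute-force normal-equation solve
  set.seed(61)
  Q3 <- panel$dosages[, c(2, 5, 8)]
  y3 <- drop(Q3 %*% c(1, -0.5, 0.25)) + rnorm(40, 0, 0.7)
  m3 <- fit_causal_ols(y3, Q3, qtl_indices = c(2L, 5L, 8L))
  W <- cbind(1, Q3)
  bf <- solve(t(W) %*% W, t(W) %*% y3)
  expect_equal(unname(m3$theta), unname(bf[-1, 1]), tolerance = 1e-10)

  # unbiasedness across replicates
  est <- replicate(200, {
    yr <- drop(Q3 %*% c(1, -0.5, 0.25)) + rnorm(40, 0, 0.7)
    fit_causal_ols(yr, Q3)$theta
  })
  se <- apply(est, 1, sd) / sqrt(200)
  expect_true(all(abs(rowMeans(est) - c(1, -0.5, 0.25)) <= 2 * se))

  # degenerate cases
  m_empty <- fit_causal_ols(y3, matrix(0, 40, 0))
  expect_equal(m_empty$intercept, mean(y3))
  expect_equal(m_empty$sigma2_e, var(y3))
  expect_warning(md <- fit_causal_ols(y3, cbind(Q3, Q3[, 1]),
                                      qtl_indices = c(2L, 5L, 8L, 2L)),
                 "collinear")
  expect_length(md$theta, 3)
})
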