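test_that("the generator is deterministic and respects the coding", {
  cfg <- sim_config(n_samples = 50, n_markers = 80, seed = 90)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% c(0, 2)))          # inbred coding
  cfg2 <- sim_config(n_samples = 50, n_markers = 80, inbred = FALSE,
                     seed = 90)
  p3 <- simulate_genotypes(cfg2)
  expect_true(all(p3$dosages %in% c(0, 1, 2)))
  expect_false(identical(p1$dosages, p3$dosages))
  expect_identical(attr(p1, "sim_config"), cfg)      # provenance attached
  expect_equal(as.integer(table(attr(p1, "cluster"))), c(25L, 25L))
})

test_that("small fst gives near-identical cluster allele frequencies", {
  cfg <- sim_config(n_samples = 400, n_markers = 1000, fst = 0.001,
                    ld_block = 1, seed = 91)
  panel <- simulate_genotypes(cfg)
  cl <- attr(panel, "cluster")
  f1 <- colMeans(panel$dosages[cl == 1, ]) / 2
  f2 <- colMeans(panel$dosages[cl == 2, ]) / 2
  expect_lt(mean(abs(f1 - f2)), 0.05)
})

test_that("high fst separates cluster allele frequencies", {
  cfg <- sim_config(n_samples = 400, n_markers = 500, fst = 0.4,
                    ld_block = 1, seed = 92)
  panel <- simulate_genotypes(cfg)
  cl <- attr(panel, "cluster")
  f1 <- colMeans(panel$dosages[cl == 1, ]) / 2
  f2 <- colMeans(panel$dosages[cl == 2, ]) / 2
  expect_gt(mean(abs(f1 - f2)), 0.2)
})

test_that("Markov copying induces local LD with cluster-specific phase", {
  cfg <- sim_config(n_samples = 600, n_markers = 200, fst = 0.3,
                    ld_block = 5, seed = 93)
  panel <- simulate_genotypes(cfg)
  cl <- attr(panel, "cluster")
  adj <- setdiff(which(seq_len(200) %% 5 != 1), 1)  # within-block positions
  r1 <- vapply(adj, function(j)
    suppressWarnings(cor(panel$dosages[cl == 1, j - 1],
                         panel$dosages[cl == 1, j])), numeric(1))
  r2 <- vapply(adj, function(j)
    suppressWarnings(cor(panel$dosages[cl == 2, j - 1],
                         panel$dosages[cl == 2, j])), numeric(1))
  ok <- is.finite(r1) & is.finite(r2)
  expect_gt(mean(abs(r1[ok])), 0.3)                  # strong local LD
  disc <- mean(sign(r1[ok]) != sign(r2[ok]))         # divergent phase
  expect_gt(disc, 0.25)
  # block starts are unlinked
  starts <- which(seq_len(200) %% 5 == 1)[-1]
  r_start <- vapply(starts, function(j)
    suppressWarnings(cor(panel$dosages[, j - 1], panel$dosages[, j])),
    numeric(1))
  expect_lt(mean(abs(r_start), na.rm = TRUE), 0.1)
})

test_that("phenotype simulation hits the target heritability", {
  cfg <- sim_config(n_samples = 1000, n_markers = 300, seed = 94)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotype(panel, n_qtl = 20, h2 = 0.5, seed = 95)
  expect_lt(abs(sim$truth$realized_h2 - 0.5), 0.05)
  expect_length(sim$truth$qtl_indices, 20)
  expect_equal(drop(panel$dosages[, sim$truth$qtl_indices] %*%
                      sim$truth$theta_true),
               sim$truth$genetic_values, ignore_attr = TRUE)
})

test_that("degenerate heritabilities behave as specified", {
  cfg <- sim_config(n_samples = 80, n_markers = 60, seed = 96)
  panel <- simulate_genotypes(cfg)
  s0 <- simulate_phenotype(panel, 5, h2 = 0, seed = 97)
  expect_true(all(s0$truth$theta_true == 0))
  expect_equal(s0$truth$realized_h2, 0)
  s1 <- simulate_phenotype(panel, 5, h2 = 1, seed = 98)
  expect_equal(unname(s1$phenotype), unname(s1$truth$genetic_values))
  # with h2 = 1 and ample training data, prediction approaches the ceiling
  cfgb <- sim_config(n_samples = 220, n_markers = 100, n_qtl = 5, h2 = 1,
                     fst = 0.15, seed = 99)
  pb <- simulate_genotypes(cfgb)
  sb <- simulate_phenotype(pb, 5, h2 = 1, seed = 100)
  acc <- ts_acc_of(pb, sb$phenotype, 1:190, 191:220)
  expect_gt(acc, 0.9)
  # cluster mean shift is applied to the non-reference cluster
  s2 <- simulate_phenotype(panel, 5, h2 = 0, seed = 97, cluster_effect = 10)
  cl <- attr(panel, "cluster")
  expect_gt(mean(s2$phenotype[cl == 2]) - mean(s2$phenotype[cl == 1]), 5)
})
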