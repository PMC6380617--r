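test_that("hill climbing solves a toy subset-recovery problem", {
  target <- c(2, 4, 6, 8, 10)
  crit <- function(idx) length(intersect(idx, target))
  for (seed in c(1, 7, 42)) {
    opt <- hill_climb(crit, start = c(1, 3, 5, 7, 9), candidates = 1:12,
                      n_moves = 500, seed = seed)
    expect_setequal(opt$final_train_idx, target)
    expect_equal(opt$best_value, 5)
  }
})

test_that("zero moves return the start and an empty trace", {
  opt <- hill_climb(function(i) 0, start = 1:4, candidates = 1:8,
                    n_moves = 0, seed = 1)
  expect_equal(opt$final_train_idx, 1:4)
  expect_equal(nrow(opt$trace), 0)
  expect_error(hill_climb(function(i) 0, 1:4, 1:4, n_moves = 10, seed = 1),
               "no legal exchange")
})

test_that("accepted criterion values are strictly increasing and size fixed", {
  panel <- random_panel(30, 25, seed = 70)
  set.seed(71)
  y <- drop(panel$dosages %*% rnorm(25, 0, 0.3)) + rnorm(30)
  test_idx <- 25:30
  crit <- ts_oracle_criterion(panel, y, test_idx)
  sets <- list()
  wrapped <- function(idx) { sets[[length(sets) + 1]] <<- idx; crit(idx) }
  opt <- hill_climb(wrapped, start = 1:8, candidates = 1:24, n_moves = 120,
                    seed = 72)
  acc_vals <- opt$trace$value[opt$trace$accepted]
  expect_true(all(diff(acc_vals) > 0))
  expect_true(all(vapply(sets, length, integer(1)) == 8))
  expect_length(opt$final_train_idx, 8)
})

test_that("identical inputs and seed give bit-identical trajectories", {
  panel <- random_panel(24, 20, seed = 73)
  set.seed(74)
  y <- rnorm(24) + drop(panel$dosages %*% rnorm(20, 0, 0.3))
  crit <- cdmean_criterion(panel, test_idx = 21:24,
                           vc_panel = variance_components(0.05, 1))
  o1 <- hill_climb(crit, 1:6, 1:20, n_moves = 60, seed = 99)
  o2 <- hill_climb(crit, 1:6, 1:20, n_moves = 60, seed = 99)
  expect_identical(o1$trace, o2$trace)
  expect_identical(o1$final_train_idx, o2$final_train_idx)
})

test_that("criterion closures agree with the estimators they delegate to", {
  cfg <- sim_config(n_samples = 60, n_markers = 50, n_qtl = 4, h2 = 0.6,
                    seed = 75)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotype(panel, 4, 0.6, seed = 76)
  y <- standardize_phenotype(sim$phenotype)
  test_idx <- 49:60
  train <- 1:20
  split <- train_test_split(train, test_idx, n = 60)

  vc_panel <- variance_components(0.02, 3)
  expect_equal(cdmean_criterion(panel, test_idx, vc_panel)(train),
               suppressWarnings(cdmean(panel, split, vc_panel))$value)

  d <- suppressWarnings(center_design(panel, split))
  vc <- reml_variance_components(y[train], d$Xc_train)
  expect_equal(ts_oracle_criterion(panel, y, test_idx)(train),
               ts_accuracy(gblup_predict(y[train], d, vc), y[test_idx])$value)

  eth_val <- ethacc_criterion(panel, y, test_idx, max_qtls = 5)(train)
  model <- suppressWarnings(mlmm(y[train], panel$dosages[train, ],
                                 max_qtls = 5))
  if (length(model$qtl_indices)) {
    expect_equal(eth_val$value,
                 suppressWarnings(ethacc(panel, split, model, vc))$value)
  } else {
    expect_equal(eth_val$value, 0)
  }
})

test_that("the EthAcc criterion demands a standardized phenotype", {
  panel <- random_panel(30, 20, seed = 77)
  y <- rnorm(30, 0, 4)
  expect_error(ethacc_criterion(panel, y, 25:30), "standardize")
})

test_that("training sets with inflated predicted genetic variance are rejected", {
  # planted large-effect rare allele: its few carriers dominate the causal
  # model, and the test set (enriched in carriers) gets predicted genetic
  # values more dispersed than the standardized phenotype
  set.seed(80)
  n <- 40
  X <- matrix(rbinom(n * 20, 2, 0.45), n, 20)
  X[, 1] <- 0
  carriers <- c(3, 9, 15, 31, 33, 35, 37, 39)  # 3 candidates, 5 in the tests
  X[carriers, 1] <- 2
  panel <- genotype_panel(X)
  y <- standardize_phenotype(1.3 * X[, 1] + rnorm(n, 0, 0.3))
  test_idx <- 31:40
  train <- sort(c(3, 9, 15, sample(setdiff(1:30, carriers), 12)))
  crit_on <- ethacc_criterion(panel, y, test_idx, max_qtls = 3)
  crit_off <- ethacc_criterion(panel, y, test_idx, max_qtls = 3,
                               constraint = FALSE)
  r_on <- suppressWarnings(crit_on(train))
  r_off <- suppressWarnings(crit_off(train))
  expect_true(r_on$reject)
  expect_false(r_off$reject)
  expect_equal(r_on$value, r_off$value)

  # a rejected evaluation is never accepted by the climber
  always_reject <- function(idx) list(value = 100, reject = TRUE)
  opt <- hill_climb(always_reject, 1:5, 1:15, n_moves = 30, seed = 81)
  expect_false(any(opt$trace$accepted))
  expect_true(all(opt$trace$rejected))
  expect_equal(opt$final_train_idx, 1:5)
})

test_that("restarted hill climbs attain the exhaustive CDmean optimum", {
  panel <- random_panel(14, 15, seed = 82)
  test_idx <- 11:14
  vc_panel <- variance_components(0.1, 2)
  crit <- cdmean_criterion(panel, test_idx, vc_panel)
  combos <- utils::combn(10, 5)
  brute <- max(vapply(seq_len(ncol(combos)),
                      function(k) crit(combos[, k]), numeric(1)))
  best <- max(vapply(1:5, function(r) {
    set.seed(r)
    start <- sort(sample(1:10, 5))
    hill_climb(crit, start, 1:10, n_moves = 60, seed = r)$best_value
  }, numeric(1)))
  expect_equal(best, brute, tolerance = 1e-12)
})
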