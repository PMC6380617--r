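test_that("TS accuracy is the Pearson correlation, with guards", {
  expect_equal(ts_accuracy(c(1, 2, 3), c(1, 2, 3))$value, 1)
  expect_equal(ts_accuracy(c(1, 2, 3), -c(1, 2, 3))$value, -1)
  y <- c(1, 2, 3, 5); u <- c(1, 1, 2, 4)
  # from-definition computation
  r <- sum((y - mean(y)) * (u - mean(u))) /
    sqrt(sum((y - mean(y))^2) * sum((u - mean(u))^2))
  expect_equal(ts_accuracy(u, y)$value, r, tolerance = 1e-12)
  expect_error(ts_accuracy(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(ts_accuracy(c(1, 2), c(1, 2)), "at least 3")
})

test_that("a test individual at the training centroid contributes zero", {
  panel <- random_panel(20, 30, seed = 2)
  X <- panel$dosages
  mu <- colMeans(X[1:15, ])
  X <- rbind(X, centroid = mu)  # centered test row will be exactly zero
  panel2 <- genotype_panel(X, sample_ids = c(panel$sample_ids, "centroid"))
  split <- train_test_split(1:15, c(16:21), n = 21)
  d <- suppressWarnings(center_design(panel2, split))
  expect_warning(est <- cd_accuracy(d, variance_components(0.1, 1)),
                 "zero centered genotype")
  expect_equal(unname(est$per_test[6]), 0)
})

test_that("CD_i approaches 1 for a test copying a training row at small lambda", {
  panel <- random_panel(20, 40, seed = 3)   # M > T: full-rank XcXc'
  X <- rbind(panel$dosages, panel$dosages[1, ])
  panel2 <- genotype_panel(X)
  split <- train_test_split(1:20, 21, n = 21)
  d <- center_design(panel2, split)
  est <- cd_accuracy(d, variance_components(1, 1e-9))
  expect_equal(unname(est$per_test[1]), 1, tolerance = 1e-5)
})

test_that("CD estimate matches Monte-Carlo accuracy under the GBLUP model", {
  panel <- random_panel(40, 50, seed = 4)
  split <- train_test_split(1:30, 31:40, n = 40)
  d <- suppressWarnings(center_design(panel, split))
  s2b <- 0.01; s2e <- 0.5
  vc <- variance_components(s2b, s2e)
  est <- cd_accuracy(d, vc)

  # Monte Carlo of mean_i corr(y_i, u_hat_i) under beta ~ N(0, s2b I)
  set.seed(5)
  B <- 5000
  M <- ncol(d$Xc_train)
  H <- ridge_matrix(d$Xc_train, vc)
  Wmat <- t(solve(H, d$Xc_train %*% t(d$Xc_test)))  # n_test x T predictor
  stat_of <- function(idx) {
    beta <- matrix(rnorm(M * length(idx), 0, sqrt(s2b)), M)
    U <- d$Xc_test %*% beta                          # n_test x B true values
    Y <- d$Xc_train %*% beta +
      matrix(rnorm(nrow(d$Xc_train) * length(idx), 0, sqrt(vc$sigma2_eps)),
             ncol = length(idx))
    Uhat <- Wmat %*% Y
    Ynew <- U + matrix(rnorm(length(U), 0, sqrt(vc$sigma2_eps)), nrow(U))
    mean(vapply(seq_len(nrow(U)),
                function(i) cor(Ynew[i, ], Uhat[i, ]), numeric(1)))
  }
  chunks <- vapply(split(seq_len(B), rep(1:10, each = B / 10)), stat_of,
                   numeric(1))
  mc <- mean(chunks)
  mc_se <- sd(chunks) / sqrt(length(chunks))
  expect_lt(abs(est$value - mc), 3 * mc_se + 1e-6)
})

test_that("CD and PEV estimates coincide and PEV_i is a valid variance", {
  for (s in 1:10) {
    panel <- random_panel(30, 40, seed = s + 20)
    split <- train_test_split(1:22, 23:30, n = 30)
    d <- suppressWarnings(center_design(panel, split))
    vc <- variance_components(exp(runif(1, -4, 0)), exp(runif(1, -2, 1)))
    cd <- cd_accuracy(d, vc)
    pev <- pev_accuracy(d, vc)
    expect_equal(cd$value, pev$value, tolerance = 1e-10)
    var_u <- vc$sigma2_beta * rowSums(d$Xc_test^2)
    expect_true(all(pev$per_test >= 0))
    expect_true(all(pev$per_test <= var_u + 1e-10))
    expect_true(all(cd$per_test >= 0 & cd$per_test <= 1))
    expect_true(cd$value >= 0 && cd$value <= 1)
  }
})

test_that("an unrelated test individual has PEV equal to Var(u)", {
  # test genotype orthogonal to every centered training row
  Xc_train <- matrix(c(1, -1, 0, 0,
                       0, 0, 1, -1), 4, 2)
  Xc_train <- cbind(Xc_train, 0)
  d <- structure(list(Xc_train = Xc_train,
                      Xc_test = matrix(c(0, 0, 2), 1, 3),
                      column_means = c(0, 0, 0), kept = 1:3,
                      train = 1:4, test = 5L),
                 class = "centered_design")
  vc <- variance_components(0.3, 1)
  pev <- pev_accuracy(d, vc)
  expect_equal(unname(pev$per_test[1]), 0.3 * 4, tolerance = 1e-12)
  expect_equal(pev$value, 0)
})
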