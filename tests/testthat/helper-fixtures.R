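# Shared fixtures: small random panels and independent oracles written from
# the definitions (kept free of the package's own computational paths).

random_panel <- function(n, M, seed, p = NULL, coding = 2) {
  set.seed(seed)
  if (is.null(p)) p <- runif(M, 0.1, 0.9)
  X <- matrix(rbinom(n * M, coding, rep(p, each = n)), n, M)
  genotype_panel(X)
}

# kinship-form GBLUP on the unnormalized Xc Xc' relationship matrix,
# written directly from the mixed-model equations (independent oracle)
gblup_kinship_oracle <- function(y_train, Xc_train, Xc_test, lambda) {
  K_tt <- Xc_train %*% t(Xc_train)
  K_st <- Xc_test %*% t(Xc_train)
  yc <- y_train - mean(y_train)
  drop(K_st %*% solve(K_tt + lambda * diag(length(y_train)), yc))
}

# brute-force VanRaden kinship by explicit double loop
vanraden_oracle <- function(X) {
  p <- colMeans(X) / 2
  Zc <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- sum(Zc[i, ] * Zc[j, ]) / denom
  K
}

# full restricted log-likelihood of y = 1*mu + u + e, Var = s2b*K + s2e*I,
# evaluated from the definition with dense solves (independent oracle)
reml_loglik_oracle <- function(s2b, s2e, y, K) {
  n <- length(y)
  V <- s2b * K + s2e * diag(n)
  W <- matrix(1, n, 1)
  Vi <- solve(V)
  WVW <- t(W) %*% Vi %*% W
  tau <- solve(WVW, t(W) %*% Vi %*% y)
  r <- y - W %*% tau
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(WVW, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r) -
               ((n - 1) / 2) * log(2 * pi) +
               0.5 * determinant(crossprod(W), logarithm = TRUE)$modulus)
}

# TS accuracy of a training set, from the package pipeline (used repeatedly)
ts_acc_of <- function(panel, y, train, test) {
  split <- train_test_split(train, test, n = nrow(panel$dosages))
  design <- suppressWarnings(center_design(panel, split))
  vc <- reml_variance_components(y[train], design$Xc_train)
  ts_accuracy(gblup_predict(y[train], design, vc), y[test])$value
}
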