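#' EthAcc: estimated theoretical accuracy given a training set
#'
#' Evaluates the theoretical accuracy of the RR-BLUP predictor when the
#' phenotype is generated by a fixed causal-QTL model y = 1 mu + Q theta + e,
#' with every population expectation over a random test individual replaced by
#' its sample mean across the given test set:
#' \deqn{\rho = \frac{\theta' A X_c' H^{-1} Q_c \theta}
#'   {\sqrt{\sigma_e^2 \overline{\|H^{-1} X_c x_i\|^2} + w' V w}
#'    \sqrt{\sigma_g^2 + \sigma_e^2}}}
#' where A is the sample mean of q_i x_i', H = Xc Xc' + lambda I,
#' w = Xc' H^{-1} Qc theta, V the sample covariance of the test genotype rows,
#' and sigma_g^2 the sample variance of the test genetic values q_i' theta.
#' Plugging in a causal model estimated by MLMM on the training set gives the
#' EthAcc estimator.
#'
#' @param panel a \code{genotype_panel}.
#' @param split a \code{train_test_split}.
#' @param causal a \code{causal_model} (see \code{\link{mlmm}} /
#'   \code{\link{fit_causal_ols}}) fitted on the training set.
#' @param vc RR-BLUP \code{variance_components} estimated on the training set.
#' @param divisor \code{"n"} (default) or \code{"n-1"} for the sample
#'   variance/covariance plug-ins.
#' @return an \code{accuracy_estimate} with method "EthAcc"; \code{components}
#'   carries numerator, noise_term, signal_dispersion_term, sigma2_g, sigma2_e
#'   and var_g_test (variance of predicted test genetic values, used by the
#'   optimization constraint).
#' @export
ethacc <- function(panel, split, causal, vc, divisor = c("n", "n-1")) {
  stopifnot(inherits(panel, "genotype_panel"))
  divisor <- match.arg(divisor)
  design <- suppressWarnings(center_design(panel, split))
  p <- length(causal$qtl_indices)
  if (p == 0) {
    warning("empty causal model: EthAcc set to 0 by convention", call. = FALSE)
    return(accuracy_estimate(0, "EthAcc",
                             components = list(numerator = 0, noise_term = NA,
                                               signal_dispersion_term = NA,
                                               sigma2_g = 0,
                                               sigma2_e = causal$sigma2_e,
                                               var_g_test = 0)))
  }
  qi <- causal$qtl_indices
  X <- panel$dosages
  qmu <- colMeans(X[split$train, qi, drop = FALSE])
  Qc_train <- sweep(X[split$train, qi, drop = FALSE], 2, qmu)
  Qc_test <- sweep(X[split$test, qi, drop = FALSE], 2, qmu)
  ethacc_components(design$Xc_train, design$Xc_test, Qc_train, Qc_test,
                    causal$theta, causal$sigma2_e, vc$lambda, divisor)
}

#' EthAcc from explicit design and QTL matrices
#'
#' Low-level evaluation of the theoretical accuracy formula; see
#' \code{\link{ethacc}} for the definition. All matrices must already be
#' column-centered on the training means.
#'
#' @param Xc_train,Xc_test centered SNP design matrices (T x M, n_test x M).
#' @param Qc_train,Qc_test centered QTL genotype matrices (T x p, n_test x p).
#' @param theta QTL effect vector (length p).
#' @param sigma2_e residual variance of the causal-QTL model (> 0 unless
#'   theta is informative enough that sigma2_g > 0).
#' @param lambda ridge ratio sigma2_eps / sigma2_beta.
#' @param divisor \code{"n"} or \code{"n-1"} for sample moments.
#' @return an \code{accuracy_estimate} with method "EthAcc".
#' @export
ethacc_components <- function(Xc_train, Xc_test, Qc_train, Qc_test, theta,
                              sigma2_e, lambda, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  n_test <- nrow(Xc_test)
  theta <- as.numeric(theta)
  adj <- if (divisor == "n") 1 else n_test / (n_test - 1)
  H <- ridge_matrix(Xc_train, lambda)

  # All test-side population moments of the theory (E(q x'), Var(x),
  # Var(g), E||.||^2) are zero-mean in the test individual's genotype
  # distribution; their sample plug-ins therefore center the test rows on
  # the TEST column means. Without this, a mean shift between test set and
  # training population (structured panels) injects a mu_g * mu_u cross
  # term into the numerator and the estimate is no longer a correlation.
  Xt <- sweep(Xc_test, 2, colMeans(Xc_test))
  Qt <- sweep(Qc_test, 2, colMeans(Qc_test))

  # numerator: theta' A Xc' H^{-1} Qc theta, A = (1/n) sum q_i x_i'
  A <- crossprod(Qt, Xt) / n_test                    # p x M
  v <- solve(H, drop(Qc_train %*% theta))            # H^{-1} Qc theta, T
  w <- drop(crossprod(Xc_train, v))                  # Xc' H^{-1} Qc theta, M
  numerator <- sum(drop(crossprod(A, theta)) * w) * adj

  # noise: sigma2_e * mean_i || H^{-1} Xc x_i ||^2
  P <- tcrossprod(Xc_train, Xt)                      # T x n, col i = Xc x_i
  S <- solve(H, P)
  noise <- sigma2_e * mean(colSums(S^2))

  # signal dispersion: w' V w = mean_i ((x_i - xbar)' w)^2
  xw <- drop(Xt %*% w)
  signal <- mean(xw^2) * adj

  # test genetic values under the causal model
  g <- drop(Qt %*% theta)
  sigma2_g <- mean(g^2) * adj

  if (sigma2_g + sigma2_e <= 0)
    stop("degenerate causal model: sigma2_g + sigma2_e = 0", call. = FALSE)
  denom <- sqrt(noise + signal) * sqrt(sigma2_g + sigma2_e)
  value <- if (denom > 0) numerator / denom else 0
  accuracy_estimate(value, "EthAcc",
                    components = list(numerator = numerator,
                                      noise_term = noise,
                                      signal_dispersion_term = signal,
                                      sigma2_g = sigma2_g,
                                      sigma2_e = sigma2_e,
                                      var_g_test = sigma2_g))
}
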