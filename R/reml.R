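# Restricted-likelihood machinery for models of the form
#   y = W tau + u + e,  u ~ N(0, sigma2_u * K),  e ~ N(0, lambda * sigma2_u * I)
# profiled over sigma2_u and optimized in log(lambda) after a one-time
# eigendecomposition K = U D U'. With K = Xc Xc' this is the RR-BLUP model
# (sigma2_u = sigma2_beta, lambda = sigma2_eps / sigma2_beta); with a VanRaden
# K it is the polygenic GWAS null model.

# Restricted log-likelihood profiled in sigma2_u, at a given lambda.
# dvals: eigenvalues of K; ytil/Wtil: rotated response/fixed effects.
reml_profile <- function(log_lambda, dvals, ytil, Wtil, logdetWW) {
  lam <- exp(log_lambda)
  n <- length(ytil)
  q <- ncol(Wtil)
  s <- 1 / sqrt(dvals + lam)
  A <- Wtil * s
  b <- ytil * s
  qrA <- qr(A)
  r <- qr.resid(qrA, b)
  rss <- sum(r^2)
  R <- qr.R(qrA)
  logdetWVW <- 2 * sum(log(abs(diag(R))))
  ll <- 0.5 * ((n - q) * log((n - q) / (2 * pi)) - (n - q) -
                 (n - q) * log(rss) - sum(log(dvals + lam)) -
                 logdetWVW + logdetWW)
  list(loglik = ll, rss = rss, qrA = qrA, b = b, s = s)
}

# Maximize the profiled restricted likelihood in log(lambda) on
# [lower, upper]; returns lambda, variance components and the whitened
# regression pieces at the optimum (reused by the marker scan).
reml_fit_eigen <- function(y, W, eig, lower = -10, upper = 10, tol = 1e-8) {
  n <- length(y)
  q <- ncol(W)
  dvals <- pmax(eig$values, 0)
  ytil <- drop(crossprod(eig$vectors, y))
  Wtil <- crossprod(eig$vectors, W)
  logdetWW <- determinant(crossprod(W), logarithm = TRUE)$modulus
  f <- function(ll) reml_profile(ll, dvals, ytil, Wtil, logdetWW)$loglik
  opt <- stats::optimize(f, interval = c(lower, upper), maximum = TRUE,
                         tol = tol)
  cand <- c(opt$maximum, lower, upper)
  vals <- c(opt$objective, f(lower), f(upper))
  best <- which.max(vals)
  log_lambda <- cand[best]
  at_boundary <- best > 1 || log_lambda <= lower + 1e-3 ||
    log_lambda >= upper - 1e-3
  prof <- reml_profile(log_lambda, dvals, ytil, Wtil, logdetWW)
  sigma2_u <- prof$rss / (n - q)
  list(lambda = exp(log_lambda), log_lambda = log_lambda,
       sigma2_u = sigma2_u, sigma2_e = exp(log_lambda) * sigma2_u,
       loglik = prof$loglik, boundary = at_boundary,
       dvals = dvals, ytil = ytil, Wtil = Wtil,
       s = prof$s, qrA = prof$qrA, b = prof$b, U = eig$vectors)
}

#' Variance components of the RR-BLUP model by REML
#'
#' Fits y = 1 mu + Xc beta + eps with beta ~ N(0, sigma2_beta I) and
#' eps ~ N(0, sigma2_eps I) by restricted maximum likelihood. The marginal
#' covariance is sigma2_beta (Xc Xc' + lambda I) with lambda =
#' sigma2_eps / sigma2_beta, so a single eigendecomposition of Xc Xc' reduces
#' REML to a one-dimensional search over log(lambda) (Brent, tolerance 1e-8 on
#' the log scale, bounds [-10, 10]). Solutions at the bounds are flagged: the
#' upper bound corresponds to no detectable marker variance.
#'
#' @param y_train numeric response vector (length T >= 3, not constant).
#' @param Xc_train column-centered training design (T x M), e.g.
#'   \code{center_design(...)$Xc_train}.
#' @param lower,upper bounds for log(lambda), natural log.
#' @return object of class \code{variance_components}: \code{sigma2_beta},
#'   \code{sigma2_eps}, \code{lambda} (= sigma2_eps/sigma2_beta),
#'   \code{loglik}, \code{boundary}.
#' @export
reml_variance_components <- function(y_train, Xc_train, lower = -10,
                                     upper = 10) {
  y_train <- as.numeric(y_train)
  T_ <- length(y_train)
  if (T_ < 3) stop("need at least 3 training individuals", call. = FALSE)
  if (stats::sd(y_train) == 0)
    stop("constant phenotype: variance components are not identifiable",
         call. = FALSE)
  if (nrow(Xc_train) != T_)
    stop("Xc_train rows must match length(y_train)", call. = FALSE)
  K <- tcrossprod(Xc_train)
  eig <- eigen(K, symmetric = TRUE)
  fit <- reml_fit_eigen(y_train, matrix(1, T_, 1), eig, lower, upper)
  variance_components(sigma2_beta = fit$sigma2_u, sigma2_eps = fit$sigma2_e,
                      loglik = fit$loglik, boundary = fit$boundary)
}

#' Construct a variance_components object
#'
#' @param sigma2_beta marker-effect variance (> 0).
#' @param sigma2_eps residual variance (>= 0).
#' @param loglik restricted log-likelihood at the optimum (optional).
#' @param boundary logical; TRUE if the REML search ended on a bound.
#' @return object of class \code{variance_components} with the ridge ratio
#'   \code{lambda = sigma2_eps / sigma2_beta}.
#' @export
variance_components <- function(sigma2_beta, sigma2_eps, loglik = NA_real_,
                                boundary = FALSE) {
  if (sigma2_beta <= 0) stop("sigma2_beta must be > 0", call. = FALSE)
  if (sigma2_eps < 0) stop("sigma2_eps must be >= 0", call. = FALSE)
  structure(list(sigma2_beta = sigma2_beta, sigma2_eps = sigma2_eps,
                 lambda = sigma2_eps / sigma2_beta,
                 loglik = loglik, boundary = boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components: sigma2_beta = %.4g, sigma2_eps = %.4g, lambda = %.4g%s\n",
              x$sigma2_beta, x$sigma2_eps, x$lambda,
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  invisible(x)
}
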