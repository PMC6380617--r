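#' Single-marker mixed-model GWAS scan
#'
#' Fits the polygenic null model y = 1 mu + X_cof gamma + u + e with
#' u ~ N(0, sigma2_u K) and e ~ N(0, sigma2_res I) by REML (one
#' eigendecomposition of K, Brent search over the variance ratio), then tests
#' every non-cofactor marker by a 1-df F test of its effect added to the null,
#' with variance components held at the null fit (the P3D shortcut). No
#' population-structure fixed effects are included: structure is absorbed by
#' the kinship.
#'
#' @param y phenotype vector (length T).
#' @param X dosage matrix (T x M) or a \code{genotype_panel} whose rows match
#'   \code{y}.
#' @param K T x T kinship matrix (e.g. \code{\link{vanraden_kinship}});
#'   computed from \code{X} if NULL.
#' @param cofactors integer indices of markers currently in the model as
#'   fixed effects.
#' @param eig optional precomputed \code{eigen(K, symmetric = TRUE)} (reused
#'   across forward-selection steps).
#' @return object of class \code{gwas_scan}: \code{p_values} (NaN for
#'   cofactors and collinear markers), \code{effect_estimates},
#'   \code{pseudo_h2} = sigma2_u / (sigma2_u + sigma2_res) of the null model,
#'   \code{cofactors}, \code{vc} (null-model components).
#' @export
gwas_scan <- function(y, X, K = NULL, cofactors = integer(0), eig = NULL) {
  if (inherits(X, "genotype_panel")) X <- X$dosages
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  M <- ncol(X)
  cofactors <- as.integer(cofactors)
  if (is.null(eig)) {
    if (is.null(K)) K <- vanraden_kinship(X)
    eig <- eigen(K, symmetric = TRUE)
  }
  W <- cbind(1, X[, cofactors, drop = FALSE])
  if (qr(W)$rank < ncol(W))
    stop("cofactor columns collinear with the intercept", call. = FALSE)
  fit <- reml_fit_eigen(y, W, eig)
  q <- ncol(W)
  pseudo_h2 <- 1 / (1 + fit$lambda)

  # whitened, rotated regression pieces at the null optimum
  bres <- qr.resid(fit$qrA, fit$b)        # residual of whitened y on null W
  rss0 <- sum(bres^2)
  Z <- crossprod(fit$U, X) * fit$s        # whitened rotated markers, n x M
  Zres <- Z - qr.fitted(fit$qrA, Z)       # residualized on null fixed effects
  znorm2 <- colSums(Zres^2)
  zy <- colSums(Zres * bres)
  df2 <- n - q - 1
  tol <- 1e-10 * pmax(colSums(Z^2), 1)
  ok <- znorm2 > tol
  effect <- ifelse(ok, zy / znorm2, NaN)
  rss1 <- pmax(rss0 - ifelse(ok, zy^2 / znorm2, 0), 0)
  Fstat <- ifelse(ok, (rss0 - rss1) / (rss1 / df2), NaN)
  p <- ifelse(ok, stats::pf(Fstat, 1, df2, lower.tail = FALSE), NaN)
  p[cofactors] <- NaN
  effect[cofactors] <- NaN
  if (any(!ok & !(seq_len(M) %in% cofactors)))
    warning("marker(s) collinear with cofactors: p-value set to NaN",
            call. = FALSE)
  structure(list(p_values = p, effect_estimates = effect,
                 pseudo_h2 = pseudo_h2, cofactors = cofactors,
                 vc = list(sigma2_u = fit$sigma2_u, sigma2_res = fit$sigma2_e,
                           lambda = fit$lambda, boundary = fit$boundary)),
            class = "gwas_scan")
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf("gwas_scan: %d markers, %d cofactor(s), pseudo-h2 = %.3f\n",
              length(x$p_values), length(x$cofactors), x$pseudo_h2))
  invisible(x)
}

#' MLMM forward-selection estimate of a causal-QTL model
#'
#' Multilocus mixed model: iteratively runs \code{\link{gwas_scan}}, adds the
#' minimum-p marker to the fixed effects (ties broken by lowest column index),
#' and re-estimates variance components, stopping when the polygenic
#' pseudo-heritability of the null model drops below \code{h2_stop} (the
#' selected SNPs then explain essentially all genetic variability) or when
#' \code{max_qtls} cofactors have been added. The selected markers are the
#' causal QTLs; their effects and the residual variance are re-estimated
#' jointly by OLS (\code{\link{fit_causal_ols}}), not taken from the mixed
#' model.
#'
#' @inheritParams gwas_scan
#' @param max_qtls cap on selected QTLs; default floor(T/10).
#' @param h2_stop stopping threshold on the polygenic pseudo-heritability
#'   (default 0.01).
#' @return a \code{causal_model}; its \code{steps} attribute records the
#'   pseudo-h2 trajectory and entry p-values.
#' @export
mlmm <- function(y, X, K = NULL, max_qtls = NULL, h2_stop = 0.01) {
  if (inherits(X, "genotype_panel")) X <- X$dosages
  X <- as.matrix(X)
  y <- as.numeric(y)
  T_ <- length(y)
  if (is.null(max_qtls)) max_qtls <- floor(T_ / 10)
  if (max_qtls > T_ - 2)
    stop("max_qtls must be at most T - 2", call. = FALSE)
  if (is.null(K)) K <- vanraden_kinship(X)
  eig <- eigen(K, symmetric = TRUE)
  cof <- integer(0)
  steps <- list()
  repeat {
    scan <- gwas_scan(y, X, K = K, cofactors = cof, eig = eig)
    steps[[length(steps) + 1]] <- list(pseudo_h2 = scan$pseudo_h2,
                                       n_cofactors = length(cof))
    if (scan$pseudo_h2 < h2_stop || length(cof) >= max_qtls) break
    p <- scan$p_values
    if (all(is.nan(p))) break
    pm <- min(p, na.rm = TRUE)
    add <- which(p == pm)[1]   # ties: lowest column index
    steps[[length(steps)]]$entered <- add
    steps[[length(steps)]]$entry_p <- pm
    cof <- c(cof, add)
  }
  model <- fit_causal_ols(y, X[, cof, drop = FALSE], qtl_indices = cof,
                          marker_ids = colnames(X)[cof], method = "mlmm")
  attr(model, "steps") <- steps
  model
}

#' Fit a causal-QTL model by ordinary least squares
#'
#' Joint OLS of the phenotype on an intercept and the selected QTL genotypes;
#' penalized or mixed-model effect estimates are deliberately not reused
#' because they are shrunken/biased. Collinear QTL columns are dropped (with a
#' warning) via pivoted QR. The residual variance is RSS / (T - p - 1).
#'
#' @param y phenotype vector (length T).
#' @param Q T x p matrix of QTL genotypes (p may be 0).
#' @param qtl_indices marker column indices corresponding to Q's columns.
#' @param marker_ids optional marker names.
#' @param method tag recorded on the model (default "ols").
#' @return object of class \code{causal_model}: \code{qtl_indices},
#'   \code{theta}, \code{intercept}, \code{sigma2_e}, \code{method}.
#' @export
fit_causal_ols <- function(y, Q, qtl_indices = seq_len(NCOL(Q)),
                           marker_ids = NULL, method = "ols") {
  y <- as.numeric(y)
  T_ <- length(y)
  Q <- as.matrix(Q)
  p <- ncol(Q)
  if (p > T_ - 2) stop("more QTLs than T - 2", call. = FALSE)
  if (p == 0) {
    return(causal_model(integer(0), numeric(0), mean(y), stats::var(y),
                        method = method))
  }
  W <- cbind(`(Intercept)` = 1, Q)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    keep_cols <- sort(qrW$pivot[seq_len(qrW$rank)])
    if (!1 %in% keep_cols)
      stop("causal model rank-deficient even against the intercept",
           call. = FALSE)
    dropped <- setdiff(seq_len(ncol(W)), keep_cols)
    warning(sprintf("%d collinear QTL column(s) dropped from the causal model",
                    length(dropped)), call. = FALSE)
    qsel <- keep_cols[keep_cols > 1] - 1
    Q <- Q[, qsel, drop = FALSE]
    qtl_indices <- qtl_indices[qsel]
    if (!is.null(marker_ids)) marker_ids <- marker_ids[qsel]
    W <- cbind(1, Q)
    qrW <- qr(W)
    p <- ncol(Q)
  }
  cf <- qr.coef(qrW, y)
  res <- qr.resid(qrW, y)
  sigma2_e <- sum(res^2) / (T_ - p - 1)
  theta <- cf[-1]
  if (!is.null(marker_ids)) names(theta) <- marker_ids
  causal_model(qtl_indices, theta, unname(cf[1]), sigma2_e, method = method)
}

#' Construct a causal_model object
#'
#' @param qtl_indices ordered marker column indices.
#' @param theta OLS effect vector (same length).
#' @param intercept intercept of the causal linear model.
#' @param sigma2_e residual variance (>= 0).
#' @param method tag: "mlmm", "lasso_min", "lasso_1se", "en", "ols", ...
#' @return object of class \code{causal_model}.
#' @export
causal_model <- function(qtl_indices, theta, intercept, sigma2_e,
                         method = "ols") {
  qtl_indices <- as.integer(qtl_indices)
  if (anyDuplicated(qtl_indices)) stop("duplicate QTL indices", call. = FALSE)
  if (length(theta) != length(qtl_indices))
    stop("theta and qtl_indices length mismatch", call. = FALSE)
  if (sigma2_e < 0) stop("sigma2_e must be >= 0", call. = FALSE)
  structure(list(qtl_indices = qtl_indices, theta = as.numeric(theta),
                 intercept = intercept, sigma2_e = sigma2_e, method = method),
            class = "causal_model")
}

#' @export
print.causal_model <- function(x, ...) {
  cat(sprintf("causal_model (%s): %d QTL(s), sigma2_e = %.4g\n",
              x$method, length(x$qtl_indices), x$sigma2_e))
  if (length(x$qtl_indices))
    cat("  indices:", paste(x$qtl_indices, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.causal_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept,
    stats::setNames(object$theta, paste0("q", object$qtl_indices)))
}

#' Genetic values under a causal model
#'
#' @param object a \code{causal_model}.
#' @param X dosage matrix or genotype_panel providing the QTL columns.
#' @param ... unused.
#' @return numeric vector intercept + Q theta.
#' @export
predict.causal_model <- function(object, X, ...) {
  if (inherits(X, "genotype_panel")) X <- X$dosages
  if (length(object$qtl_indices) == 0)
    return(rep(object$intercept, nrow(X)))
  drop(object$intercept +
         X[, object$qtl_indices, drop = FALSE] %*% object$theta)
}
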