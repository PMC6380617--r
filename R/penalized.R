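#' Locate QTLs by penalized regression (LASSO / elastic net)
#'
#' Runs a coordinate-descent elastic-net path (glmnet) with k-fold
#' cross-validation and returns the indices of markers with non-zero
#' coefficients at the selected penalty. The penalty is chosen either at the
#' minimum cross-validated MSE (\code{"cv_min"}) or at the largest lambda
#' within one standard error of that minimum (\code{"cv_1se"}, usually
#' sparser). The returned indices are a LOCATION estimate only: penalized
#' coefficients are biased, so effects should be re-estimated with
#' \code{\link{fit_causal_ols}}.
#'
#' @param y phenotype vector (length T).
#' @param X dosage matrix (T x M) or genotype_panel.
#' @param method \code{"lasso"} (alpha forced to 1) or \code{"en"}.
#' @param alpha elastic-net mixing parameter in (0, 1]; typical EN choices
#'   are 0.5 and 0.1.
#' @param lambda_rule \code{"cv_min"} or \code{"cv_1se"}.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return integer vector of selected marker column indices (may be empty),
#'   with the chosen lambda as attribute \code{"lambda"}.
#' @export
penalized_locate <- function(y, X, method = c("lasso", "en"), alpha = 1,
                             lambda_rule = c("cv_min", "cv_1se"), folds = 10,
                             seed = 1) {
  method <- match.arg(method)
  lambda_rule <- match.arg(lambda_rule)
  if (inherits(X, "genotype_panel")) X <- X$dosages
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (folds < 2) stop("need at least 2 CV folds", call. = FALSE)
  if (n < folds) stop("fewer samples than CV folds", call. = FALSE)
  if (method == "lasso") alpha <- 1
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                             standardize = TRUE)
  lam <- if (lambda_rule == "cv_min") cvfit$lambda.min else cvfit$lambda.1se
  beta <- stats::coef(cvfit, s = lam)[-1]
  idx <- which(as.numeric(beta) != 0)
  attr(idx, "lambda") <- lam
  idx
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
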