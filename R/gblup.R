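#' Ridge matrix of the RR-BLUP model
#'
#' H = Xc Xc' + lambda I, the T x T system matrix through which all BLUP
#' computations are routed. Unlike a VanRaden kinship, H is always positive
#' definite for lambda > 0, which is why the ridge-matrix route is preferred
#' over Henderson's equations when the kinship is singular.
#'
#' @param Xc_train column-centered training design (T x M).
#' @param vc a \code{variance_components} object, or a positive scalar ridge
#'   ratio lambda.
#' @return T x T symmetric positive-definite matrix.
#' @export
ridge_matrix <- function(Xc_train, vc) {
  lambda <- if (inherits(vc, "variance_components")) vc$lambda else vc
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda must be finite and > 0", call. = FALSE)
  H <- tcrossprod(Xc_train)
  diag(H) <- diag(H) + lambda
  H
}

#' GBLUP/RR-BLUP prediction of test genetic values
#'
#' Predicts u_test = Xc_test Xc_train' H^{-1} (y_train - mean(y_train)).
#' The intercept is absorbed by centering the response; with column-centered
#' genotypes this is the exact GLS intercept, so no fixed-effect solve is
#' needed. Equivalent to kinship-form GBLUP built on the unnormalized Xc Xc'
#' relationship matrix.
#'
#' @param y_train training phenotypes (length T).
#' @param design a \code{centered_design}.
#' @param vc a \code{variance_components} object (or scalar lambda).
#' @return numeric vector of predicted genetic values for the test rows.
#' @export
gblup_predict <- function(y_train, design, vc) {
  stopifnot(inherits(design, "centered_design"))
  y_train <- as.numeric(y_train)
  if (length(y_train) != nrow(design$Xc_train))
    stop("y_train length must match the training design", call. = FALSE)
  H <- ridge_matrix(design$Xc_train, vc)
  yc <- y_train - mean(y_train)
  alpha <- solve(H, yc)
  drop(design$Xc_test %*% crossprod(design$Xc_train, alpha))
}

#' Fit an RR-BLUP genomic prediction model
#'
#' Convenience fit over a panel and split: centers the design on the training
#' rows, estimates variance components by REML, and stores everything needed
#' for prediction. This is the whole-genome regression model
#' y = 1 mu + Xc beta + eps, beta ~ N(0, sigma2_beta I).
#'
#' @param y phenotype vector over all panel samples (or named over ids).
#' @param panel a \code{genotype_panel}.
#' @param split a \code{train_test_split}.
#' @return object of class \code{rrblup} with elements \code{vc}
#'   (variance_components), \code{design} (centered_design), \code{y_train},
#'   \code{mu} (training phenotype mean), \code{split}.
#' @export
rrblup <- function(y, panel, split) {
  stopifnot(inherits(panel, "genotype_panel"))
  y <- align_phenotype(y, panel)
  design <- center_design(panel, split)
  y_train <- y[split$train]
  vc <- reml_variance_components(y_train, design$Xc_train)
  structure(list(vc = vc, design = design, y_train = y_train,
                 mu = mean(y_train), split = split,
                 marker_ids = panel$marker_ids[design$kept]),
            class = "rrblup")
}

align_phenotype <- function(y, panel) {
  if (!is.null(names(y)) && all(panel$sample_ids %in% names(y)))
    return(as.numeric(y[panel$sample_ids]))
  if (length(y) != nrow(panel$dosages))
    stop("phenotype length must match the panel (or carry sample names)",
         call. = FALSE)
  as.numeric(y)
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("rrblup fit: T = %d training, %d markers, %d test\n",
              nrow(x$design$Xc_train), ncol(x$design$Xc_train),
              nrow(x$design$Xc_test)))
  print(x$vc)
  invisible(x)
}

#' @export
summary.rrblup <- function(object, ...) {
  vc <- object$vc
  M <- ncol(object$design$Xc_train)
  # genomic variance as mean diagonal of sigma2_beta * Xc Xc' over training
  sig_g <- vc$sigma2_beta * mean(rowSums(object$design$Xc_train^2))
  h2 <- sig_g / (sig_g + vc$sigma2_eps)
  out <- list(vc = vc, n_train = nrow(object$design$Xc_train),
              n_test = nrow(object$design$Xc_test), n_markers = M,
              genomic_variance = sig_g, pseudo_h2 = h2)
  class(out) <- "summary.rrblup"
  out
}

#' @export
print.summary.rrblup <- function(x, ...) {
  cat(sprintf("RR-BLUP model: %d training / %d test individuals, %d markers\n",
              x$n_train, x$n_test, x$n_markers))
  print(x$vc)
  cat(sprintf("  genomic variance (train): %.4g, pseudo-h2: %.3f\n",
              x$genomic_variance, x$pseudo_h2))
  invisible(x)
}

#' @export
coef.rrblup <- function(object, ...) {
  # BLUP marker effects beta_hat = Xc' H^{-1} (y - ybar)
  H <- ridge_matrix(object$design$Xc_train, object$vc)
  alpha <- solve(H, object$y_train - object$mu)
  b <- drop(crossprod(object$design$Xc_train, alpha))
  names(b) <- object$marker_ids
  b
}

#' Predict genetic values from an rrblup fit
#'
#' @param object an \code{rrblup} fit.
#' @param what \code{"test"} (default) for the stored test rows,
#'   \code{"train"} for fitted training genetic values.
#' @param ... unused.
#' @return numeric vector of predicted genetic values (phenotype scale offsets
#'   from the training mean).
#' @export
predict.rrblup <- function(object, what = c("test", "train"), ...) {
  what <- match.arg(what)
  H <- ridge_matrix(object$design$Xc_train, object$vc)
  alpha <- solve(H, object$y_train - object$mu)
  X <- if (what == "test") object$design$Xc_test else object$design$Xc_train
  drop(X %*% crossprod(object$design$Xc_train, alpha))
}

#' @export
residuals.rrblup <- function(object, ...) {
  object$y_train - object$mu - predict(object, what = "train")
}

#' @export
fitted.rrblup <- function(object, ...) {
  object$mu + predict(object, what = "train")
}
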