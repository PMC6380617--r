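#' Construct an accuracy estimate
#'
#' Container for a scalar accuracy value with its method tag, per-test
#' diagnostics and (for EthAcc) the formula components.
#'
#' @param value scalar accuracy.
#' @param method one of "TS", "CD", "PEV", "EthAcc", "CDmean".
#' @param per_test optional vector of per-individual components.
#' @param components optional named list of scalar diagnostics.
#' @return object of class \code{accuracy_estimate}.
#' @export
accuracy_estimate <- function(value, method, per_test = NULL,
                              components = NULL) {
  structure(list(value = value, method = method, per_test = per_test,
                 components = components),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("accuracy estimate (%s): %.4f\n", x$method, x$value))
  if (!is.null(x$components))
    cat("  components:",
        paste(sprintf("%s = %.4g", names(x$components),
                      unlist(x$components)), collapse = ", "), "\n")
  invisible(x)
}

#' Empirical test-set accuracy
#'
#' Pearson correlation between observed test phenotypes and their predicted
#' genetic values; the quantity every given-training-set estimator tries to
#' anticipate without using \code{y_test}.
#'
#' @param u_hat_test predicted genetic values.
#' @param y_test observed test phenotypes.
#' @return an \code{accuracy_estimate} with method "TS".
#' @export
ts_accuracy <- function(u_hat_test, y_test) {
  if (length(u_hat_test) != length(y_test))
    stop("length mismatch between predictions and phenotypes", call. = FALSE)
  if (length(y_test) < 3)
    stop("need at least 3 test individuals", call. = FALSE)
  if (stats::sd(y_test) == 0 || stats::sd(u_hat_test) == 0)
    stop("correlation undefined: constant input", call. = FALSE)
  accuracy_estimate(stats::cor(y_test, u_hat_test), "TS")
}

# shared CD_i machinery: for each centered test row x_i returns
#   xx_i   = x_i'x_i
#   cd_i   = (x_i' Xc' H^{-1} Xc x_i) / (x_i'x_i)
cd_components <- function(design, vc) {
  H <- ridge_matrix(design$Xc_train, vc)
  P <- tcrossprod(design$Xc_train, design$Xc_test)  # T x n_test, col i = Xc x_i
  S <- solve(H, P)
  quad <- colSums(P * S)                            # x_i' Xc' H^{-1} Xc x_i
  xx <- rowSums(design$Xc_test^2)
  list(xx = xx, quad = quad)
}

#' CD-based accuracy estimate
#'
#' Under the GBLUP model of the genetic value (every marker a QTL, iid
#' Gaussian effects), the coefficient of determination of test individual i is
#' CD_i = (x_i' Xc' H^{-1} Xc x_i) / (x_i' x_i), the squared correlation
#' between u_i and its BLUP. The phenotype-scale estimate averages
#' sqrt(h_i^2 * CD_i), where h_i^2 = Var(u_i) / (Var(u_i) + sigma2_eps) and
#' Var(u_i) = sigma2_beta x_i'x_i: accuracy against phenotype is the
#' genetic-value accuracy times the square root of heritability. Set
#' \code{sqrt_link = FALSE} for the plain average of h_i^2 * CD_i.
#'
#' @param design a \code{centered_design}.
#' @param vc a \code{variance_components} object.
#' @param sqrt_link logical; take sqrt of each per-test product (default).
#' @return an \code{accuracy_estimate} with method "CD"; \code{per_test}
#'   carries the CD_i.
#' @export
cd_accuracy <- function(design, vc, sqrt_link = TRUE) {
  cc <- cd_components(design, vc)
  cd <- ifelse(cc$xx > 0, cc$quad / cc$xx, 0)
  if (any(cc$xx == 0))
    warning("test individual(s) with zero centered genotype contribute 0",
            call. = FALSE)
  cd <- pmin(pmax(cd, 0), 1)
  var_u <- vc$sigma2_beta * cc$xx
  h2 <- ifelse(var_u > 0, var_u / (var_u + vc$sigma2_eps), 0)
  per <- h2 * cd
  if (sqrt_link) per <- sqrt(per)
  accuracy_estimate(mean(per), "CD", per_test = cd)
}

#' PEV-based accuracy estimate
#'
#' The prediction error variance of test individual i is
#' PEV_i = Var(u_i) - sigma2_beta x_i' Xc' H^{-1} Xc x_i, and the estimate
#' averages sqrt(h_i^2 * (1 - PEV_i / Var(u_i))). Since
#' 1 - PEV_i/Var(u_i) = CD_i identically, this coincides with
#' \code{\link{cd_accuracy}}; both are provided because they are derived and
#' reported separately in practice.
#'
#' @inheritParams cd_accuracy
#' @return an \code{accuracy_estimate} with method "PEV"; \code{per_test}
#'   carries the PEV_i.
#' @export
pev_accuracy <- function(design, vc, sqrt_link = TRUE) {
  cc <- cd_components(design, vc)
  var_u <- vc$sigma2_beta * cc$xx
  pev <- var_u - vc$sigma2_beta * cc$quad
  pev <- pmin(pmax(pev, 0), var_u)
  reliability <- ifelse(var_u > 0, 1 - pev / var_u, 0)
  if (any(cc$xx == 0))
    warning("test individual(s) with zero centered genotype contribute 0",
            call. = FALSE)
  h2 <- ifelse(var_u > 0, var_u / (var_u + vc$sigma2_eps), 0)
  per <- h2 * reliability
  if (sqrt_link) per <- sqrt(per)
  accuracy_estimate(mean(per), "PEV", per_test = pev)
}
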