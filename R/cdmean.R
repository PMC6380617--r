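#' CDmean training-set design criterion
#'
#' Mean coefficient of determination of the contrasts between each test
#' individual's genetic value and the mean genetic value of the combined
#' population (test + training individuals). With the combined centered design
#' Xc_all (N = T + n_test rows, columns centered on the combined set), the
#' training rows Xc_train of that design, and H = Xc_train Xc_train' +
#' lambda I:
#' \deqn{CD(c_i) = \frac{c_i' B c_i}{c_i' G c_i}, \quad
#'   B = X_{all} X_{tr}' H^{-1} X_{tr} X_{all}', \quad G = X_{all} X_{all}'}
#' with contrast c_i = e_i - 1/N. Variance components are estimated once on
#' the entire candidate panel and held fixed across training sets, which is
#' what makes CDmean cheap inside an optimization loop.
#'
#' @param panel a \code{genotype_panel}.
#' @param split a \code{train_test_split} (current training set + test set).
#' @param vc_panel \code{variance_components} estimated on the whole candidate
#'   panel (or a scalar lambda).
#' @return an \code{accuracy_estimate} with method "CDmean"; \code{per_test}
#'   carries the contrast CDs.
#' @export
cdmean <- function(panel, split, vc_panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  train <- split$train
  test <- split$test
  if (length(train) == 0) stop("empty training set", call. = FALSE)
  combined <- c(train, test)
  N <- length(combined)
  X <- panel$dosages[combined, , drop = FALSE]
  Xc_all <- sweep(X, 2, colMeans(X))
  tr_pos <- seq_along(train)
  te_pos <- length(train) + seq_along(test)
  Xc_tr <- Xc_all[tr_pos, , drop = FALSE]
  H <- ridge_matrix(Xc_tr, vc_panel)
  Ct <- tcrossprod(Xc_all, Xc_tr)        # N x T = Xc_all Xc_tr'
  B <- Ct %*% solve(H, t(Ct))
  G <- tcrossprod(Xc_all)
  cd <- vapply(te_pos, function(i) {
    # c' M c with c = e_i - 1/N
    num <- B[i, i] - 2 * mean(B[i, ]) + mean(B)
    den <- G[i, i] - 2 * mean(G[i, ]) + mean(G)
    if (den <= 1e-12) {
      warning("test contrast with zero genetic variance contributes 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }, numeric(1))
  cd <- pmin(pmax(cd, 0), 1)
  accuracy_estimate(mean(cd), "CDmean", per_test = cd)
}
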