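#' Train/test split over a genotype panel
#'
#' Holds the index sets of a prediction problem: training rows, test rows, and
#' the candidate pool from which training sets may be drawn during
#' optimization. Training and candidate indices must be disjoint from the test
#' indices, and the training set must lie inside the candidate pool.
#'
#' @param train integer vector of training row indices.
#' @param test integer vector of test row indices.
#' @param candidates integer vector of candidate row indices; defaults to
#'   \code{train}.
#' @param n panel size for bounds checking (optional).
#' @return an object of class \code{train_test_split}.
#' @export
train_test_split <- function(train, test, candidates = NULL, n = NULL) {
  train <- sort(unique(as.integer(train)))
  test <- sort(unique(as.integer(test)))
  if (is.null(candidates)) candidates <- train
  candidates <- sort(unique(as.integer(candidates)))
  if (length(train) == 0) stop("empty training set", call. = FALSE)
  if (length(intersect(train, test)))
    stop("train and test indices overlap", call. = FALSE)
  if (length(setdiff(train, candidates)))
    stop("training set is not contained in the candidate pool", call. = FALSE)
  if (length(intersect(candidates, test)))
    stop("candidate and test indices overlap", call. = FALSE)
  if (!is.null(n) && length(c(train, test, candidates)) &&
      (max(c(train, test, candidates)) > n || min(c(train, test, candidates)) < 1))
    stop("split indices out of panel bounds", call. = FALSE)
  structure(list(train = train, test = test, candidates = candidates),
            class = "train_test_split")
}

#' @export
print.train_test_split <- function(x, ...) {
  cat(sprintf("train_test_split: %d train / %d test / %d candidates\n",
              length(x$train), length(x$test), length(x$candidates)))
  invisible(x)
}

#' Center a genotype design on training column means
#'
#' Builds the column-centered design matrices required by the ridge-matrix
#' formulation: every genotype column must be orthogonal to the intercept on
#' the training side. Test rows are centered with the TRAINING column means,
#' so that prediction never uses test-set composition. Columns with zero
#' variance in the training subset are dropped from the design (with a
#' warning); their training column means are still recorded.
#'
#' @param panel a genotype_panel.
#' @param split a train_test_split (or a list with \code{train}/\code{test}).
#' @return an object of class \code{centered_design}: \code{Xc_train}
#'   (T x M'), \code{Xc_test} (n_test x M'), \code{column_means} (length-M,
#'   all markers), \code{kept} (indices of retained marker columns),
#'   \code{train}, \code{test} (row indices into the panel).
#' @export
center_design <- function(panel, split) {
  stopifnot(inherits(panel, "genotype_panel"))
  train <- split$train
  test <- split$test
  if (length(train) == 0) stop("empty training set", call. = FALSE)
  X <- panel$dosages
  mu <- colMeans(X[train, , drop = FALSE])
  Xc_train <- sweep(X[train, , drop = FALSE], 2, mu)
  keep <- colSums(Xc_train^2) > 1e-12
  if (!all(keep))
    warning(sprintf("%d marker(s) constant in the training subset dropped from the design",
                    sum(!keep)), call. = FALSE)
  Xc_train <- Xc_train[, keep, drop = FALSE]
  Xc_test <- sweep(X[test, , drop = FALSE], 2, mu)[, keep, drop = FALSE]
  structure(list(Xc_train = Xc_train, Xc_test = Xc_test,
                 column_means = mu, kept = which(keep),
                 train = train, test = test),
            class = "centered_design")
}

#' @export
print.centered_design <- function(x, ...) {
  cat(sprintf("centered_design: %d train x %d markers, %d test rows\n",
              nrow(x$Xc_train), ncol(x$Xc_train), nrow(x$Xc_test)))
  invisible(x)
}
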