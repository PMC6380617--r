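#' Hill-climbing training-set optimization with exchange moves
#'
#' Local search over fixed-size training sets: at each move one current member
#' and one outside candidate are drawn uniformly at random and swapped; the
#' swap is kept only if the criterion strictly improves and is not rejected by
#' a constraint. There is no stopping rule: exactly \code{n_moves} moves are
#' always performed (the search landscape has many flat plateaus and late
#' improvements, so early stopping is counterproductive). Every evaluation is
#' recorded in the trace.
#'
#' @param criterion_fn function of a training index vector returning either a
#'   numeric value or \code{list(value =, reject =)}; rejected sets are never
#'   accepted regardless of value.
#' @param start initial training index set.
#' @param candidates candidate pool (superset of \code{start}), disjoint from
#'   the test set by construction of the split.
#' @param n_moves number of exchange moves (default 5000).
#' @param seed integer RNG seed; the whole trajectory is reproducible from it.
#' @return object of class \code{ts_opt}: \code{final_train_idx},
#'   \code{best_value}, \code{start_train_idx}, \code{n_moves}, \code{seed},
#'   \code{trace} (data.frame move/value/accepted/rejected).
#' @export
hill_climb <- function(criterion_fn, start, candidates, n_moves = 5000,
                       seed = 1) {
  start <- sort(unique(as.integer(start)))
  candidates <- sort(unique(as.integer(candidates)))
  if (length(setdiff(start, candidates)))
    stop("start must be a subset of candidates", call. = FALSE)
  if (n_moves < 0) stop("n_moves must be >= 0", call. = FALSE)
  if (n_moves > 0 && length(candidates) < length(start) + 1)
    stop("no legal exchange move: candidate pool too small", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  eval_crit <- function(idx) {
    r <- criterion_fn(idx)
    if (is.list(r)) list(value = as.numeric(r$value),
                         reject = isTRUE(r$reject))
    else list(value = as.numeric(r), reject = FALSE)
  }

  current <- start
  r0 <- eval_crit(current)
  best <- if (r0$reject) -Inf else r0$value
  mv <- integer(n_moves); val <- numeric(n_moves)
  acc <- logical(n_moves); rej <- logical(n_moves)
  for (k in seq_len(n_moves)) {
    out_pool <- setdiff(candidates, current)
    drop_i <- current[sample.int(length(current), 1)]
    add_i <- out_pool[sample.int(length(out_pool), 1)]
    proposal <- sort(c(setdiff(current, drop_i), add_i))
    r <- eval_crit(proposal)
    accept <- !r$reject && r$value > best
    if (accept) {
      current <- proposal
      best <- r$value
    }
    mv[k] <- k; val[k] <- r$value; acc[k] <- accept; rej[k] <- r$reject
  }
  structure(list(final_train_idx = current, best_value = best,
                 start_train_idx = start, n_moves = n_moves, seed = seed,
                 trace = data.frame(move = mv, value = val, accepted = acc,
                                    rejected = rej)),
            class = "ts_opt")
}

#' @export
print.ts_opt <- function(x, ...) {
  cat(sprintf("ts_opt: %d moves (%d accepted), best criterion %.4f, |train| = %d\n",
              x$n_moves, sum(x$trace$accepted), x$best_value,
              length(x$final_train_idx)))
  invisible(x)
}

#' Plot a hill-climbing trace
#'
#' Accepted moves as filled points on the running-best line; rejected and
#' non-improving evaluations as light triangles.
#'
#' @param x a \code{ts_opt}.
#' @param ... passed to \code{plot}.
#' @export
plot.ts_opt <- function(x, ...) {
  tr <- x$trace
  plot(tr$move, tr$value, col = "grey70",
       pch = ifelse(tr$rejected, 4, 2), cex = 0.6,
       xlab = "exchange move", ylab = "criterion value", ...)
  if (any(tr$accepted))
    points(tr$move[tr$accepted], tr$value[tr$accepted], col = "red",
           pch = 19, cex = 0.8)
  invisible(x)
}

#' EthAcc optimization criterion
#'
#' Builds the per-training-set criterion the EthAcc optimizer maximizes. Each
#' evaluation re-runs the whole pipeline on the proposed training set: REML
#' variance components, MLMM causal-QTL discovery, then the EthAcc formula.
#' The phenotype must be standardized to unit variance beforehand
#' (\code{\link{standardize_phenotype}}); a set is REJECTED when the sample
#' variance (divisor n_test) of the predicted test genetic values under its
#' causal model is not strictly below 1, i.e. when the estimated genetic
#' variance would exceed the phenotypic variance. This constraint suppresses
#' false-positive training sets with inflated EthAcc.
#'
#' @param panel a \code{genotype_panel}.
#' @param y standardized phenotype over panel samples.
#' @param test_idx test row indices.
#' @param max_qtls,h2_stop MLMM settings per evaluation; defaults are reduced
#'   (\code{max_qtls = 10}) to bound per-move cost.
#' @param constraint logical; disable only for diagnostics of false positives.
#' @return function(train_idx) -> list(value, reject) for
#'   \code{\link{hill_climb}}.
#' @export
ethacc_criterion <- function(panel, y, test_idx, max_qtls = 10,
                             h2_stop = 0.01, constraint = TRUE) {
  y <- align_phenotype(y, panel)
  if (abs(stats::var(y) - 1) > 1e-6)
    stop("phenotype must be standardized to unit variance first; ",
         "see standardize_phenotype()", call. = FALSE)
  test_idx <- sort(unique(as.integer(test_idx)))
  X <- panel$dosages
  function(train_idx) {
    split <- train_test_split(train_idx, test_idx,
                              candidates = train_idx, n = nrow(X))
    y_tr <- y[split$train]
    design <- suppressWarnings(center_design(panel, split))
    vc <- reml_variance_components(y_tr, design$Xc_train)
    model <- suppressWarnings(
      mlmm(y_tr, X[split$train, , drop = FALSE],
           max_qtls = min(max_qtls, length(split$train) - 2),
           h2_stop = h2_stop))
    if (length(model$qtl_indices) == 0)
      return(list(value = 0, reject = FALSE))
    est <- suppressWarnings(ethacc(panel, split, model, vc))
    var_g <- est$components$var_g_test
    reject <- constraint && var_g >= 1 - 1e-12
    list(value = est$value, reject = reject)
  }
}

#' CDmean optimization criterion
#'
#' Delegates to \code{\link{cdmean}} with variance components estimated once
#' on the entire candidate panel (the standard CDmean protocol); no
#' constraint.
#'
#' @param panel a \code{genotype_panel}.
#' @param test_idx test row indices.
#' @param vc_panel precomputed whole-candidate-panel
#'   \code{variance_components}.
#' @return function(train_idx) -> numeric.
#' @export
cdmean_criterion <- function(panel, test_idx, vc_panel) {
  test_idx <- sort(unique(as.integer(test_idx)))
  function(train_idx) {
    split <- train_test_split(train_idx, test_idx, candidates = train_idx,
                              n = nrow(panel$dosages))
    suppressWarnings(cdmean(panel, split, vc_panel))$value
  }
}

#' Oracle test-set-accuracy criterion
#'
#' Uses the observed test phenotypes: REML + GBLUP on the proposed training
#' set, then the Pearson correlation with y_test. Only available in evaluation
#' settings where the test set is phenotyped; used to construct the "optimal
#' start" of criterion comparisons, and flagged as an oracle in reports.
#'
#' @param panel a \code{genotype_panel}.
#' @param y phenotype over all samples, including the test rows.
#' @param test_idx test row indices.
#' @return function(train_idx) -> numeric.
#' @export
ts_oracle_criterion <- function(panel, y, test_idx) {
  y <- align_phenotype(y, panel)
  test_idx <- sort(unique(as.integer(test_idx)))
  if (anyNA(y[test_idx]))
    stop("oracle criterion unavailable: test phenotypes missing",
         call. = FALSE)
  function(train_idx) {
    split <- train_test_split(train_idx, test_idx, candidates = train_idx,
                              n = nrow(panel$dosages))
    design <- suppressWarnings(center_design(panel, split))
    vc <- reml_variance_components(y[split$train], design$Xc_train)
    u <- gblup_predict(y[split$train], design, vc)
    ts_accuracy(u, y[split$test])$value
  }
}
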