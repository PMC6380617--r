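#' Experiment configuration
#'
#' Settings of the sampling protocol used to compare accuracy estimators and
#' training-set optimization criteria: a fraction of the panel is repeatedly
#' drawn as the test set (default 20%), the rest are candidates, and for each
#' draw the estimators are computed and (optionally) the training set is
#' optimized under each criterion.
#'
#' @param ts_fraction test-set fraction in (0, 1); default 0.20.
#' @param n_draws number of random test-set draws; default 30.
#' @param criteria character subset of c("ethacc", "cdmean", "ts_oracle");
#'   criteria to optimize under (may be empty for estimation-only runs).
#' @param train_size fixed training-set size; default 50% of the candidates.
#' @param n_moves exchange moves per optimization (default 5000).
#' @param optimal_start logical; start each criterion's climb from the
#'   training set found by maximizing the oracle TS accuracy (requires test
#'   phenotypes), the protocol that measures how much each criterion degrades
#'   the attainable maximum. Default FALSE (random start).
#' @param oracle_moves moves for the oracle-start search (default
#'   \code{n_moves}).
#' @param max_qtls,h2_stop MLMM settings used inside the EthAcc criterion.
#' @param seed master seed; draw d uses seed + d.
#' @return object of class \code{experiment_config}.
#' @export
experiment_config <- function(ts_fraction = 0.20, n_draws = 30,
                              criteria = c("cdmean"), train_size = NULL,
                              n_moves = 5000, optimal_start = FALSE,
                              oracle_moves = NULL, max_qtls = 10,
                              h2_stop = 0.01, seed = 1) {
  stopifnot(ts_fraction > 0, ts_fraction < 1, n_draws >= 1, n_moves >= 0)
  criteria <- match.arg(criteria, c("ethacc", "cdmean", "ts_oracle"),
                        several.ok = TRUE)
  structure(list(ts_fraction = ts_fraction, n_draws = n_draws,
                 criteria = criteria, train_size = train_size,
                 n_moves = n_moves, optimal_start = optimal_start,
                 oracle_moves = if (is.null(oracle_moves)) n_moves
                                else oracle_moves,
                 max_qtls = max_qtls, h2_stop = h2_stop,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

ts_accuracy_of <- function(panel, y, train_idx, test_idx) {
  split <- train_test_split(train_idx, test_idx, candidates = train_idx,
                            n = nrow(panel$dosages))
  design <- suppressWarnings(center_design(panel, split))
  vc <- reml_variance_components(y[split$train], design$Xc_train)
  u <- gblup_predict(y[split$train], design, vc)
  ts_accuracy(u, y[split$test])$value
}

#' Run the sampling/optimization experiment
#'
#' For each draw: sample the test set, form the candidate pool, draw a random
#' training set of the configured size, compute all accuracy estimators on it
#' (TS accuracy, CD, PEV, EthAcc with an MLMM causal model, CDmean), then for
#' each requested criterion run the hill-climber (from the oracle-optimal
#' start when \code{optimal_start}) and record the realized TS accuracy of the
#' final training set. Failed draws are recorded and skipped.
#'
#' @param panel a \code{genotype_panel}.
#' @param y phenotype over all panel samples; standardized internally to unit
#'   variance when the EthAcc criterion is active.
#' @param config an \code{experiment_config}.
#' @return object of class \code{experiment_result}: \code{estimates}
#'   (per-draw estimator table), \code{optimization} (per draw x criterion),
#'   \code{summary}, \code{config}, \code{failures}.
#' @export
run_experiment <- function(panel, y, config = experiment_config()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "experiment_config"))
  y <- align_phenotype(y, panel)
  y <- standardize_phenotype(y)
  n <- nrow(panel$dosages)
  n_test <- max(3, round(config$ts_fraction * n))
  est_rows <- list(); opt_rows <- list(); failures <- list()
  for (d in seq_len(config$n_draws)) {
    seed_d <- config$seed + d
    res <- tryCatch(
      run_one_draw(panel, y, config, d, seed_d, n_test),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(draw = d, seed = seed_d,
                                               message = conditionMessage(res))
      next
    }
    est_rows[[length(est_rows) + 1]] <- res$estimates
    opt_rows <- c(opt_rows, res$optimization)
  }
  estimates <- do.call(rbind, est_rows)
  optimization <- if (length(opt_rows)) do.call(rbind, opt_rows) else NULL
  summary <- summarize_experiment(estimates, optimization)
  structure(list(estimates = estimates, optimization = optimization,
                 summary = summary, config = config, failures = failures),
            class = "experiment_result")
}

run_one_draw <- function(panel, y, config, d, seed_d, n_test) {
  n <- nrow(panel$dosages)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed_d)
  test_idx <- sort(sample.int(n, n_test))
  cand <- setdiff(seq_len(n), test_idx)
  train_size <- if (is.null(config$train_size))
    max(4, floor(length(cand) / 2)) else config$train_size
  if (train_size >= length(cand))
    stop("train_size must leave at least one candidate out", call. = FALSE)
  start <- sort(sample(cand, train_size))

  split <- train_test_split(start, test_idx, candidates = cand, n = n)
  design <- suppressWarnings(center_design(panel, split))
  vc <- reml_variance_components(y[start], design$Xc_train)
  u <- gblup_predict(y[start], design, vc)
  model <- suppressWarnings(mlmm(y[start],
                                 panel$dosages[start, , drop = FALSE],
                                 max_qtls = min(config$max_qtls,
                                                train_size - 2),
                                 h2_stop = config$h2_stop))
  vc_panel <- local({
    sp <- train_test_split(cand, test_idx, candidates = cand, n = n)
    de <- suppressWarnings(center_design(panel, sp))
    reml_variance_components(y[cand], de$Xc_train)
  })
  estimates <- data.frame(
    draw = d, seed = seed_d, n_test = n_test, train_size = train_size,
    ts = ts_accuracy(u, y[test_idx])$value,
    cd = suppressWarnings(cd_accuracy(design, vc))$value,
    pev = suppressWarnings(pev_accuracy(design, vc))$value,
    ethacc = suppressWarnings(ethacc(panel, split, model, vc))$value,
    cdmean = suppressWarnings(cdmean(panel, split, vc_panel))$value)

  optimization <- list()
  if (length(config$criteria) && config$n_moves >= 0) {
    start_opt <- start
    if (config$optimal_start) {
      oracle <- hill_climb(ts_oracle_criterion(panel, y, test_idx),
                           start, cand, n_moves = config$oracle_moves,
                           seed = seed_d)
      start_opt <- oracle$final_train_idx
    }
    for (crit in config$criteria) {
      fn <- switch(crit,
        ethacc = ethacc_criterion(panel, y, test_idx,
                                  max_qtls = config$max_qtls,
                                  h2_stop = config$h2_stop),
        cdmean = cdmean_criterion(panel, test_idx, vc_panel),
        ts_oracle = ts_oracle_criterion(panel, y, test_idx))
      opt <- hill_climb(fn, start_opt, cand, n_moves = config$n_moves,
                        seed = seed_d)
      optimization[[crit]] <- data.frame(
        draw = d, seed = seed_d, criterion = crit,
        best_value = opt$best_value,
        n_accepted = sum(opt$trace$accepted),
        final_ts_accuracy = ts_accuracy_of(panel, y, opt$final_train_idx,
                                           test_idx),
        oracle_start = config$optimal_start)
    }
  }
  list(estimates = estimates, optimization = optimization)
}

summarize_experiment <- function(estimates, optimization) {
  out <- list(n_draws_completed = NROW(estimates))
  if (NROW(estimates)) {
    for (m in c("cd", "pev", "ethacc", "cdmean")) {
      out[[paste0("mean_", m)]] <- mean(estimates[[m]])
      out[[paste0("mse_", m)]] <- mean((estimates[[m]] - estimates$ts)^2)
    }
    out$mean_ts <- mean(estimates$ts)
  }
  if (!is.null(optimization)) {
    for (crit in unique(optimization$criterion)) {
      rows <- optimization[optimization$criterion == crit, ]
      out[[paste0("mean_final_ts_", crit)]] <- mean(rows$final_ts_accuracy)
    }
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d draw(s) completed, %d failed\n",
              x$summary$n_draws_completed, length(x$failures)))
  if (!is.null(x$summary$mean_ts))
    cat(sprintf("  mean TS accuracy %.3f | EthAcc MSE %.2e | CD MSE %.2e\n",
                x$summary$mean_ts, x$summary$mse_ethacc, x$summary$mse_cd))
  for (nm in grep("^mean_final_ts_", names(x$summary), value = TRUE))
    cat(sprintf("  %s = %.3f\n", nm, x$summary[[nm]]))
  invisible(x)
}

#' Write an experiment report
#'
#' Emits \code{<basename>.json} (schema-versioned summary: config, seeds,
#' summary statistics, failures) and \code{<basename>_estimates.tsv} /
#' \code{<basename>_optimization.tsv} with the per-draw rows.
#'
#' @param result an \code{experiment_result}.
#' @param basename output path prefix.
#' @return named list of the files written, invisibly.
#' @export
write_report <- function(result, basename) {
  stopifnot(inherits(result, "experiment_result"))
  files <- list(json = paste0(basename, ".json"),
                estimates = paste0(basename, "_estimates.tsv"))
  payload <- list(schema_version = 1L,
                  seed = result$config$seed,
                  config = unclass(result$config),
                  summary = result$summary,
                  failures = result$failures)
  jsonlite::write_json(payload, files$json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  utils::write.table(result$estimates, files$estimates, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(result$optimization)) {
    files$optimization <- paste0(basename, "_optimization.tsv")
    utils::write.table(result$optimization, files$optimization, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(files)
}

#' Read back an experiment report
#'
#' @param basename the prefix passed to \code{\link{write_report}}.
#' @return list with \code{meta} (parsed JSON), \code{estimates} and
#'   optionally \code{optimization} data frames. Reports without a seed field
#'   are rejected.
#' @export
read_report <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"),
                              simplifyVector = TRUE)
  if (is.null(meta$seed))
    stop("invalid report: missing seed field", call. = FALSE)
  out <- list(meta = meta,
              estimates = utils::read.delim(paste0(basename,
                                                   "_estimates.tsv")))
  opt_path <- paste0(basename, "_optimization.tsv")
  if (file.exists(opt_path)) out$optimization <- utils::read.delim(opt_path)
  out
}

#' Write a hill-climbing trace as TSV
#'
#' @param opt a \code{ts_opt}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(opt, path) {
  stopifnot(inherits(opt, "ts_opt"))
  utils::write.table(opt$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
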