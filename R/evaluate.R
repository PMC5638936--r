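# Evaluation statistics: concordance index, log-time prediction MSE,
# gene-selection counts, and the multi-seed benchmark harness.

#' Concordance index
#'
#' Over ordered pairs (i, j) with `t_i < t_j` and `delta_i = 1` (the
#' comparable pairs), the fraction with `f_i < f_j`; tied predictions
#' contribute 1/2. `pred` is a survival-duration score: larger means longer
#' predicted survival, so a Cox prognostic index must be negated before
#' scoring.
#'
#' @param pred predicted survival-duration scores.
#' @param time observed times.
#' @param status event indicators in {0, 1}.
#' @return CI in [0, 1].
#' @export
concordance_index <- function(pred, time, status) {
  n <- length(pred)
  if (n < 2 || length(time) != n || length(status) != n)
    stop_validation("need matching vectors of length >= 2")
  comp <- outer(time, time, "<") & (status == 1)   # [i,j]: t_i<t_j, d_i=1
  npairs <- sum(comp)
  if (npairs == 0) stop_validation("no comparable pairs")
  conc <- sum(comp & outer(pred, pred, "<")) +
    0.5 * sum(comp & outer(pred, pred, "=="))
  conc / npairs
}

#' Mean squared error of predicted log survival times
#'
#' Mean over `subset` of `(pred_log_time - log(true_times))^2`; by
#' convention evaluated on test samples against simulation ground truth.
#'
#' @param pred_log_time predicted log times.
#' @param true_times positive true survival times.
#' @param subset index set (default: all).
#' @return nonnegative scalar.
#' @export
time_mse <- function(pred_log_time, true_times,
                     subset = seq_along(true_times)) {
  if (!length(subset)) stop_validation("empty subset")
  mean((pred_log_time[subset] - log(true_times[subset]))^2)
}

#' Gene-selection metrics
#'
#' @param support indices selected by a fit.
#' @param true_support true nonzero indices.
#' @return list: `correct` = |support intersect true|, `total` = |support|,
#'   `accuracy` = correct/total (0 when nothing is selected).
#' @export
selection_metrics <- function(support, true_support) {
  correct <- length(intersect(support, true_support))
  total <- length(support)
  list(correct = correct, total = total,
       accuracy = if (total == 0) 0 else correct / total)
}

#' Method identifiers understood by the benchmark and the CLI
#' @export
spaft_methods <- function() {
  c("cox-sp-aft", "semi-cox", "cox-mcp", "cox-lasso", "cox-en")
}

method_family <- function(method) {
  switch(method, `cox-mcp` = "mcp", `cox-lasso` = "lasso",
         `cox-en` = "elastic_net",
         stop_validation("unknown supervised method: ", method))
}

# Run one method on one train/test split. Returns the Cox-side metrics
# (selection counts, test CI) and the AFT-side test log-time predictions.
# For the two semi-supervised methods the AFT prediction routes each test
# sample through its risk group's latest AFT fit; supervised methods use a
# penalized AFT fit on the labelled training samples with the same family.
run_method_once <- function(method, train, test, truth = NULL, seed = 1L,
                            base_config = NULL) {
  if (method %in% c("cox-sp-aft", "semi-cox")) {
    config <- base_config %||% pipeline_config()
    config$seed <- as.integer(seed)
    config$use_spl <- method == "cox-sp-aft"
    res <- run_cox_sp_aft(train, config)
    cox_fit <- res$final_cox
    rec <- res$std_record
    Xt <- apply_standardization(test$X, rec)
    pi_t <- prognostic_index(cox_fit, Xt)
    grp <- classify_risk(pi_t, threshold = res$threshold)$group
    pred_log <- rep(NA_real_, nrow(Xt))
    fallback <- NULL
    for (g in c("high", "low")) {
      gi <- which(grp == g)
      if (!length(gi)) next
      gf <- res$group_fits[[g]]
      if (!is.null(gf)) {
        pred_log[gi] <- predict(gf$fit, Xt[gi, , drop = FALSE])
      } else {
        if (is.null(fallback)) {
          aug <- res$augmented
          lab <- aug$status == 1
          Xa <- apply_standardization(aug$X, rec)
          fallback <- fit_penalized_aft(Xa[lab, , drop = FALSE],
                                        log(aug$time[lab]),
                                        config$aft_penalty)
        }
        pred_log[gi] <- predict(fallback, Xt[gi, , drop = FALSE])
      }
    }
    n_promoted <- sum(res$augmented$promoted)
  } else {
    fam <- method_family(method)
    cox_fit <- run_supervised_baseline(train, fam, seed = seed)
    rec <- attr(cox_fit, "std_record")
    Xt <- apply_standardization(test$X, rec)
    pi_t <- prognostic_index(cox_fit, Xt)
    Xs <- apply_standardization(train$X, rec)
    lab <- train$status == 1
    aft <- fit_penalized_aft(Xs[lab, , drop = FALSE], log(train$time[lab]),
                             penalty_spec(fam))
    pred_log <- predict(aft, Xt)
    n_promoted <- 0L
  }
  out <- list(method = method, cox_fit = cox_fit,
              support = cox_fit$support, pred_log_time = pred_log,
              ci = concordance_index(-pi_t, test$time, test$status),
              n_promoted = n_promoted,
              pipeline = if (method %in% c("cox-sp-aft", "semi-cox")) res)
  if (!is.null(truth)) {
    sel <- selection_metrics(match(names(cox_fit$beta)[cox_fit$support],
                                   names(truth$beta_true)),
                             truth$true_support)
    out$correct <- sel$correct
    out$total <- sel$total
    out$accuracy <- sel$accuracy
  }
  out
}

#' Multi-seed benchmark harness
#'
#' For each of `n_datasets` independently drawn true models, and each of
#' `n_repeats` train/test splits, runs every method and accumulates
#' per-method means of correct/total selected genes, test concordance index
#' and test log-time MSE (against simulation ground truth). Emits one table
#' per metric with a per-dataset row and an `Average` row. A single-method
#' failure on one repeat is logged (warning) and reported as `NA`, not an
#' abort. Deterministic given `seed`: child seeds stream per
#' (dataset, repeat, method), so growing `n_repeats` leaves earlier repeats
#' unchanged.
#'
#' @param config a [simulation_config()] (its `seed` field is ignored; seeds
#'   stream from `seed`).
#' @param methods subset of [spaft_methods()].
#' @param n_datasets,n_repeats benchmark dimensions (the full-scale design is
#'   10 datasets x 100 repeats).
#' @param n_train training samples per split.
#' @param seed master seed.
#' @param base_config optional [pipeline_config()] template for the
#'   semi-supervised methods.
#' @return object of class `benchmark_result`: `tables` (named list of
#'   dataset x method data frames with an Average row, one per metric:
#'   `correct`, `total`, `ci`, `mse`), and `repeats` (long per-repeat data
#'   frame).
#' @export
run_benchmark <- function(config = simulation_config(),
                          methods = spaft_methods(), n_datasets = 10,
                          n_repeats = 100, n_train = 200, seed = 1L,
                          base_config = NULL) {
  methods <- match.arg(methods, spaft_methods(), several.ok = TRUE)
  rows <- list()
  for (d in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- child_seed(seed, d, 0L)
    study <- simulate_study(cfg)
    for (r in seq_len(n_repeats)) {
      sp <- split_train_test(study$data, n_train, child_seed(seed, d, r))
      for (mi in seq_along(methods)) {
        m <- methods[mi]
        res <- tryCatch(
          run_method_once(m, sp$train, sp$test, study$truth,
                          seed = child_seed(seed, d, r, mi),
                          base_config = base_config),
          error = function(e) {
            warning(sprintf("method %s failed on dataset %d repeat %d: %s",
                            m, d, r, conditionMessage(e)))
            NULL
          })
        mse <- if (is.null(res)) NA_real_ else {
          test_idx <- match(sp$test$sample_ids, study$data$sample_ids)
          time_mse(res$pred_log_time, study$truth$true_times[test_idx])
        }
        rows[[length(rows) + 1]] <- data.frame(
          dataset = d, repeat_ = r, method = m,
          correct = if (is.null(res)) NA_real_ else res$correct,
          total = if (is.null(res)) NA_real_ else res$total,
          ci = if (is.null(res)) NA_real_ else res$ci,
          mse = mse,
          n_promoted = if (is.null(res)) NA_real_ else res$n_promoted)
      }
    }
  }
  long <- do.call(rbind, rows)
  tables <- lapply(c(correct = "correct", total = "total", ci = "ci",
                     mse = "mse"), function(metric) {
    agg <- stats::aggregate(long[[metric]],
                            by = list(dataset = long$dataset,
                                      method = long$method),
                            FUN = mean, na.rm = TRUE)
    tab <- stats::reshape(agg, idvar = "dataset", timevar = "method",
                          direction = "wide")
    names(tab) <- sub("^x\\.", "", names(tab))
    tab <- tab[order(tab$dataset), c("dataset", methods), drop = FALSE]
    avg <- c(dataset = NA, colMeans(tab[, methods, drop = FALSE]))
    tab <- rbind(tab, avg)
    tab$dataset <- c(as.character(seq_len(n_datasets)), "Average")
    rownames(tab) <- NULL
    tab
  })
  structure(list(tables = tables, repeats = long,
                 methods = methods, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> methods:", paste(x$methods, collapse = ", "), "\n")
  for (m in names(x$tables)) {
    cat("\n==", m, "==\n")
    print(x$tables[[m]], digits = 4)
  }
  invisible(x)
}
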