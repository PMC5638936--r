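# The outer Cox-SP-AFT semi-supervised loop, the no-SPL Semi-Cox ablation and
# the supervised penalized-Cox baselines.

#' Pipeline configuration
#'
#' @param cox_penalty [penalty_spec()] for the Cox stage (default MCP,
#'   cross-validated lambda re-tuned each outer round).
#' @param aft_penalty [penalty_spec()] shared by both risk groups' AFT stage.
#' @param sp an [sp_config()].
#' @param max_outer_rounds cap on outer Cox/SP-AFT rounds (default 5).
#' @param min_group_labeled minimum labelled samples a risk group needs for
#'   its AFT stage to run that round (default 10); smaller groups are skipped
#'   and logged, not an abort.
#' @param use_spl `FALSE` gives the Semi-Cox ablation (no self-paced
#'   selection; only censoring-constraint violators are excluded).
#' @param seed integer seed driving every random draw in the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cox_penalty = penalty_spec("mcp"),
                            aft_penalty = penalty_spec("mcp"),
                            sp = sp_config(), max_outer_rounds = 5,
                            min_group_labeled = 10, use_spl = TRUE,
                            seed = 1L) {
  if (max_outer_rounds < 1 || min_group_labeled < 1)
    stop_validation("counts must be positive")
  structure(list(cox_penalty = cox_penalty, aft_penalty = aft_penalty,
                 sp = sp, max_outer_rounds = max_outer_rounds,
                 min_group_labeled = min_group_labeled,
                 use_spl = isTRUE(use_spl), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the Cox-SP-AFT semi-supervised pipeline
#'
#' Per outer round: (1) fit a penalized Cox model on the current training set
#' (promoted pseudo-labelled samples count as events; not-yet-promoted
#' censored samples stay in the risk sets as ordinary censored
#' observations); (2) median-split all training samples into high/low risk by
#' prognostic index; (3) within each group run the self-paced AFT model
#' (or its no-SPL variant) on the group's labelled and censored samples —
#' previously promoted samples re-enter on the censored side, initialized
#' with their current pseudo-label, so their labels refresh; (4) censored
#' samples with terminal weight 1 whose pseudo time strictly exceeds their
#' censor time are promoted to labelled status (time `exp(pseudo_log_time)`,
#' status 1, provenance flag retained; promotions are never reverted);
#' (5) repeat until no new promotions or `max_outer_rounds`.
#'
#' @param train a [survival_dataset()]; expression is standardized
#'   internally.
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result`: `final_cox` (fit on the
#'   augmented labelled set), `augmented` (dataset with promoted samples
#'   relabelled, original-scale X), `audit` (per-round data frame),
#'   `group_fits` (latest `sp_aft_fit` per risk group), `risk` (final
#'   `risk_groups` of the training samples), `threshold`, `std_record`,
#'   `pseudo` (per-censored-sample table), `config`.
#' @export
run_cox_sp_aft <- function(train, config = pipeline_config()) {
  set.seed(config$seed)
  std <- standardize(train)
  ds <- std$data
  n <- nrow(ds$X)
  if (sum(train$status) < config$min_group_labeled)
    stop_validation("fewer labelled samples than min_group_labeled")

  orig_time <- ds$time
  orig_status <- ds$status
  cur_time <- ds$time
  cur_status <- ds$status
  promoted <- rep(FALSE, n)
  pseudo_y <- rep(NA_real_, n)
  group_fits <- list()
  audit <- list()
  cox_fit <- NULL
  risk <- NULL

  for (round in seq_len(config$max_outer_rounds)) {
    cur <- survival_dataset(ds$X, cur_time, cur_status,
                            sample_ids = ds$sample_ids,
                            gene_ids = ds$gene_ids, promoted = promoted)
    cox_fit <- fit_penalized_cox(cur, config$cox_penalty)
    pi <- prognostic_index(cox_fit, ds$X)
    risk <- classify_risk(pi)
    new_promotions <- 0L
    skipped <- character(0)
    for (g in c("high", "low")) {
      gidx <- which(risk$group == g)
      lab_idx <- gidx[orig_status[gidx] == 1]
      cen_idx <- gidx[orig_status[gidx] == 0]   # incl. promoted: re-enter
      if (length(lab_idx) < config$min_group_labeled) {
        skipped <- c(skipped, g)
        next
      }
      if (!length(cen_idx)) next
      init <- stats::setNames(pseudo_y[cen_idx], ds$sample_ids[cen_idx])
      init <- init[!is.na(init)]
      cen_ds <- survival_dataset(ds$X[cen_idx, , drop = FALSE],
                                 orig_time[cen_idx],
                                 rep(0L, length(cen_idx)),
                                 sample_ids = ds$sample_ids[cen_idx],
                                 gene_ids = ds$gene_ids)
      sp_res <- fit_sp_aft(cur[lab_idx, ], cen_ds,
                           config$aft_penalty, config$sp,
                           use_spl = config$use_spl,
                           pseudo_init = if (length(init)) init else NULL)
      group_fits[[g]] <- sp_res
      keep <- sp_res$state$weights == 1
      y <- sp_res$state$pseudo_log_time
      for (k in seq_along(cen_idx)) {
        i <- cen_idx[k]
        if (keep[k] && exp(y[k]) > orig_time[i]) {
          if (!promoted[i]) new_promotions <- new_promotions + 1L
          promoted[i] <- TRUE
          pseudo_y[i] <- y[k]
          cur_time[i] <- exp(y[k])
          cur_status[i] <- 1L
        }
        # promoted samples with weight 0 keep their previous pseudo label
      }
    }
    audit[[round]] <- data.frame(
      round = round, cox_lam = cox_fit$lam_used,
      n_high = sum(risk$group == "high"), n_low = sum(risk$group == "low"),
      n_labeled = sum(cur_status == 1), n_new_promoted = new_promotions,
      n_promoted_total = sum(promoted),
      skipped_groups = paste(skipped, collapse = ","))
    if (new_promotions == 0L) break
  }

  augmented_std <- survival_dataset(ds$X, cur_time, cur_status,
                                    sample_ids = ds$sample_ids,
                                    gene_ids = ds$gene_ids,
                                    promoted = promoted)
  # final Cox fit on the augmented set: the last round's fit already used it
  # when that round promoted nothing; otherwise refit once more
  last <- audit[[length(audit)]]
  if (last$n_new_promoted > 0L) {
    cox_fit <- fit_penalized_cox(augmented_std, config$cox_penalty)
    risk <- classify_risk(prognostic_index(cox_fit, ds$X))
  }
  # promotion safety, asserted on every run
  stopifnot(all(!promoted | (cur_time > orig_time & cur_status == 1L)))

  augmented <- survival_dataset(train$X[, ds$gene_ids, drop = FALSE],
                                cur_time, cur_status,
                                sample_ids = ds$sample_ids,
                                gene_ids = ds$gene_ids, promoted = promoted)
  pseudo <- data.frame(sample_id = ds$sample_ids[orig_status == 0],
                       original_time = orig_time[orig_status == 0],
                       pseudo_time = ifelse(
                         is.na(pseudo_y[orig_status == 0]), NA,
                         exp(pseudo_y[orig_status == 0])),
                       promoted = promoted[orig_status == 0])
  structure(list(final_cox = cox_fit, augmented = augmented,
                 audit = do.call(rbind, audit), group_fits = group_fits,
                 risk = risk, threshold = risk$threshold,
                 std_record = std$record, pseudo = pseudo, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d outer round(s); %d censored sample(s) promoted; %d genes selected\n",
    nrow(x$audit), sum(x$augmented$promoted), length(x$final_cox$support)))
  invisible(x)
}

#' Run the Semi-Cox ablation (no self-paced learning)
#'
#' Identical outer loop, but the AFT stage keeps every censored sample whose
#' prediction satisfies the censoring constraint; only constraint violators
#' are dismissed. Equivalent to [run_cox_sp_aft()] with `use_spl = FALSE`.
#'
#' @inheritParams run_cox_sp_aft
#' @export
run_semi_cox_baseline <- function(train, config = pipeline_config()) {
  config$use_spl <- FALSE
  run_cox_sp_aft(train, config)
}

#' Supervised penalized-Cox baseline
#'
#' Fits a penalized Cox model on the training data alone: censored samples
#' keep their observed times and contribute to risk sets as ordinary censored
#' observations, but no pseudo-labelling happens.
#'
#' @param train a [survival_dataset()]; standardized internally.
#' @param family penalty family: `"mcp"`, `"lasso"` or `"elastic_net"`.
#' @param seed integer seed (drives the lambda cross-validation folds).
#' @return a `cox_fit` with the standardization record attached as
#'   attribute `std_record`.
#' @export
run_supervised_baseline <- function(train, family = "mcp", seed = 1L) {
  set.seed(seed)
  std <- standardize(train)
  fit <- fit_penalized_cox(std$data, penalty_spec(family))
  attr(fit, "std_record") <- std$record
  fit
}
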