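# The self-paced learning engine: hard-threshold weight updates, pseudo-label
# updates, age-parameter scheduling, and the SP-AFT alternating optimization.
#
# The SP-AFT objective, over coefficients beta, binary censored-sample
# weights v_j and pseudo-labels y_j:
#   sum_labelled (y_i - x_i'beta)^2
#   + sum_censored [ v_j * loss(y_j, x_j'beta) - alpha * v_j ]
#   + penalty(beta),
# where loss() is the censoring-constrained squared loss (censored_loss) and
# alpha the age parameter. Alternating minimization: beta by penalized
# weighted least squares, v by hard thresholding of losses at alpha, y by the
# current predictions on the selected set.

#' Self-paced learning configuration
#'
#' @param age_init_quantile quantile of the finite first-round losses used to
#'   initialize the age parameter (default 0.5: start from the easier half).
#' @param age_growth multiplicative growth factor mu > 1 applied each round
#'   (default 1.3), gradually admitting harder samples.
#' @param max_rounds cap on alternating rounds (default 20).
#' @param tol convergence tolerance on the max coefficient change.
#' @return object of class `sp_config`.
#' @export
sp_config <- function(age_init_quantile = 0.5, age_growth = 1.3,
                      max_rounds = 20, tol = 1e-4) {
  if (!(age_init_quantile > 0 && age_init_quantile < 1))
    stop_validation("age_init_quantile must be in (0,1)")
  if (age_growth <= 1) stop_validation("age_growth must be > 1")
  if (max_rounds < 1) stop_validation("max_rounds must be >= 1")
  structure(list(age_init_quantile = age_init_quantile,
                 age_growth = age_growth, max_rounds = max_rounds,
                 tol = tol), class = "sp_config")
}

sp_state <- function(weights, pseudo_log_time, age = NA_real_, round = 0L) {
  structure(list(weights = weights, pseudo_log_time = pseudo_log_time,
                 age = age, round = as.integer(round)), class = "sp_state")
}

#' Hard-threshold self-paced weight update
#'
#' Closed-form minimizer of the SPL objective in the weights: `v_j = 1` iff
#' `loss_j <= age` (boundary included), else 0. Infinite-sentinel losses are
#' always excluded for any finite age.
#'
#' @param losses nonnegative losses (may contain the sentinel).
#' @param age positive age parameter.
#' @return integer 0/1 vector.
#' @export
update_weights <- function(losses, age) {
  if (!is.finite(age) || age <= 0) stop_validation("age must be > 0")
  as.integer(losses <= age)
}

#' Pseudo-label update
#'
#' Samples with weight 1 receive the newly estimated log survival time
#' (the model prediction); samples with weight 0 keep their previous label.
#'
#' @param state an `sp_state`.
#' @param predictions model predictions `x_j'beta`, one per censored sample.
#' @return the updated `sp_state`.
#' @export
update_pseudo_labels <- function(state, predictions) {
  if (length(predictions) != length(state$weights))
    stop_validation("predictions length mismatch")
  sel <- state$weights == 1
  state$pseudo_log_time[sel] <- predictions[sel]
  state
}

#' Age-parameter schedule
#'
#' At round 1 the age is initialized to the `age_init_quantile` quantile of
#' the finite losses; thereafter it grows by the factor `age_growth`. The age
#' never decreases.
#'
#' @param state an `sp_state` with `round >= 1`.
#' @param losses current losses (used only at round 1).
#' @param config an [sp_config()].
#' @return the new age parameter.
#' @export
schedule_age <- function(state, losses, config) {
  if (state$round < 1) stop_validation("round must be >= 1")
  if (state$round == 1) {
    fin <- losses[losses < .spl_sentinel & is.finite(losses)]
    if (!length(fin)) {
      warning("no finite losses at age initialization; using smallest ",
              "positive step")
      a <- .Machine$double.xmin
    } else {
      a <- as.numeric(stats::quantile(fin, config$age_init_quantile))
      if (a <= 0) a <- .Machine$double.xmin
    }
  } else {
    a <- config$age_growth * state$age
  }
  max(a, state$age, na.rm = TRUE)
}

#' Fit the self-paced AFT model
#'
#' Alternating optimization: (i) penalized AFT fit on the labelled samples
#' plus the currently selected censored samples (warm-started), (ii)
#' censoring-constrained losses for every censored sample, (iii) age schedule
#' and hard-threshold weight update, (iv) pseudo-label refresh on the
#' selected set. Censored pseudo-labels are initialized by Kaplan-Meier
#' conditional-mean imputation on the combined data and all weights start
#' at 1. Stops when weights and coefficients are unchanged between rounds
#' (max coefficient change below `config$tol`) or `config$max_rounds` is
#' reached.
#'
#' With `use_spl = FALSE` (the no-SPL semi-supervised ablation) every
#' censored sample whose prediction satisfies the censoring constraint keeps
#' weight 1 each round; only constraint violators are excluded.
#'
#' The AFT lambda, when `penalty$lam` is `NULL`, is cross-validated once on
#' the initial design and then held fixed across rounds.
#'
#' @param labeled `survival_dataset` of event samples (>= 2), standardized.
#' @param censored `survival_dataset` of censored samples (may have 0 rows).
#' @param penalty a [penalty_spec()].
#' @param config an [sp_config()].
#' @param use_spl logical; `FALSE` gives the no-SPL ablation.
#' @param pseudo_init optional named vector of initial pseudo log-times
#'   overriding the KM imputation (names = censored sample ids); used by the
#'   pipeline to re-enter promoted samples with their current labels.
#' @return object of class `sp_aft_fit`: `fit` (the final `aft_fit`),
#'   `state` (`sp_state` with per-censored-sample weights and pseudo
#'   log-times), `n_rounds`, `converged`, and `objective_trace` (per-round
#'   unnormalized SPL objective after the fit, weight and label steps).
#' @export
fit_sp_aft <- function(labeled, censored, penalty = penalty_spec("mcp"),
                       config = sp_config(), use_spl = TRUE,
                       pseudo_init = NULL) {
  if (nrow(labeled$X) < 2) stop_validation("need >= 2 labelled samples")
  m <- nrow(censored$X)
  if (m == 0) {
    fit <- fit_penalized_aft(labeled$X, log(labeled$time), penalty)
    st <- sp_state(integer(0), numeric(0), age = NA_real_, round = 0L)
    return(structure(list(fit = fit, state = st, n_rounds = 0L,
                          converged = TRUE,
                          objective_trace = data.frame()),
                     class = "sp_aft_fit"))
  }
  if (!identical(labeled$gene_ids, censored$gene_ids))
    stop_validation("labelled and censored gene sets differ")

  # initial pseudo-labels: KM conditional mean on the combined data
  comb <- survival_dataset(rbind(labeled$X, censored$X),
                           c(labeled$time, censored$time),
                           c(labeled$status, censored$status),
                           sample_ids = c(labeled$sample_ids,
                                          censored$sample_ids),
                           gene_ids = labeled$gene_ids)
  y_cen <- km_conditional_mean_impute(comb)
  y_cen <- y_cen[censored$sample_ids]
  if (!is.null(pseudo_init)) {
    hit <- intersect(names(pseudo_init), names(y_cen))
    y_cen[hit] <- pseudo_init[hit]
  }

  X_all <- rbind(labeled$X, censored$X)
  y_lab <- log(labeled$time)
  log_c <- log(censored$time)
  n_all <- nrow(X_all)
  v <- rep(1L, m)

  # lambda is tuned on the labelled samples only: the KM-imputed initial
  # pseudo-labels are marginal (x-independent) quantities, and tuning on
  # them over-penalizes every fit into the intercept-only model
  sp <- penalty
  if (is.null(sp$lam)) {
    w_lab <- rep(1, nrow(labeled$X))
    lambdas <- aft_lambda_path(labeled$X, y_lab, w_lab, sp)
    sp$lam <- aft_cv_lambda(labeled$X, y_lab, w_lab, sp, lambdas)
  }

  state <- sp_state(v, y_cen, age = NA_real_, round = 0L)
  beta_prev <- numeric(ncol(X_all)); b0_prev <- NULL
  fit <- NULL
  converged <- FALSE
  trace <- vector("list", config$max_rounds)

  spl_obj <- function(fit, v, y, alpha) {
    # unnormalized SPL objective at fixed alpha (sentinel losses excluded by
    # their zero weights; v=1 sentinel rows contribute the sentinel)
    pred_l <- predict(fit, labeled$X)
    pred_c <- predict(fit, censored$X)
    lo <- censored_loss(y, log_c, pred_c)
    sum((y_lab - pred_l)^2) + sum(v * lo) - alpha * sum(v) +
      2 * n_all * sum(penalty_value(fit$beta, sp))
  }

  for (r in seq_len(config$max_rounds)) {
    state$round <- r
    w <- c(rep(1, nrow(labeled$X)), as.numeric(state$weights))
    fit <- aft_wls(X_all, c(y_lab, state$pseudo_log_time), w, sp,
                   beta_init = beta_prev, b0_init = b0_prev,
                   tol = config$tol / 10)
    pred_c <- predict(fit, censored$X)
    losses <- censored_loss(state$pseudo_log_time, log_c, pred_c)
    if (use_spl) {
      state$age <- schedule_age(state, losses, config)
      v_new <- update_weights(losses, state$age)
    } else {
      state$age <- .spl_sentinel / 2   # admit every constraint-satisfier
      v_new <- as.integer(losses < .spl_sentinel)
    }
    e_fit <- spl_obj(fit, state$weights, state$pseudo_log_time, state$age)
    e_wt <- spl_obj(fit, v_new, state$pseudo_log_time, state$age)
    state$weights <- v_new
    state <- update_pseudo_labels(state, pred_c)
    e_lab <- spl_obj(fit, state$weights, state$pseudo_log_time, state$age)
    trace[[r]] <- data.frame(round = r, age = state$age,
                             n_selected = sum(v_new),
                             after_fit = e_fit, after_weights = e_wt,
                             after_labels = e_lab)
    dbeta <- max(abs(c(fit$beta, fit$intercept) -
                     c(beta_prev, b0_prev %||% fit$intercept)))
    if (r > 1 && all(v_new == v_prev) && dbeta < config$tol) {
      converged <- TRUE
      break
    }
    v_prev <- v_new
    beta_prev <- fit$beta; b0_prev <- fit$intercept
  }
  if (!converged)
    warning("SP-AFT did not converge in ", config$max_rounds, " rounds")
  names(state$weights) <- censored$sample_ids
  names(state$pseudo_log_time) <- censored$sample_ids
  structure(list(fit = fit, state = state, n_rounds = state$round,
                 converged = converged,
                 objective_trace = do.call(rbind, trace[!vapply(
                   trace, is.null, logical(1))])),
            class = "sp_aft_fit")
}

#' @export
print.sp_aft_fit <- function(x, ...) {
  cat(sprintf(
    "<sp_aft_fit> %d rounds (%s); %d of %d censored samples selected\n",
    x$n_rounds, if (x$converged) "converged" else "not converged",
    sum(x$state$weights == 1), length(x$state$weights)))
  invisible(x)
}
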