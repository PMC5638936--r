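# Penalized log-linear AFT regression, Kaplan-Meier conditional-mean initial
# imputation of censored times, and the censoring-constrained loss.
#
# All AFT computation is on the log-time scale: the model is
# log t = intercept + x'beta + eps, and the censoring constraint
# "predicted survival time >= censor time" reads x'beta >= log t_j.

# penalized (weighted) least squares core shared by the plain AFT fit and the
# self-paced loop; objective (1/(2n)) sum_i w_i (y_i - b0 - x_i'b)^2 + pen
aft_wls <- function(X, y, w, spec, beta_init = NULL, b0_init = NULL,
                    max_sweeps = 2000, tol = 1e-7) {
  n <- nrow(X)
  beta0 <- beta_init %||% numeric(ncol(X))
  b0 <- b0_init %||% (if (sum(w) > 0) sum(w * y) / sum(w) else 0)
  res <- .cd_gaussian(X, y, w, spec_lam(spec), family_code(spec$family),
                      spec$gamma, spec$mix, TRUE, beta0, b0,
                      as.integer(max_sweeps), tol, TRUE, 60)
  beta <- drop(res$beta)
  names(beta) <- colnames(X)
  structure(list(intercept = res$b0, beta = beta,
                 support = which(beta != 0),
                 converged = res$converged, n_iterations = res$sweeps,
                 lam_used = spec$lam),
            class = "aft_fit")
}

aft_objective <- function(fit, X, y, w, spec) {
  r <- y - fit$intercept - drop(X %*% fit$beta)
  sum(w * r^2) / (2 * length(y)) + sum(penalty_value(fit$beta, spec))
}

aft_lambda_path <- function(X, y, w, spec, nlambda = 50,
                            lambda_min_ratio = 0.01) {
  n <- nrow(X)
  b0 <- sum(w * y) / sum(w)
  lmax <- max(abs(crossprod(X, w * (y - b0)))) / n
  if (spec$family == "elastic_net") lmax <- lmax / spec$mix
  lmax <- max(lmax, .Machine$double.eps)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# K-fold CV on weighted squared prediction error
aft_cv_lambda <- function(X, y, w, spec, lambdas, nfolds = 5, foldid = NULL) {
  n <- nrow(X)
  foldid <- foldid %||% sample(rep(seq_len(nfolds), length.out = n))
  nfolds <- max(foldid)
  err <- matrix(NA_real_, nfolds, length(lambdas))
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    if (sum(w[tr] > 0) < 2) next
    beta <- numeric(ncol(X)); b0 <- NULL
    dfmax <- min(ncol(X), sum(tr))
    for (k in seq_along(lambdas)) {
      sp <- spec; sp$lam <- lambdas[k]
      fit <- aft_wls(X[tr, , drop = FALSE], y[tr], w[tr], sp,
                     beta_init = beta, b0_init = b0,
                     max_sweeps = 300, tol = 1e-5)   # loose CV profile
      if (any(!is.finite(fit$beta)) || max(abs(fit$beta)) > 50 ||
          sum(fit$beta != 0) > dfmax) break   # saturated: leave rest NA
      beta <- fit$beta; b0 <- fit$intercept
      pred <- fit$intercept + drop(X[!tr, , drop = FALSE] %*% fit$beta)
      wt <- w[!tr]
      err[f, k] <- if (sum(wt) > 0) sum(wt * (y[!tr] - pred)^2) / sum(wt)
                   else NA_real_
    }
  }
  if (all(!is.finite(err))) {
    warning("AFT cross-validation impossible; using lambda = 0.1*lambda_max")
    return(lambdas[1] * 0.1)
  }
  lambdas[which.min(colMeans(err, na.rm = TRUE))]
}

#' Fit a penalized AFT regression on log-times
#'
#' Coordinate-descent minimizer of
#' `sum_i (y_i - intercept - x_i'beta)^2 / (2m) + sum_j pen(beta_j)` with an
#' unpenalized intercept. When `spec$lam` is `NULL` lambda is chosen by
#' K-fold cross-validated prediction error over a log-spaced path.
#'
#' @param X m x p standardized design matrix.
#' @param y length-m responses (log survival times).
#' @param spec a [penalty_spec()].
#' @param weights optional nonnegative case weights (used by the self-paced
#'   loop; the normalizing m stays `nrow(X)`).
#' @param max_sweeps,tol coordinate-descent budget and tolerance.
#' @param nfolds,foldid,nlambda,lambda_min_ratio tuning controls.
#' @return object of class `aft_fit`: `intercept`, `beta` (named), `support`,
#'   `converged`, `n_iterations`, `lam_used`.
#' @export
fit_penalized_aft <- function(X, y, spec = penalty_spec("mcp"),
                              weights = NULL, max_sweeps = 2000, tol = 1e-7,
                              nfolds = 5, foldid = NULL, nlambda = 50,
                              lambda_min_ratio = 0.01) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_validation("need at least 2 samples")
  if (length(y) != nrow(X)) stop_validation("y length mismatch")
  w <- weights %||% rep(1, nrow(X))
  lambdas <- aft_lambda_path(X, y, w, spec, nlambda, lambda_min_ratio)
  lam <- spec$lam %||% aft_cv_lambda(X, y, w, spec, lambdas, nfolds, foldid)
  # warm-started refit down the path to lam: loose profile for the
  # intermediate lambdas, full budget at the chosen one, saturation-guarded
  beta <- numeric(ncol(X)); b0 <- NULL; fit <- NULL
  dfmax <- min(ncol(X), nrow(X))
  for (l in lambdas[lambdas > lam]) {
    sp <- spec; sp$lam <- l
    cand <- aft_wls(X, y, w, sp, beta_init = beta, b0_init = b0,
                    max_sweeps = 300, tol = max(tol, 1e-5))
    if (!is.null(fit) && (any(!is.finite(cand$beta)) ||
        max(abs(cand$beta)) > 50 || sum(cand$beta != 0) > dfmax)) break
    fit <- cand
    beta <- fit$beta; b0 <- fit$intercept
  }
  sp <- spec; sp$lam <- lam
  cand <- aft_wls(X, y, w, sp, beta_init = beta, b0_init = b0,
                  max_sweeps = max_sweeps, tol = tol)
  if (!is.null(fit) && (any(!is.finite(cand$beta)) ||
      max(abs(cand$beta)) > 50 || sum(cand$beta != 0) > dfmax)) {
    warning("AFT fit saturated at the requested lambda; returning ",
            "the last well-posed path solution")
    return(fit)
  }
  cand
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("<aft_fit> intercept %.4g; %d nonzero of %d coefficients\n",
              x$intercept, length(x$support), length(x$beta)))
  invisible(x)
}

#' Predict log survival times from an AFT fit
#' @param object an `aft_fit`.
#' @param X design matrix on the scale the fit used.
#' @param ... unused.
#' @export
predict.aft_fit <- function(object, X, ...) {
  object$intercept + drop(as.matrix(X) %*% object$beta)
}

#' Kaplan-Meier conditional-mean imputation of censored log-times
#'
#' For each censored sample with censor time `c`, returns
#' `log E[T | T > c]` computed as `c + (integral_c^Inf S(t) dt) / S(c)` with
#' `S` the step-function KM curve of the whole dataset. If `S` never reaches
#' zero, the largest observed time is treated as an event for the tail mass
#' (Efron tail convention). Every imputed time is strictly larger than its
#' censor time; in the degenerate case of a censor time at/beyond the last
#' knot the imputation is `c*(1 + 1e-6)` with a warning.
#'
#' @param data a [survival_dataset()] with at least one event.
#' @return named numeric vector of pseudo log-times, one per censored sample
#'   (names = sample ids), in dataset order.
#' @export
km_conditional_mean_impute <- function(data) {
  if (sum(data$status) == 0)
    stop_validation("no events: cannot form a Kaplan-Meier curve")
  cen <- which(data$status == 0)
  out <- numeric(length(cen))
  if (!length(cen)) return(stats::setNames(out, character(0)))
  km <- km_estimator(data$time, data$status)
  knots <- km$event_times
  surv <- km$survival_prob
  tmax <- max(data$time)
  if (km_surv_at(km, tmax) > 0) {   # Efron tail: force S(tmax) = 0
    if (length(knots) && knots[length(knots)] == tmax) {
      surv[length(surv)] <- 0
    } else {
      knots <- c(knots, tmax)
      surv <- c(surv, 0)
    }
  }
  s_at <- function(tt) { k <- sum(knots <= tt); if (k == 0) 1 else surv[k] }
  for (i in seq_along(cen)) {
    cc <- data$time[cen[i]]
    sc <- s_at(cc)
    if (sc <= 0) {
      warning("censor time at/after the last support point; imputing ",
              "c*(1+1e-6) for sample ", data$sample_ids[cen[i]])
      out[i] <- log(cc * (1 + 1e-6))
      next
    }
    # integral of the step function S from cc to the last knot
    after <- which(knots > cc)
    pts <- c(cc, knots[after])
    sv <- c(sc, surv[after])
    integral <- sum(sv[-length(sv)] * diff(pts))
    m <- cc + integral / sc
    if (m <= cc) {
      warning("degenerate tail for sample ", data$sample_ids[cen[i]],
              "; imputing c*(1+1e-6)")
      m <- cc * (1 + 1e-6)
    }
    out[i] <- log(m)
  }
  stats::setNames(out, data$sample_ids[cen])
}

#' Censoring-constrained squared loss for a pseudo-labelled sample
#'
#' On the log-time scale: when the prediction `x_j'beta` falls below the
#' censor log-time the sample is infeasible (its true survival time must be
#' at least the censor time) and the loss is an infinite sentinel — a finite
#' value far above any attainable age parameter, so self-paced weight updates
#' stay well defined. Otherwise the loss is `(y_j - x_j'beta)^2`. Vectorized.
#'
#' @param pseudo_log_time current pseudo-label(s) `y_j`.
#' @param censor_log_time `log t_j` of the censored sample(s).
#' @param predicted model prediction(s) `x_j'beta`.
#' @return nonnegative loss(es); the sentinel is `spl_sentinel()`.
#' @export
censored_loss <- function(pseudo_log_time, censor_log_time, predicted) {
  ifelse(predicted < censor_log_time, .spl_sentinel,
         (pseudo_log_time - predicted)^2)
}

#' The infinite-loss sentinel value
#' @export
spl_sentinel <- function() .spl_sentinel
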