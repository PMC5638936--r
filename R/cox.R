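# Penalized Cox proportional-hazards fitting, risk stratification and the
# Kaplan-Meier estimator.
#
# The partial likelihood uses risk sets R_i = {j : t_j >= t_i} and the Breslow
# convention for tied event times. The coordinate-descent solver follows the
# usual IRLS scheme: at the current linear predictor eta the negative partial
# log-likelihood (scaled by 1/n) is replaced by its diagonal quadratic
# approximation, giving a penalized weighted least-squares subproblem.

# Sufficient statistics at a linear predictor eta, all in input order:
# loglik (raw, unscaled), grad = d(-loglik)/d eta, w = diagonal of the
# Hessian of -loglik. O(n log n).
cox_suffstats <- function(eta, time, status) {
  n <- length(eta)
  ord <- order(time)
  ts <- time[ord]; ds <- status[ord]
  # centering: the partial likelihood is shift-invariant; the +/-70 clip
  # protects exp() and exp()^2 from overflow on saturated fits
  ec <- pmin(pmax(eta[ord] - mean(eta), -70), 70)
  es <- exp(ec)
  S <- rev(cumsum(rev(es)))             # suffix sums of exp(eta)
  r <- rle(ts)
  glen <- r$lengths
  gend <- cumsum(glen)
  gstart <- gend - glen + 1L
  gid <- rep(seq_along(glen), glen)
  D <- S[gstart]                        # shared Breslow denominator per group
  dg <- as.vector(rowsum(ds, gid))      # events per tied-time group
  a <- cumsum(dg / D)                   # sum_{groups t<=.} d/D
  b <- cumsum(dg / D^2)
  A <- a[gid]; B <- b[gid]
  loglik <- sum(ds * (ec - log(D)[gid]))
  grad_s <- -ds + es * A
  w_s <- pmax(es * A - es^2 * B, 0)
  grad <- numeric(n); w <- numeric(n)
  grad[ord] <- grad_s; w[ord] <- w_s
  list(loglik = loglik, grad = grad, w = w)
}

#' Negative Cox partial log-likelihood
#'
#' `-sum_i delta_i { x_i'beta - log sum_{j in R_i} exp(x_j'beta) }` with risk
#' sets `R_i = { j : t_j >= t_i }` and Breslow handling of ties. Returns the
#' raw (unscaled) value.
#'
#' @param beta coefficient vector, length p.
#' @param data a [survival_dataset()].
#' @return a finite scalar.
#' @export
neg_partial_loglik <- function(beta, data) {
  if (any(!is.finite(beta))) stop_validation("non-finite beta")
  if (length(beta) != ncol(data$X)) stop_validation("beta length mismatch")
  eta <- drop(data$X %*% beta)
  -cox_suffstats(eta, data$time, data$status)$loglik
}

# gradient of neg_partial_loglik w.r.t. beta (raw scale); used in tests
cox_grad_beta <- function(beta, data) {
  eta <- drop(data$X %*% beta)
  drop(crossprod(data$X, cox_suffstats(eta, data$time, data$status)$grad))
}

# One penalized Cox fit at fixed lambda by IRLS + coordinate descent on the
# objective (1/n)*negloglik + sum_j pen(beta_j). Warm-startable.
cox_irls <- function(X, time, status, spec, beta_init = NULL,
                     max_iter = 50, tol = 1e-6, cd_tol = NULL,
                     cd_sweeps = 500L) {
  n <- nrow(X); p <- ncol(X)
  beta <- beta_init %||% numeric(p)
  cd_tol <- cd_tol %||% (tol / 10)
  fam <- family_code(spec$family)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    st <- cox_suffstats(eta, time, status)
    w <- pmax(st$w, 1e-8)
    z <- eta - st$grad / w
    res <- .cd_gaussian(X, z, w, spec_lam(spec), fam, spec$gamma, spec$mix,
                        FALSE, beta, 0, as.integer(cd_sweeps), cd_tol, TRUE,
                        60)
    if (any(!is.finite(res$beta)) || isTRUE(res$diverged)) break
    delta <- max(abs(res$beta - beta))
    beta <- res$beta
    if (max(abs(beta)) > 50) break         # monotone-likelihood divergence
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta, n_iterations = it, converged = converged)
}

# lambda where all coefficients are zero (score condition at beta = 0)
cox_lambda_max <- function(X, time, status, spec) {
  g0 <- cox_suffstats(numeric(nrow(X)), time, status)$grad
  lmax <- max(abs(crossprod(X, g0))) / nrow(X)
  if (spec$family == "elastic_net") lmax <- lmax / spec$mix
  max(lmax, .Machine$double.eps)
}

cox_lambda_path <- function(X, time, status, spec, nlambda = 50,
                            lambda_min_ratio = 0.01) {
  lmax <- cox_lambda_max(X, time, status, spec)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# Warm-started path fit; returns p x nlambda coefficient matrix. The path
# stops early once the fit saturates (support larger than dfmax, or
# coefficients diverging under the monotone partial likelihood when p > n);
# remaining columns repeat the last well-posed solution.
cox_path <- function(X, time, status, spec, lambdas, max_iter = 6,
                     tol = 1e-4, dfmax = NULL) {
  p <- ncol(X)
  dfmax <- dfmax %||% min(p, nrow(X))
  B <- matrix(0, p, length(lambdas))
  beta <- numeric(p)
  for (k in seq_along(lambdas)) {
    sp <- spec; sp$lam <- lambdas[k]
    fit <- cox_irls(X, time, status, sp, beta_init = beta,
                    max_iter = max_iter, tol = tol, cd_sweeps = 50L)
    if (any(!is.finite(fit$beta)) || max(abs(fit$beta)) > 50 ||
        sum(fit$beta != 0) > dfmax) {
      B[, k:length(lambdas)] <- beta   # saturated: freeze at last solution
      break
    }
    beta <- fit$beta
    B[, k] <- beta
  }
  B
}

# K-fold cross-validation for the Cox lambda, scored by held-out
# concordance (Harrell's C of the negated held-out prognostic index).
# Likelihood-based CV (Verweij & van Houwelingen deviance) degenerates when
# the linear predictor nearly separates the risk ordering: the MCP leaves
# large coefficients unshrunk, the held-out partial likelihood then diverges
# and the deviance minimizer collapses onto near-empty models. Concordance
# scores only the risk ranking, which is what the downstream stratification
# uses. Ties are broken toward the larger (sparser) lambda.
cox_cv_lambda <- function(X, time, status, spec, lambdas, nfolds = 5,
                          foldid = NULL) {
  n <- nrow(X)
  foldid <- foldid %||% sample(rep(seq_len(nfolds), length.out = n))
  nfolds <- max(foldid)
  ci <- matrix(NA_real_, nfolds, length(lambdas))
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    if (sum(status[tr]) < 2 || sum(status[!tr]) < 1) next
    B <- cox_path(X[tr, , drop = FALSE], time[tr], status[tr], spec, lambdas)
    Xte <- X[!tr, , drop = FALSE]
    for (k in seq_along(lambdas)) {
      ci[f, k] <- tryCatch(
        concordance_index(-drop(Xte %*% B[, k]), time[!tr], status[!tr]),
        error = function(e) NA_real_)
    }
  }
  if (all(!is.finite(ci))) {
    warning("cross-validation impossible (too few events per fold); ",
            "using lambda = 0.1 * lambda_max")
    return(lambdas[1] * 0.1)
  }
  m <- colMeans(ci, na.rm = TRUE)
  lambdas[which.max(m)]   # which.max: first index = largest lambda on ties
}

#' Fit a penalized Cox proportional-hazards model
#'
#' Coordinate descent on an iteratively reweighted quadratic approximation of
#' the partial likelihood, objective `(1/n)*negloglik + sum_j pen(beta_j)`.
#' When `spec$lam` is `NULL`, lambda is chosen by K-fold (default 5)
#' cross-validated partial likelihood over a `nlambda`-point log-spaced path
#' from `lambda_max` down to `lambda_min_ratio*lambda_max`, then the model is
#' refit on the full data along the path down to the chosen value.
#'
#' The expression matrix is assumed standardized (see [standardize()]).
#'
#' @param data a [survival_dataset()] with at least 2 events.
#' @param spec a [penalty_spec()].
#' @param max_iter maximum IRLS iterations per lambda.
#' @param tol convergence tolerance on the max coefficient change.
#' @param nlambda,lambda_min_ratio tuning path geometry.
#' @param nfolds,foldid cross-validation folds.
#' @return object of class `cox_fit`: `beta` (named), `support` (indices of
#'   nonzero entries), `lam_used`, `n_iterations`, `converged`,
#'   `partial_loglik` (raw value at the optimum).
#' @export
fit_penalized_cox <- function(data, spec = penalty_spec("mcp"),
                              max_iter = 50, tol = 1e-5, nlambda = 50,
                              lambda_min_ratio = 0.01, nfolds = 5,
                              foldid = NULL) {
  X <- data$X; time <- data$time; status <- data$status
  if (sum(status) == 0) stop_validation("no events in data")
  if (sum(status) < 2) stop_validation("need at least 2 events")
  lam <- spec$lam
  lambdas <- cox_lambda_path(X, time, status, spec, nlambda,
                             lambda_min_ratio)
  if (is.null(lam)) {
    lam <- cox_cv_lambda(X, time, status, spec, lambdas, nfolds, foldid)
  }
  # refit on full data down the path to lam (stabilizes the nonconvex MCP
  # solution): cheap path profile for the intermediate lambdas, full budget
  # only at the chosen one
  above <- lambdas[lambdas > lam]
  beta <- numeric(ncol(X))
  if (length(above)) {
    B <- cox_path(X, time, status, spec, above)
    beta <- B[, ncol(B)]
  }
  sp <- spec; sp$lam <- lam
  fit <- cox_irls(X, time, status, sp, beta_init = beta,
                  max_iter = max_iter, tol = tol)
  dfmax <- min(ncol(X), nrow(X))
  if (any(!is.finite(fit$beta)) || max(abs(fit$beta)) > 50 ||
      sum(fit$beta != 0) > dfmax) {
    warning("fit saturated at the requested lambda; ",
            "returning the last well-posed path solution")
    fit$beta <- beta
    fit$converged <- FALSE
  }
  beta <- fit$beta
  if (!fit$converged)
    warning("penalized Cox fit did not converge in ", max_iter,
            " IRLS iterations")
  names(beta) <- data$gene_ids
  structure(list(beta = beta, support = which(beta != 0), lam_used = lam,
                 n_iterations = fit$n_iterations, converged = fit$converged,
                 partial_loglik = -neg_partial_loglik(beta, data)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> %d nonzero of %d coefficients; lambda = %.4g; %s\n",
    length(x$support), length(x$beta), x$lam_used,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Prognostic index (Cox linear predictor)
#'
#' @param fit a `cox_fit`.
#' @param X expression matrix on the same (standardized) scale the fit used.
#' @return numeric vector `x_i'beta`, one per row of `X`.
#' @export
prognostic_index <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(fit$beta)) stop_validation("dimension mismatch")
  drop(X %*% fit$beta)
}

#' Median split of prognostic indices into high/low risk groups
#'
#' The threshold defaults to the median of `pi` (the training samples); ties
#' at the threshold go to the low-risk group. Pass an explicit `threshold`
#' to classify new samples with a training cutoff.
#'
#' @param pi prognostic indices, length >= 2.
#' @param threshold optional fixed cutoff.
#' @return object of class `risk_groups`: factor `group` with levels
#'   `low`, `high`, and the `threshold` used.
#' @export
classify_risk <- function(pi, threshold = NULL) {
  if (length(pi) < 2 && is.null(threshold))
    stop_validation("need at least 2 samples")
  thr <- threshold %||% stats::median(pi)
  if (is.null(threshold) && all(pi == pi[1])) {
    warning("all prognostic indices equal; assigning every sample low risk")
    g <- rep("low", length(pi))
  } else {
    g <- ifelse(pi > thr, "high", "low")
  }
  structure(list(group = factor(g, levels = c("low", "high")),
                 threshold = thr), class = "risk_groups")
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod_{t_k <= t} (1 - d_k/n_k)` over distinct event times `t_k`
#' (`d_k` events, `n_k` at risk). With no events the curve is identically 1
#' (zero-length step set).
#'
#' @param time positive observed times.
#' @param status event indicators in {0, 1}.
#' @return object of class `km_curve`: `event_times` (ascending),
#'   `survival_prob` (non-increasing), `n_risk`, `n_event`.
#' @export
km_estimator <- function(time, status) {
  if (!length(time)) stop_validation("empty input")
  if (!all(status %in% c(0, 1))) stop_validation("status must be 0/1")
  evt <- sort(unique(time[status == 1]))
  n_risk <- vapply(evt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(evt, function(t) sum(time == t & status == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(event_times = evt, survival_prob = surv,
                 n_risk = n_risk, n_event = n_event), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times (right-continuous step)
#' @param curve a `km_curve`.
#' @param t times at which to evaluate `S(t)`.
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    k <- sum(curve$event_times <= tt)
    if (k == 0) 1 else curve$survival_prob[k]
  }, numeric(1))
}

#' Export a KM curve as a two-column data frame (time, survival)
#' @param curve a `km_curve`.
#' @export
km_table <- function(curve) {
  data.frame(time = c(0, curve$event_times),
             survival = c(1, curve$survival_prob))
}
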