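test_that("neg_partial_loglik closed forms and brute-force oracle", {
  # beta = 0, three events at distinct times: risk-set sizes 3, 2, 1
  d <- survival_dataset(matrix(0, 3, 2), c(1, 2, 3), c(1, 1, 1))
  expect_equal(neg_partial_loglik(c(0, 0), d), log(6))
  # single event sample: its risk set is itself
  d1 <- survival_dataset(matrix(rnorm(2), 1, 2), 5, 1)
  expect_equal(neg_partial_loglik(rnorm(2), d1), 0)
  # 5-sample toy with censoring vs term-by-term oracle
  set.seed(3)
  d5 <- make_toy_surv(n = 5, p = 3, seed = 3, cens_frac = 0.2)
  b <- rnorm(3) / 2
  expect_lt(abs(neg_partial_loglik(b, d5) -
                npll_bruteforce(b, d5$X, d5$time, d5$status)), 1e-10)
  expect_error(neg_partial_loglik(c(NA, 0, 0), d5),
               class = "spaft_validation_error")
})

test_that("Breslow ties match the brute-force oracle", {
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)
  d <- survival_dataset(X, c(1, 1, 2, 2, 2, 3), c(1, 1, 1, 0, 1, 1))
  b <- rnorm(3) / 3
  expect_lt(abs(neg_partial_loglik(b, d) -
                npll_bruteforce(b, X, d$time, d$status)), 1e-10)
})

test_that("analytic gradient matches finite differences", {
  for (s in 1:10) {
    d <- make_toy_surv(n = 10, p = 4, seed = s, cens_frac = 0.3)
    b <- rnorm(4) / 2
    g <- spaft:::cox_grad_beta(b, d)
    gfd <- fd_gradient(function(bb) neg_partial_loglik(bb, d), b)
    expect_lt(max(abs(g - gfd)), 1e-5)
  }
})

test_that("neg_partial_loglik is convex along random segments", {
  set.seed(11)
  d <- make_toy_surv(n = 15, p = 4, seed = 11, cens_frac = 0.3)
  for (k in 1:25) {
    b1 <- rnorm(4); b2 <- rnorm(4)
    mid <- neg_partial_loglik((b1 + b2) / 2, d)
    expect_lte(mid, (neg_partial_loglik(b1, d) +
                     neg_partial_loglik(b2, d)) / 2 + 1e-10)
  }
})

test_that("lambda above lambda_max gives the null model", {
  d <- standardize(make_toy_surv(n = 30, p = 5, seed = 5,
                                 beta = c(1, 0, 0, 0, 0)))$data
  lmax <- spaft:::cox_lambda_max(d$X, d$time, d$status,
                                 penalty_spec("lasso"))
  fit <- fit_penalized_cox(d, penalty_spec("lasso", lam = lmax * 1.01))
  expect_equal(unname(fit$beta), numeric(5))
  expect_length(fit$support, 0)
})

test_that("a single informative gene is recovered at moderate lambda", {
  d <- standardize(make_toy_surv(n = 60, p = 3, seed = 8,
                                 beta = c(2, 0, 0)))$data
  lmax <- spaft:::cox_lambda_max(d$X, d$time, d$status, penalty_spec("mcp"))
  fit <- fit_penalized_cox(d, penalty_spec("mcp", lam = lmax * 0.5))
  expect_equal(unname(fit$support), 1L)
  expect_gt(fit$beta[1], 0)   # gene 1 raises the hazard
})

test_that("returned beta is a local minimum of the penalized objective", {
  d <- standardize(make_toy_surv(n = 40, p = 2, seed = 9,
                                 beta = c(1, -1)))$data
  spec <- penalty_spec("mcp", lam = 0.05)
  fit <- fit_penalized_cox(d, spec, tol = 1e-8)
  obj <- function(b) neg_partial_loglik(b, d) / nrow(d$X) +
    sum(penalty_value(b, spec))
  f0 <- obj(fit$beta)
  set.seed(1)
  for (k in 1:100) {
    expect_gte(obj(fit$beta + rnorm(2) * 0.01), f0 - 1e-8)
  }
})

test_that("lasso Cox objective matches the glmnet oracle", {
  skip_if_not_installed("glmnet")
  d <- standardize(make_toy_surv(n = 50, p = 4, seed = 10,
                                 beta = c(1, -0.5, 0, 0)))$data
  lam <- 0.08
  fit <- fit_penalized_cox(d, penalty_spec("lasso", lam = lam), tol = 1e-8)
  g <- glmnet::glmnet(d$X, survival::Surv(d$time, d$status),
                      family = "cox", lambda = lam, standardize = FALSE,
                      thresh = 1e-12)
  bg <- as.numeric(g$beta)
  obj <- function(b) neg_partial_loglik(b, d) / nrow(d$X) + lam * sum(abs(b))
  expect_lt(abs(obj(fit$beta) - obj(bg)), 1e-5)
})

test_that("prognostic_index is the linear predictor", {
  d <- make_toy_surv(n = 10, p = 5, seed = 12)
  fit <- structure(list(beta = rnorm(5)), class = "cox_fit")
  expect_equal(prognostic_index(fit, d$X), drop(d$X %*% fit$beta))
  fit0 <- structure(list(beta = numeric(5)), class = "cox_fit")
  expect_equal(unname(prognostic_index(fit0, d$X)), rep(0, 10))
  fitk <- structure(list(beta = c(0, 1, 0, 0, 0)), class = "cox_fit")
  expect_equal(unname(prognostic_index(fitk, d$X)), unname(d$X[, 2]))
})

test_that("classify_risk median split, ties to low, degenerate warning", {
  rg <- classify_risk(c(1, 2, 3, 4))
  expect_equal(rg$threshold, 2.5)
  expect_equal(as.character(rg$group), c("low", "low", "high", "high"))
  expect_warning(rg0 <- classify_risk(rep(1, 4)), "low risk")
  expect_true(all(rg0$group == "low"))
  # tie at an explicit threshold goes low
  expect_equal(as.character(classify_risk(c(1, 2), threshold = 2)$group),
               c("low", "low"))
  set.seed(13)
  for (k in 1:100) {
    x <- rnorm(2 * sample(2:20, 1))
    g <- classify_risk(x)$group
    expect_equal(sum(g == "high"), length(x) / 2)
  }
})

test_that("km_estimator matches hand calculations and survfit", {
  km <- km_estimator(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival_prob, c(0.75, 0.5, 0.25, 0))
  km0 <- km_estimator(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$event_times, 0)
  expect_equal(km_surv_at(km0, c(0.5, 10)), c(1, 1))
  # times (1, 2+, 3, 4): S(1)=3/4, S(3)=3/4*1/2, S(4)=0
  km1 <- km_estimator(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km_surv_at(km1, c(1, 3, 4)), c(0.75, 0.375, 0))
  expect_true(all(diff(km1$survival_prob) <= 0))
  skip_if_not_installed("survival")
  set.seed(14)
  for (s in 1:5) {
    d <- make_toy_surv(n = 25, p = 1, seed = s, cens_frac = 0.4)
    km <- km_estimator(d$time, d$status)
    sf <- survival::survfit(survival::Surv(d$time, d$status) ~ 1)
    at <- km$event_times
    expect_equal(km_surv_at(km, at),
                 unname(summary(sf, times = at)$surv), tolerance = 1e-12)
  }
})

test_that("km_table exports a plot-ready step table", {
  km <- km_estimator(c(1, 2), c(1, 1))
  tab <- km_table(km)
  expect_equal(tab$time, c(0, 1, 2))
  expect_equal(tab$survival, c(1, 0.5, 0))
})
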