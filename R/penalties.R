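#' Specify a sparsity penalty
#'
#' Three families are supported: the minimax concave penalty (MCP), the lasso,
#' and the elastic net. `lam = NULL` means "tune by cross-validation" inside
#' the fitting routines.
#'
#' @param family one of `"mcp"`, `"lasso"`, `"elastic_net"`.
#' @param lam tuning parameter lambda >= 0, or `NULL` to cross-validate.
#' @param gamma MCP concavity parameter, > 1; ignored by other families. The
#'   conventional default 3 is used (the source model states none).
#' @param mix elastic-net mixing weight in (0, 1] on the l1 term; ignored by
#'   other families.
#' @return object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("mcp", "lasso", "elastic_net"),
                         lam = NULL, gamma = 3, mix = 0.5) {
  family <- match.arg(family)
  if (!is.null(lam) && (!is.finite(lam) || lam < 0))
    stop_validation("lam must be >= 0")
  if (family == "mcp" && (!is.finite(gamma) || gamma <= 1))
    stop_validation("gamma must be > 1 for mcp")
  if (family == "elastic_net" && !(mix > 0 && mix <= 1))
    stop_validation("mix must be in (0, 1] for elastic_net")
  structure(list(family = family, lam = lam, gamma = gamma, mix = mix),
            class = "penalty_spec")
}

spec_lam <- function(spec) {
  if (is.null(spec$lam)) stop_validation("penalty lam is NULL (untuned)")
  spec$lam
}

family_code <- function(family) {
  match(family, c("lasso", "mcp", "elastic_net")) - 1L
}

#' Penalty value at a coefficient
#'
#' MCP: `lam*|b| - b^2/(2*gamma)` for `|b| <= gamma*lam`, constant
#' `gamma*lam^2/2` beyond; lasso: `lam*|b|`; elastic net:
#' `lam*(mix*|b| + (1-mix)*b^2/2)`. Vectorized over `beta_j`.
#'
#' @param beta_j coefficient value(s).
#' @param spec a [penalty_spec()] with non-NULL `lam`.
#' @return nonnegative penalty value(s).
#' @export
penalty_value <- function(beta_j, spec) {
  lam <- spec_lam(spec)
  b <- abs(beta_j)
  switch(spec$family,
    lasso = lam * b,
    mcp = ifelse(b <= spec$gamma * lam,
                 lam * b - b^2 / (2 * spec$gamma),
                 spec$gamma * lam^2 / 2),
    elastic_net = lam * (spec$mix * b + (1 - spec$mix) * b^2 / 2))
}

#' Derivative of the penalty (subgradient magnitude times sign)
#'
#' Used in gradient checks; for MCP this is
#' `lam*sign(b)*max(0, 1 - |b|/(gamma*lam))`.
#' @inheritParams penalty_value
#' @keywords internal
penalty_deriv <- function(beta_j, spec) {
  lam <- spec_lam(spec)
  s <- sign(beta_j); b <- abs(beta_j)
  switch(spec$family,
    lasso = lam * s,
    mcp = s * lam * pmax(0, 1 - b / (spec$gamma * lam)),
    elastic_net = lam * (spec$mix * s + (1 - spec$mix) * beta_j))
}

#' Scalar thresholding (proximal) operator
#'
#' Returns the minimizer of `0.5*step_curvature*(b - z)^2 +
#' penalty_value(b, spec)`: soft thresholding for the lasso, firm thresholding
#' for MCP, scaled soft thresholding for the elastic net. For MCP the
#' subproblem is convex only when `step_curvature*gamma > 1`; otherwise the
#' lasso rule is used with a warning.
#'
#' @param z the unpenalized scalar target.
#' @param step_curvature positive curvature of the quadratic term.
#' @param spec a [penalty_spec()] with non-NULL `lam`.
#' @return the thresholded value (vectorized over `z`).
#' @export
threshold <- function(z, step_curvature, spec) {
  lam <- spec_lam(spec)
  s <- step_curvature
  if (!is.finite(s) || s <= 0) stop_validation("step_curvature must be > 0")
  az <- abs(z); sg <- sign(z)
  soft <- sg * pmax(az - lam / s, 0)
  switch(spec$family,
    lasso = soft,
    mcp = {
      if (s * spec$gamma <= 1) {
        warning("step_curvature*gamma <= 1: MCP subproblem non-convex, ",
                "falling back to lasso thresholding")
        soft
      } else {
        ifelse(az <= lam / s, 0,
               ifelse(az <= spec$gamma * lam,
                      sg * (s * az - lam) / (s - 1 / spec$gamma),
                      z))
      }
    },
    elastic_net = {
      t <- pmax(az - lam * spec$mix / s, 0)
      sg * t * s / (s + lam * (1 - spec$mix))
    })
}
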