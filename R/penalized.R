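#' Penalty specification
#'
#' Elastic-net family penalties on the genetic block of the model:
#' `lambda * sum_j (alpha*|b_j| + (1-alpha)/2 * b_j^2)`. `lasso` is
#' `alpha = 1`, `ridge` is `alpha = 0`, `elastic_net` mixes with
#' `alpha = 0.5` by default.
#'
#' @param family `"lasso"`, `"ridge"` or `"elastic_net"`.
#' @param lambda Non-negative tuning weight.
#' @param alpha Elastic-net mixing in (0, 1); used only for
#'   `elastic_net`.
#' @return List of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("lasso", "ridge", "elastic_net"),
                         lambda = 0, alpha = 0.5) {
  family <- match.arg(family)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stopf("`lambda` must be a single non-negative number")
  a <- switch(family, lasso = 1, ridge = 0, elastic_net = {
    if (alpha <= 0 || alpha >= 1) stopf("`alpha` must lie in (0, 1)")
    alpha
  })
  structure(list(family = family, lambda = lambda, alpha = a),
            class = "penalty_spec")
}

#' Partially-penalized logistic regression
#'
#' Minimizes the penalized negative log-likelihood
#' `(1/n) sum_i ( -y_i x_i'b + log(1 + exp(x_i'b)) ) + sum_l J_lambda(|b_l|)`
#' where the penalty runs over the genetic columns only; the intercept and
#' clinical covariates are never shrunk. Solved by cyclic coordinate
#' descent with a majorized curvature bound, so the objective decreases
#' monotonically across sweeps. Penalized columns are standardized
#' internally (unless `standardize = FALSE`) and coefficients are returned
#' on the original scale.
#'
#' @param X Numeric design matrix *without* intercept; column names
#'   required.
#' @param y Binary outcome in `{0, 1}`, both classes present.
#' @param penalty A [penalty_spec()].
#' @param penalized_mask Logical vector marking the penalized (genetic)
#'   columns of `X`.
#' @param variant_info Optional `data.frame` (`id`, `allele_effect`,
#'   `allele_other`) describing the penalized columns, carried into the
#'   model for external validation.
#' @param standardize Standardize penalized columns internally.
#' @param tol Convergence threshold on the maximum coefficient change per
#'   sweep (internal scale).
#' @param max_sweeps Sweep cap; non-convergence is flagged, not an error.
#' @param beta_init Optional warm-start coefficients (internal scale),
#'   as returned in `$beta_internal`.
#' @param track_objective Record the objective after every sweep (for
#'   diagnostics; adds overhead).
#' @return List of class `penalized_model`: `coefficients` (named, original
#'   scale, `(Intercept)` first), `penalty`, `penalized` (named mask),
#'   `clinical` (unpenalized column names), `variant_info`,
#'   `standardization` (centers/scales used), `converged`, `sweeps`,
#'   `objective`, `obj_path` (if tracked), `beta_internal`.
#' @export
fit_penalized_logistic <- function(X, y, penalty, penalized_mask,
                                   variant_info = NULL, standardize = TRUE,
                                   tol = 1e-7, max_sweeps = 50000L,
                                   beta_init = NULL,
                                   track_objective = FALSE) {
  stopifnot(inherits(penalty, "penalty_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) stopf("`X` must have column names")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("`y` must be binary 0/1")
  if (length(unique(y)) < 2)
    stopf("outcome has a single class: logistic fit is degenerate")
  if (length(penalized_mask) != ncol(X))
    stopf("`penalized_mask` must have one entry per column of `X`")
  pen <- as.logical(penalized_mask)

  center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  Xi <- X
  if (standardize && ncol(X)) {
    ## all columns are standardized internally: for penalized columns this
    ## defines the penalty scale; for unpenalized ones it only improves
    ## conditioning and is undone exactly on the way out
    center <- colMeans(X)
    s <- apply(X, 2, sd)
    zero_var <- s == 0 | !is.finite(s)
    s[zero_var] <- 1
    center[zero_var] <- 0
    scl <- s
    Xi <- sweep(sweep(X, 2, center), 2, scl, "/")
  }
  Xd <- cbind(`(Intercept)` = 1, Xi)
  mask <- c(FALSE, pen)
  b0 <- if (is.null(beta_init)) rep(0, ncol(Xd)) else beta_init
  res <- cd_logistic(Xd, y, mask, penalty$lambda, penalty$alpha, b0,
                     tol, as.integer(max_sweeps), track_objective)
  bi <- res$beta
  ## back-transform to the original scale
  beta <- bi
  beta[-1] <- bi[-1] / scl
  beta[1] <- bi[1] - sum(bi[-1] * center / scl)
  names(beta) <- colnames(Xd)
  if (!res$converged)
    warnf("coordinate descent hit the sweep cap (%d) before tol %.1e",
          max_sweeps, tol)
  structure(list(coefficients = beta, penalty = penalty,
                 penalized = setNames(pen, colnames(X)),
                 clinical = colnames(X)[!pen],
                 variant_info = variant_info,
                 standardization = list(center = center, scale = scl),
                 converged = res$converged, sweeps = res$sweeps,
                 objective = res$objective,
                 obj_path = if (track_objective) res$obj_path,
                 beta_internal = bi),
            class = "penalized_model")
}

#' @export
print.penalized_model <- function(x, ...) {
  nz <- sum(x$coefficients[names(which(x$penalized))] != 0)
  cat(sprintf(
    "penalized logistic model: %s (lambda = %.4g), %d clinical + %d genetic columns (%d nonzero)\n",
    x$penalty$family, x$penalty$lambda, length(x$clinical),
    sum(x$penalized), nz))
  invisible(x)
}

#' Predicted risk probabilities
#'
#' Inverse-logit of the linear predictor `x'b` for each row of `X`.
#'
#' @param model A [fit_penalized_logistic()] result.
#' @param X Design matrix containing every model column (intercept
#'   excluded); extra columns are ignored.
#' @return Vector of probabilities in (0, 1).
#' @export
predict_risk <- function(model, X) {
  stopifnot(inherits(model, "penalized_model"))
  X <- as.matrix(X)
  need <- names(model$coefficients)[-1]
  miss <- setdiff(need, colnames(X))
  if (length(miss))
    stopf("prediction matrix is missing model column(s): %s",
          paste(head(miss, 5), collapse = ", "))
  eta <- drop(X[, need, drop = FALSE] %*% model$coefficients[-1]) +
    model$coefficients[[1]]
  unname(plogis(eta))
}

#' Data-driven lambda grid
#'
#' Log-spaced from `lambda_max` (the smallest lambda that zeroes every
#' penalized coefficient given the unpenalized block, computed from the
#' standardized data) down to `min_ratio * lambda_max`. For the ridge
#' family (no finite zeroing lambda) the lasso-form `lambda_max` is used
#' with the mixing floored at 0.001, as is conventional.
#'
#' @inheritParams fit_penalized_logistic
#' @param alpha Elastic-net mixing of the target family.
#' @param n_lambda Grid size.
#' @param min_ratio Ratio of smallest to largest lambda.
#' @return Decreasing numeric vector of lambdas.
#' @export
lambda_grid <- function(X, y, penalized_mask, alpha = 1, n_lambda = 20L,
                        min_ratio = 1e-3) {
  X <- as.matrix(X)
  pen <- as.logical(penalized_mask)
  if (!any(pen)) return(0)
  ## null fit: unpenalized block only (huge lasso penalty zeroes the rest)
  null_fit <- fit_penalized_logistic(X, y, penalty_spec("lasso", 1e10),
                                     pen, standardize = TRUE, tol = 1e-8)
  mu0 <- predict_risk(null_fit, X)
  Xp <- X[, pen, drop = FALSE]
  Xs <- scale(Xp)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  lmax <- max(abs(crossprod(Xs, y - mu0))) / (nrow(X) * max(alpha, 1e-3))
  ## nudge above the exact stationarity boundary so the top of the grid
  ## really zeroes every penalized coefficient
  lmax <- max(lmax * (1 + 1e-6), 1e-8)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Area under the ROC curve
#'
#' The probability that a random case outscores a random control, ties
#' credited one half (the normalized Mann-Whitney U statistic), computed
#' exactly from midranks.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels in `{0, 1}`; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stopf("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
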