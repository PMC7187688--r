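## Shared fixture: modest logistic problem with clinical + genetic columns
pred_fixture <- function(n = 200, p_gen = 8, seed = 60) {
  set.seed(seed)
  Z <- cbind(age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5))
  G <- matrix(rbinom(n * p_gen, 2, 0.3), n, p_gen,
              dimnames = list(NULL, sprintf("g%02d", seq_len(p_gen))))
  eta <- -0.5 + 0.04 * (Z[, "age"] - 55) + 0.5 * Z[, "sex"] +
    G %*% c(0.6, -0.4, rep(0, p_gen - 2))
  y <- rbinom(n, 1, plogis(eta))
  list(X = cbind(Z, G), y = y,
       mask = c(FALSE, FALSE, rep(TRUE, p_gen)))
}

test_that("unpenalized fit matches the IRLS logistic MLE", {
  fx <- pred_fixture()
  for (fam in c("lasso", "ridge", "elastic_net")) {
    f <- fit_penalized_logistic(fx$X, fx$y, penalty_spec(fam, 0), fx$mask,
                                tol = 1e-9)
    gl <- glm(fx$y ~ fx$X, family = binomial)
    expect_lt(max(abs(f$coefficients - coef(gl))), 1e-5)
  }
})

test_that("huge lasso penalty zeroes the genetic block and leaves clinical MLE", {
  fx <- pred_fixture()
  f <- fit_penalized_logistic(fx$X, fx$y, penalty_spec("lasso", 1e6),
                              fx$mask, tol = 1e-9)
  gen <- names(which(f$penalized))
  expect_true(all(f$coefficients[gen] == 0))
  gl <- glm(fx$y ~ fx$X[, 1:2], family = binomial)
  expect_lt(max(abs(f$coefficients[1:3] - coef(gl))), 1e-5)
})

test_that("ridge solutions satisfy first-order stationarity", {
  fx <- pred_fixture()
  f <- fit_penalized_logistic(fx$X, fx$y, penalty_spec("ridge", 0.07),
                              fx$mask, standardize = FALSE, tol = 1e-10)
  b <- f$coefficients
  Xd <- cbind(1, fx$X)
  mu <- plogis(drop(Xd %*% b))
  grad <- drop(crossprod(Xd, mu - fx$y)) / nrow(fx$X)
  grad[c(FALSE, fx$mask)] <- grad[c(FALSE, fx$mask)] +
    0.07 * b[c(FALSE, fx$mask)]
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("the objective decreases monotonically across sweeps", {
  fx <- pred_fixture()
  for (fam in c("lasso", "ridge")) {
    f <- fit_penalized_logistic(fx$X, fx$y, penalty_spec(fam, 0.03),
                                fx$mask, track_objective = TRUE)
    expect_true(all(diff(f$obj_path) <= 1e-12))
  }
})

test_that("the lasso path is monotone in sparsity and matches glmnet", {
  fx <- pred_fixture(n = 300)
  lams <- exp(seq(log(0.2), log(1e-3), length.out = 12))
  nz <- vapply(lams, function(l) {
    f <- fit_penalized_logistic(fx$X, fx$y, penalty_spec("lasso", l),
                                fx$mask)
    sum(f$coefficients[names(which(f$penalized))] != 0)
  }, numeric(1))
  expect_true(all(diff(nz) >= 0))   # nonzeros grow as lambda shrinks

  ## independent cross-check against glmnet's partially-penalized fit
  pf <- as.numeric(fx$mask)
  lam <- 0.04
  gfit <- glmnet::glmnet(fx$X, fx$y, family = "binomial", alpha = 1,
                         lambda = lam * sum(pf) / ncol(fx$X),
                         penalty.factor = pf, standardize = TRUE,
                         thresh = 1e-12)
  ours <- fit_penalized_logistic(fx$X, fx$y, penalty_spec("lasso", lam),
                                 fx$mask, tol = 1e-10)
  ref <- c(gfit$a0, as.numeric(gfit$beta))
  expect_lt(max(abs(ours$coefficients - ref)), 1e-3)
})

test_that("predicted risks follow the inverse logit exactly", {
  m <- fit_penalized_logistic(matrix(rnorm(40), 20, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              rep(0:1, 10), penalty_spec("ridge", 0.1),
                              c(TRUE, TRUE))
  m$coefficients <- c(`(Intercept)` = 0.5, a = 1.0, b = 0)
  X <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_risk(m, X), 1 / (1 + exp(-1.5)), tolerance = 1e-12)
  m$coefficients[] <- 0
  expect_equal(predict_risk(m, X), 0.5)
  ## extreme linear predictors push probabilities to the limits monotonely
  m$coefficients <- c(`(Intercept)` = 0, a = 50, b = 0)
  xs <- matrix(c(-10, 0, 10, 0, 0, 0), 3, 2,
               dimnames = list(NULL, c("a", "b")))
  pr <- predict_risk(m, xs)
  expect_true(all(diff(pr) > 0))
  expect_lt(pr[1], 1e-12)
  expect_gt(pr[3], 1 - 1e-12)
  expect_error(predict_risk(m, matrix(0, 1, 1, dimnames = list(NULL, "a"))),
               "missing model column")
})

test_that("degenerate outcomes and bad masks are rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_penalized_logistic(X, rep(1, 10),
                                      penalty_spec("ridge", 0.1),
                                      c(TRUE, TRUE)), "single class")
  expect_error(fit_penalized_logistic(X, rep(0:1, 5),
                                      penalty_spec("ridge", 0.1),
                                      c(TRUE, TRUE, TRUE)), "one entry per")
  expect_error(penalty_spec("lasso", -1), "non-negative")
  expect_error(penalty_spec("elastic_net", 1, alpha = 1.2), "alpha")
})

test_that("AUC matches the pair-counting oracle including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(61)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # coarse grid forces ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), auc_oracle(s, l), tolerance = 1e-12)
  }
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("the data-driven lambda grid zeroes all penalized terms at its top", {
  fx <- pred_fixture()
  lg <- lambda_grid(fx$X, fx$y, fx$mask, alpha = 1, n_lambda = 5)
  expect_true(all(diff(lg) < 0))
  f <- fit_penalized_logistic(fx$X, fx$y, penalty_spec("lasso", lg[1]),
                              fx$mask, tol = 1e-9)
  expect_true(all(f$coefficients[names(which(f$penalized))] == 0))
  ## just below lambda_max at least one variant enters
  f2 <- fit_penalized_logistic(fx$X, fx$y, penalty_spec("lasso",
                                                        lg[1] * 0.8),
                               fx$mask, tol = 1e-9)
  expect_gt(sum(f2$coefficients[names(which(f2$penalized))] != 0), 0)
})
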