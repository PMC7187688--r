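## Covariate matrix utilities -------------------------------------------

## Builds the fixed-effect design (intercept + covariates) and checks rank.
.design_matrix <- function(Z, n) {
  if (is.null(Z)) {
    Zm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    return(Zm)
  }
  if (is.data.frame(Z)) Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  has_const <- any(apply(Z, 2, function(c) all(c == c[1])))
  Zm <- if (has_const) Z else cbind(`(Intercept)` = 1, Z)
  qrz <- qr(Zm)
  if (qrz$rank < ncol(Zm)) {
    bad <- colnames(Zm)[qrz$pivot[(qrz$rank + 1):ncol(Zm)]]
    stopf("collinear fixed-effect columns: %s", paste(bad, collapse = ", "))
  }
  Zm
}

#' Restricted log-likelihood of the GRM mixed model
#'
#' Evaluates the REML log-likelihood of `y ~ MVN(Z beta, sigma_g2 K +
#' sigma_e2 I)` at given variance components, sharing the eigendecomposition
#' of `K` across evaluations. Used both by the fitter and as an independent
#' surface for grid-search checks.
#'
#' @param y Trait vector.
#' @param Z Covariate matrix/data.frame (intercept added if absent).
#' @param K A [compute_grm()] result, a plain matrix, or an `eigen()`
#'   decomposition of the GRM.
#' @param sigma_g2,sigma_e2 Variance components (`sigma_e2 > 0`).
#' @return Restricted log-likelihood (includes the `-(n-q)/2 log(2*pi)`
#'   constant).
#' @export
reml_loglik <- function(y, Z, K, sigma_g2, sigma_e2) {
  n <- length(y)
  e <- if (is.list(K) && !is.null(K$vectors)) K else grm_eigen(K)
  Zm <- .design_matrix(Z, n)
  q <- ncol(Zm)
  ys <- crossprod(e$vectors, y)
  Zs <- crossprod(e$vectors, Zm)
  w <- sigma_g2 * e$values + sigma_e2
  if (any(w <= 0)) return(-Inf)
  A <- crossprod(Zs, Zs / w)
  b <- crossprod(Zs, ys / w)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  r <- ys - Zs %*% beta
  ypy <- sum(r^2 / w)
  -0.5 * (sum(log(w)) + 2 * sum(log(diag(ch))) + ypy + (n - q) * log(2 * pi))
}

## Profiled REML criterion over h2 with total variance profiled out
## analytically; returns the restricted log-likelihood and the implied
## components. Operates in the rotated basis.
.reml_profile <- function(h2, ys, Zs, d, n, q) {
  w <- h2 * d + (1 - h2)
  A <- crossprod(Zs, Zs / w)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Zs, ys / w)))
  r <- ys - Zs %*% beta
  rss_w <- sum(r^2 / w)
  s2 <- rss_w / (n - q)
  ll <- -0.5 * ((n - q) * log(s2) + sum(log(w)) + 2 * sum(log(diag(ch))) +
                  (n - q) + (n - q) * log(2 * pi))
  list(ll = ll, s2 = s2, beta = beta)
}

#' REML fit of the single-GRM mixed model
#'
#' Fits `y ~ MVN(Z beta, sigma_g2 K + sigma_e2 I)` by restricted maximum
#' likelihood. The heritability ratio is profiled against the cached
#' eigendecomposition of `K` (total variance has a closed-form profile), so
#' the optimum is located by a dense scan plus golden-section refinement on
#' one dimension; the non-negativity boundary `h2 = 0` is always evaluated.
#'
#' @inheritParams reml_loglik
#' @param K A [compute_grm()] result or plain symmetric matrix.
#' @param n_grid Size of the initial `h2` scan.
#' @param tol Convergence tolerance of the 1-D refinement on `h2`.
#' @return List of class `reml_fit` with `sigma_g2`, `sigma_e2`, `h2`,
#'   `se` (delta-method standard errors from the numerical information
#'   matrix; may be `NA` at the boundary), `loglik`, `converged`,
#'   `n_iterations`, `fixed_effects` (named vector), `eigen` (reusable
#'   factorization) and `residuals` (`y - Z beta_hat`).
#' @export
reml_fit <- function(y, Z, K, n_grid = 64L, tol = 1e-10) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stopf("trait vector contains missing values")
  Zm <- .design_matrix(Z, n)
  q <- ncol(Zm)
  if (n < q + 2) stopf("too few samples (%d) for %d fixed effects", n, q)
  e <- grm_eigen(K)
  ys <- drop(crossprod(e$vectors, y))
  Zs <- crossprod(e$vectors, Zm)

  crit <- function(h2) .reml_profile(h2, ys, Zs, e$values, n, q)$ll
  grid <- seq(0, 0.999, length.out = n_grid)
  lls <- vapply(grid, crit, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- optimize(crit, c(lo, hi), maximum = TRUE, tol = tol)
  h2 <- opt$maximum; ll <- opt$objective
  if (lls[1] >= ll) { h2 <- 0; ll <- lls[1] }   # boundary wins
  prof <- .reml_profile(h2, ys, Zs, e$values, n, q)
  s2_tot <- prof$s2
  sigma_g2 <- h2 * s2_tot
  sigma_e2 <- (1 - h2) * s2_tot

  ## SEs from a finite-difference information matrix on (sigma_g2, sigma_e2)
  se <- c(sigma_g2 = NA_real_, sigma_e2 = NA_real_, h2 = NA_real_)
  if (h2 > 1e-6) {
    se <- tryCatch({
      f <- function(th) reml_loglik(y, Zm, e, th[1], th[2])
      th <- c(sigma_g2, sigma_e2)
      h <- pmax(1e-4 * th, 1e-8)
      H <- matrix(0, 2, 2)
      for (a in 1:2) for (b in 1:2) {
        ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
        H[a, b] <- (f(th + ea + eb) - f(th + ea - eb) -
                      f(th - ea + eb) + f(th - ea - eb)) / (4 * h[a] * h[b])
      }
      V <- solve(-H)
      gh <- c(sigma_e2, -sigma_g2) / (sigma_g2 + sigma_e2)^2  # d h2 / d theta
      c(sigma_g2 = sqrt(V[1, 1]), sigma_e2 = sqrt(V[2, 2]),
        h2 = sqrt(drop(t(gh) %*% V %*% gh)))
    }, error = function(err) se, warning = function(wrn) se)
  }
  beta <- drop(prof$beta)
  names(beta) <- colnames(Zm)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2,
                 se = se, loglik = ll, converged = TRUE,
                 n_iterations = n_grid + 1L,
                 fixed_effects = beta, design = Zm,
                 residuals = drop(y - Zm %*% prof$beta), eigen = e),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "REML fit: sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f (SE %.3f), logLik = %.3f\n",
    x$sigma_g2, x$sigma_e2, x$h2, x$se[["h2"]], x$loglik))
  invisible(x)
}

#' Multi-component (chromosome-partitioned) REML
#'
#' Jointly fits `V = sum_c sigma_c2 K_c + sigma_e2 I` by
#' average-information REML with EM fallback steps and projection onto the
#' non-negative orthant. Reports each component and its share of the total
#' genetic variance (the relative chromosomal SNP heritability when the
#' `K_c` are per-chromosome GRMs).
#'
#' @inheritParams reml_fit
#' @param grms List of two or more [compute_grm()] results (or matrices)
#'   over identical samples.
#' @param max_iter,tol_ll Iteration cap and restricted-log-likelihood
#'   convergence tolerance.
#' @return List of class `reml_fit_partitioned`: `sigma_c2` (named vector),
#'   `sigma_e2`, `shares` (`sigma_c2 / sum(sigma_c2)`), `h2_total`,
#'   `loglik`, `converged`, `n_iterations`, `fixed_effects`.
#' @export
reml_fit_partitioned <- function(y, Z, grms, max_iter = 200L, tol_ll = 1e-8) {
  if (length(grms) < 1) stopf("need at least one variance component")
  Ks <- lapply(grms, function(k) if (inherits(k, "grm")) k$matrix else k)
  n <- length(y)
  if (any(vapply(Ks, nrow, 1L) != n))
    stopf("component GRMs must cover the same samples as `y`")
  Zm <- .design_matrix(Z, n)
  q <- ncol(Zm)
  nc <- length(Ks)
  vy <- var(y)
  theta <- rep(vy / (nc + 1), nc + 1)   # components then residual
  floor_v <- 1e-8 * vy

  eval_state <- function(theta) {
    V <- diag(theta[nc + 1], n)
    for (c in seq_len(nc)) V <- V + theta[c] * Ks[[c]]
    ch <- chol(V)
    Vi <- chol2inv(ch)
    ViZ <- Vi %*% Zm
    ZtViZ <- crossprod(Zm, ViZ)
    chA <- chol(ZtViZ)
    beta <- backsolve(chA, forwardsolve(t(chA), crossprod(ViZ, y)))
    P <- Vi - ViZ %*% chol2inv(chA) %*% t(ViZ)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chA))) +
                    sum(y * Py) + (n - q) * log(2 * pi))
    list(P = P, Py = Py, ll = ll, beta = beta)
  }

  st <- eval_state(theta)
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    KPy <- vector("list", nc + 1)
    trPK <- numeric(nc + 1)
    for (c in seq_len(nc)) {
      KPy[[c]] <- Ks[[c]] %*% Py
      trPK[c] <- sum(P * Ks[[c]])
    }
    KPy[[nc + 1]] <- Py
    trPK[nc + 1] <- sum(diag(P))
    score <- vapply(seq_len(nc + 1), function(c)
      -0.5 * (trPK[c] - sum(Py * KPy[[c]])), numeric(1))
    PKPy <- lapply(KPy, function(v) P %*% v)
    AI <- matrix(0, nc + 1, nc + 1)
    for (a in seq_len(nc + 1)) for (b in a:(nc + 1)) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(KPy[[a]] * PKPy[[b]])
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    cand <- if (!is.null(step)) pmax(theta + step, floor_v) else NULL
    st_new <- NULL
    if (!is.null(cand)) {
      st_new <- tryCatch(eval_state(cand), error = function(e) NULL)
      if (!is.null(st_new) && st_new$ll < st$ll - 1e-10) st_new <- NULL
    }
    if (is.null(st_new)) {   # EM fallback (guaranteed ascent direction)
      cand <- pmax(theta + theta^2 *
                     (vapply(seq_len(nc + 1), function(c)
                       sum(Py * KPy[[c]]), numeric(1)) - trPK) / n, floor_v)
      st_new <- eval_state(cand)
    }
    dll <- st_new$ll - st$ll
    theta <- cand; st <- st_new
    if (abs(dll) < tol_ll) { converged <- TRUE; break }
  }
  sigma_c2 <- theta[seq_len(nc)]
  sigma_c2[sigma_c2 <= 2 * floor_v] <- sigma_c2[sigma_c2 <= 2 * floor_v] - floor_v
  sigma_c2 <- pmax(sigma_c2, 0)
  names(sigma_c2) <- if (!is.null(names(grms))) names(grms)
  else paste0("component", seq_len(nc))
  tot <- sum(sigma_c2)
  beta <- drop(st$beta); names(beta) <- colnames(Zm)
  structure(list(sigma_c2 = sigma_c2, sigma_e2 = theta[nc + 1],
                 shares = if (tot > 0) sigma_c2 / tot else sigma_c2 * 0,
                 h2_total = tot / (tot + theta[nc + 1]),
                 loglik = st$ll, converged = converged, n_iterations = it,
                 fixed_effects = beta),
            class = "reml_fit_partitioned")
}
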