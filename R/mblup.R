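#' REML fit of the single-kernel mixed model
#'
#' Fits `y = 1 mu + m + e` with `m ~ N(0, M sigma2_m)` and
#' `e ~ N(0, I sigma2_e)` by restricted maximum likelihood. The kernel is
#' eigendecomposed once and the REML criterion is profiled over the variance
#' fraction `h = Mbar sigma2_m / sigma2_P` (which equals the relative
#' variance component RVCm), with the total variance `sigma2_P` solved in
#' closed form at each `h`; a one-dimensional bounded search on
#' `h in [1e-6, 1 - 1e-6]` finds the optimum. The intercept is the GLS
#' estimate at the optimum. An approximate standard error of RVCm from the
#' curvature of the profiled criterion is reported as `rvc_se`.
#'
#' @param y numeric trait vector, ordered as `kernel$sample_ids` (or named
#'   by sample id, in which case it is reordered). Must have positive
#'   variance.
#' @param kernel a [build_similarity()] result.
#' @param bounds search interval for the variance fraction.
#' @param tol relative convergence tolerance of the 1-D search.
#' @return An object of class `mblup_vc` with elements `sigma2_m`,
#'   `sigma2_e`, `sigma2_P`, `mean_diag`, `rvc_m`, `rvc_se`, `mu_hat`,
#'   `reml_loglik`, `converged`, `at_bound`, `n_used`.
#' @export
reml_fit <- function(y, kernel, bounds = c(1e-6, 1 - 1e-6), tol = 1e-8) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  n <- nrow(kernel$M)
  if (!is.null(names(y))) {
    idx <- match(kernel$sample_ids, names(y))
    if (anyNA(idx)) stop("y names do not cover kernel sample_ids")
    y <- as.numeric(y[idx])
  }
  if (length(y) != n) stop("length(y) must match kernel order")
  if (stats::var(y) <= 0) stop("y has zero variance")

  eg <- eigen(kernel$M, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < -1e-8 * max(lam)) {
    stop("kernel is not positive semidefinite within tolerance")
  }
  lam <- pmax(lam, 0)
  mbar <- mean(diag(kernel$M))
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))

  # profiled negative REML criterion in h (constant terms included)
  prof <- function(h) {
    d <- h * lam / mbar + (1 - h)
    sxx <- sum(xt^2 / d)
    mu <- sum(xt * yt / d) / sxx
    rss <- sum((yt - xt * mu)^2 / d)
    s2p <- rss / (n - 1)
    ll <- -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2p) +
                    sum(log(d)) + log(sxx) + (n - 1))
    list(loglik = ll, mu = mu, s2p = s2p)
  }
  opt <- stats::optimize(function(h) prof(h)$loglik,
                         interval = bounds, maximum = TRUE,
                         tol = max(tol, .Machine$double.eps^0.5 * 1e-2))
  h <- opt$maximum
  at_bound <- (h - bounds[1] < 1e-5) || (bounds[2] - h < 1e-5)
  fit <- prof(h)
  s2p <- fit$s2p
  sigma2_m <- h * s2p / mbar
  sigma2_e <- (1 - h) * s2p

  # curvature-based approximate SE of h (= RVCm)
  eps <- 1e-4
  h1 <- min(max(h, bounds[1] + eps), bounds[2] - eps)
  d2 <- (prof(h1 + eps)$loglik - 2 * prof(h1)$loglik +
           prof(h1 - eps)$loglik) / eps^2
  rvc_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_

  structure(list(sigma2_m = sigma2_m, sigma2_e = sigma2_e, sigma2_P = s2p,
                 mean_diag = mbar,
                 rvc_m = mbar * sigma2_m / (mbar * sigma2_m + sigma2_e),
                 rvc_se = rvc_se, mu_hat = fit$mu,
                 reml_loglik = fit$loglik, converged = TRUE,
                 at_bound = at_bound, n_used = n),
            class = "mblup_vc")
}

#' @export
print.mblup_vc <- function(x, ...) {
  cat(sprintf(
    "mblup_vc: sigma2_m %.5g, sigma2_e %.5g, RVCm %.4f (se %.4f), mu %.4g, logLik %.3f%s\n",
    x$sigma2_m, x$sigma2_e, x$rvc_m, x$rvc_se, x$mu_hat, x$reml_loglik,
    if (x$at_bound) " [at bound]" else ""))
  invisible(x)
}

#' Relative variance component
#'
#' The fraction of total phenotypic variance attributed to metabolomic
#' effects: `Mbar sigma2_m / (Mbar sigma2_m + sigma2_e)`.
#'
#' @param vc an `mblup_vc`, or a list with `sigma2_m`, `sigma2_e`,
#'   `mean_diag`.
#' @return A number in `[0, 1]`.
#' @export
relative_variance <- function(vc) {
  mbar <- if (is.null(vc$mean_diag)) 1 else vc$mean_diag
  num <- mbar * vc$sigma2_m
  den <- num + vc$sigma2_e
  if (den == 0) stop("both variance components are zero")
  num / den
}

#' BLUP prediction of held-out samples
#'
#' Predicts target phenotypes from training phenotypes and the similarity
#' matrix: `yhat = mu + M[target, train] (M[train, train] + lambda I)^-1
#' (y_train - mu)` with `lambda = sigma2_e / sigma2_m` and `mu` the GLS
#' intercept on the training block. With `sigma2_m = 0` all predictions are
#' the training mean.
#'
#' @param vc variance components (an `mblup_vc`).
#' @param y_train training trait values, ordered as `train_ids` (or named).
#' @param kernel full [build_similarity()] kernel covering both id sets.
#' @param train_ids,target_ids disjoint subsets of `kernel$sample_ids`.
#' @return Named numeric vector of predictions for `target_ids`.
#' @export
blup_predict <- function(vc, y_train, kernel, train_ids, target_ids) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  ti <- match(train_ids, kernel$sample_ids)
  vi <- match(target_ids, kernel$sample_ids)
  if (anyNA(ti) || anyNA(vi)) stop("ids not present in kernel")
  if (length(intersect(train_ids, target_ids)) > 0L) {
    stop("train_ids and target_ids must be disjoint")
  }
  if (!is.null(names(y_train))) y_train <- as.numeric(y_train[train_ids])
  if (length(y_train) != length(ti)) stop("y_train length mismatch")

  if (vc$sigma2_m <= 0) {
    out <- rep(mean(y_train), length(vi))
    names(out) <- target_ids
    return(out)
  }
  lambda <- vc$sigma2_e / vc$sigma2_m
  A <- kernel$M[ti, ti, drop = FALSE]
  diag(A) <- diag(A) + lambda
  sol <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(sol)) {
    diag(A) <- diag(A) + 1e-10
    sol <- tryCatch(chol(A), error = function(e)
      stop("singular training system in blup_predict"))
  }
  ones <- rep(1, length(ti))
  a1 <- backsolve(sol, forwardsolve(t(sol), ones))
  mu <- sum(a1 * y_train) / sum(a1)
  ay <- backsolve(sol, forwardsolve(t(sol), y_train - mu))
  out <- drop(mu + kernel$M[vi, ti, drop = FALSE] %*% ay)
  names(out) <- target_ids
  out
}
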