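#' Fit a univariate partial least squares regression (NIPALS PLS1)
#'
#' Decomposes the (training-centered) feature matrix into orthogonal scores
#' and loadings and regresses the response on the scores. Per component:
#' `w = Q'y` normalized, `t = Qw`, `p = Q't / t't`, `q = y't / t't`, then
#' deflation `Q <- Q - t p'`, `y <- y - t q`. Regression coefficients on the
#' original feature scale are `W (P'W)^-1 q`, folded with the centering into
#' `(coefficients, intercept)`. Features are centered on training means but
#' not re-scaled (global standardization is preprocessing's job).
#'
#' @param Q numeric n x m matrix (or a [standardized_matrix()], whose `$Q`
#'   is used).
#' @param y numeric response of length n.
#' @param n_components number of latent components, at most `min(n - 1, m)`.
#' @return An object of class `pls1_model` with `weights` (W), `x_loadings`
#'   (P), `y_loadings` (q), `scores` (T), `x_center`, `y_center`,
#'   `coefficients`, `intercept`, `n_components` (attained).
#' @export
pls1_fit <- function(Q, y, n_components) {
  if (inherits(Q, "standardized_matrix")) Q <- Q$Q
  Q <- as.matrix(Q)
  y <- as.numeric(y)
  n <- nrow(Q); m <- ncol(Q)
  stopifnot(length(y) == n, all(is.finite(Q)), all(is.finite(y)))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, m)) {
    stop("n_components must be in 1..min(n-1, m)")
  }
  x_center <- colMeans(Q)
  y_center <- mean(y)
  E <- sweep(Q, 2, x_center)
  f <- y - y_center
  W <- matrix(0, m, n_components)
  P <- matrix(0, m, n_components)
  Tm <- matrix(0, n, n_components)
  qload <- numeric(n_components)
  attained <- 0L
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(f^2)))) {
      warning("zero weight vector at component ", a,
              "; stopping at ", attained, " components")
      break
    }
    w <- w / nw
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    p <- drop(crossprod(E, tt)) / t2
    qa <- sum(f * tt) / t2
    E <- E - tcrossprod(tt, p)
    f <- f - tt * qa
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; qload[a] <- qa
    attained <- a
  }
  if (attained == 0L) stop("response is orthogonal to all features")
  W <- W[, seq_len(attained), drop = FALSE]
  P <- P[, seq_len(attained), drop = FALSE]
  Tm <- Tm[, seq_len(attained), drop = FALSE]
  qload <- qload[seq_len(attained)]
  coef_path <- pls1_coef_path(W, P, qload)
  coefficients <- coef_path[, attained]
  structure(list(weights = W, x_loadings = P, y_loadings = qload,
                 scores = Tm, x_center = x_center, y_center = y_center,
                 coefficients = coefficients,
                 intercept = y_center - sum(x_center * coefficients),
                 coef_path = coef_path,
                 n_components = attained),
            class = "pls1_model")
}

# internal: m x t matrix whose column a holds the coefficients of the
# a-component model, B_a = W_a (P_a' W_a)^-1 q_a
pls1_coef_path <- function(W, P, qload) {
  t <- length(qload)
  out <- matrix(0, nrow(W), t)
  R <- crossprod(P, W)   # upper triangular in exact arithmetic
  for (a in seq_len(t)) {
    out[, a] <- W[, seq_len(a), drop = FALSE] %*%
      solve(R[seq_len(a), seq_len(a), drop = FALSE], qload[seq_len(a)])
  }
  out
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("pls1_model: %d components, %d features\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS1 model
#'
#' @param model a [pls1_fit()] result.
#' @param Q_new matrix with the same feature columns as the training matrix.
#' @param n_components optionally predict from a smaller number of
#'   components than the model was fit with.
#' @return Numeric predictions, one per row of `Q_new`.
#' @export
pls1_predict <- function(model, Q_new, n_components = NULL) {
  if (inherits(Q_new, "standardized_matrix")) Q_new <- Q_new$Q
  Q_new <- as.matrix(Q_new)
  if (ncol(Q_new) != length(model$coefficients)) {
    stop("Q_new has ", ncol(Q_new), " columns; model expects ",
         length(model$coefficients))
  }
  if (is.null(n_components)) {
    b <- model$coefficients
  } else {
    a <- min(as.integer(n_components), model$n_components)
    b <- model$coef_path[, a]
  }
  drop(Q_new %*% b) + model$y_center - sum(model$x_center * b)
}

#' Leave-one-out tuning of the component count
#'
#' For each candidate component count, leaves each training sample out in
#' turn, refits, and predicts it; reports the LOO correlation and RMSE per
#' count. The selected count maximizes the LOO correlation, ties broken
#' toward fewer components. Grid values exceeding `n - 2` are skipped with a
#' warning.
#'
#' @param Q training feature matrix (or [standardized_matrix()]).
#' @param y training response.
#' @param component_grid candidate counts, default `c(5, 10, 20, 50)`.
#' @return List with `table` (data frame: n_components, loo_cor, loo_rmse)
#'   and `selected`.
#' @export
loo_tune <- function(Q, y, component_grid = c(5, 10, 20, 50)) {
  if (inherits(Q, "standardized_matrix")) Q <- Q$Q
  Q <- as.matrix(Q)
  y <- as.numeric(y)
  n <- nrow(Q)
  if (n < 5L) stop("leave-one-out tuning needs at least 5 samples")
  grid <- sort(unique(as.integer(component_grid)))
  ok <- grid <= n - 2L & grid <= ncol(Q) & grid >= 1L
  if (any(!ok)) {
    warning("skipping component counts not supported by the data: ",
            paste(grid[!ok], collapse = ", "))
    grid <- grid[ok]
  }
  if (length(grid) == 0L) stop("no valid component counts in grid")
  tmax <- max(grid)
  pred <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    fit <- suppressWarnings(pls1_fit(Q[-i, , drop = FALSE], y[-i], tmax))
    for (j in seq_along(grid)) {
      pred[i, j] <- pls1_predict(fit, Q[i, , drop = FALSE],
                                 n_components = grid[j])
    }
  }
  loo_cor <- apply(pred, 2, function(p) suppressWarnings(stats::cor(y, p)))
  loo_rmse <- apply(pred, 2, function(p) sqrt(mean((y - p)^2)))
  tab <- data.frame(n_components = grid, loo_cor = loo_cor,
                    loo_rmse = loo_rmse)
  sel <- grid[which.max(loo_cor)]  # which.max takes the first maximum
  list(table = tab, selected = sel)
}
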