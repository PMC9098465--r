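# Independent oracles, coded without shortcuts, used to cross-check the
# implementation paths.

# textbook NIPALS PLS1 with explicit deflation; fitted values via the score
# path (regression of the response on each score), no coefficient shortcut
oracle_nipals <- function(X, y, ncomp) {
  xc <- colMeans(X); yc <- mean(y)
  E <- sweep(X, 2, xc)
  f <- y - yc
  W <- NULL; P <- NULL; Tm <- NULL; q <- c()
  for (a in seq_len(ncomp)) {
    w <- t(E) %*% f
    w <- w / sqrt(sum(w^2))
    tt <- E %*% w
    p <- t(E) %*% tt / drop(t(tt) %*% tt)
    qa <- drop(t(f) %*% tt / drop(t(tt) %*% tt))
    E <- E - tt %*% t(p)
    f <- f - tt * qa
    W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, tt); q <- c(q, qa)
  }
  beta <- W %*% solve(t(P) %*% W) %*% q
  list(coefficients = drop(beta),
       intercept = yc - sum(xc * beta),
       fitted = drop(Tm %*% q) + yc,
       scores = Tm, weights = W, loadings = P, q = q,
       x_center = xc, y_center = yc)
}

# ridge regression on the feature columns with penalty `penalty`, response
# centered on the given intercept; direct solve in feature space
oracle_ridge_predict <- function(Q_train, y_train, Q_new, penalty, mu) {
  m <- ncol(Q_train)
  A <- crossprod(Q_train) + diag(penalty, m)
  beta <- solve(A, crossprod(Q_train, y_train - mu))
  drop(mu + Q_new %*% beta)
}

# entry-by-entry double-loop similarity matrix
oracle_similarity <- function(Q) {
  n <- nrow(Q); m <- ncol(Q)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) s <- s + Q[i, j] * Q[k, j]
    M[i, k] <- s / m
  }
  M
}

# simulate directly under the mixed model: y = mu + m + e with
# m ~ N(0, M sigma2_m) via the eigendecomposition of M
simulate_from_model <- function(kernel, sigma2_m, sigma2_e, mu = 0) {
  eg <- eigen(kernel$M, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  n <- length(lam)
  m <- drop(eg$vectors %*% (sqrt(lam * sigma2_m) * rnorm(n)))
  y <- mu + m + rnorm(n, 0, sqrt(sigma2_e))
  names(y) <- kernel$sample_ids
  y
}
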