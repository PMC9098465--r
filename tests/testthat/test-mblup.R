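test_that("relative variance component follows its closed form", {
  expect_equal(relative_variance(list(sigma2_m = 9, sigma2_e = 1,
                                      mean_diag = 1)), 0.9)
  expect_equal(relative_variance(list(sigma2_m = 0, sigma2_e = 2,
                                      mean_diag = 1)), 0)
  set.seed(3)
  for (i in 1:10) {
    sm <- runif(1, 0.01, 5); se <- runif(1, 0.01, 5); md <- runif(1, 0.5, 2)
    expect_equal(relative_variance(list(sigma2_m = sm, sigma2_e = se,
                                        mean_diag = md)),
                 md * sm / (md * sm + se), tolerance = 1e-15)
  }
  expect_error(relative_variance(list(sigma2_m = 0, sigma2_e = 0,
                                      mean_diag = 1)), "zero")
})

test_that("REML finds the limits: pure noise and noise-free signal", {
  set.seed(12)
  std <- random_standardized(300, 400, seed = 12)
  M <- build_similarity(std)
  y_noise <- rnorm(300)
  names(y_noise) <- std$plot_ids
  vc0 <- reml_fit(y_noise, M)
  expect_lt(vc0$rvc_m, 0.05)
  # noise-free limit: with a rank-deficient kernel (m < n) the null
  # directions carry no signal, so REML pins the fraction at the upper bound
  std2 <- random_standardized(300, 100, seed = 13)
  M2 <- build_similarity(std2)
  set.seed(13)
  y_pure <- simulate_from_model(M2, sigma2_m = 1, sigma2_e = 0)
  vc1 <- reml_fit(y_pure, M2)
  expect_gt(vc1$rvc_m, 0.98)
  expect_true(vc1$at_bound)
})

test_that("the rvc invariant links the stored components exactly", {
  std <- random_standardized(60, 80, seed = 14)
  M <- build_similarity(std)
  set.seed(15)
  y <- simulate_from_model(M, 2, 1, mu = 3)
  vc <- reml_fit(y, M)
  expect_equal(vc$rvc_m,
               vc$mean_diag * vc$sigma2_m /
                 (vc$mean_diag * vc$sigma2_m + vc$sigma2_e),
               tolerance = 1e-12)
  expect_true(vc$converged)
})

test_that("no point on a 50-point ratio grid beats the optimizer", {
  std <- random_standardized(80, 100, seed = 16)
  M <- build_similarity(std)
  set.seed(17)
  y <- simulate_from_model(M, 1, 0.5, mu = 1)
  vc <- reml_fit(y, M)
  # recompute the profiled criterion on a grid via an independent path
  eg <- eigen(M$M, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  mbar <- mean(diag(M$M))
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, length(y))))
  n <- length(y)
  prof <- function(h) {
    d <- h * lam / mbar + (1 - h)
    sxx <- sum(xt^2 / d)
    mu <- sum(xt * yt / d) / sxx
    s2p <- sum((yt - xt * mu)^2 / d) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2p) + sum(log(d)) +
              log(sxx) + (n - 1))
  }
  grid <- seq(1e-6, 1 - 1e-6, length.out = 50)
  expect_gte(vc$reml_loglik, max(vapply(grid, prof, numeric(1))) - 1e-6)
})

test_that("outputs are invariant to joint permutation of y and M", {
  std <- random_standardized(50, 60, seed = 18)
  M <- build_similarity(std)
  set.seed(19)
  y <- simulate_from_model(M, 1.5, 0.5, mu = 2)
  vc <- reml_fit(y, M)
  perm <- sample(50)
  Mp <- M
  Mp$M <- M$M[perm, perm]
  Mp$sample_ids <- M$sample_ids[perm]
  vcp <- reml_fit(y[perm], Mp)
  expect_equal(vcp$rvc_m, vc$rvc_m, tolerance = 1e-6)
  expect_equal(vcp$mu_hat, vc$mu_hat, tolerance = 1e-6)
  expect_equal(vcp$reml_loglik, vc$reml_loglik, tolerance = 1e-6)
})

test_that("BLUP equals feature-space ridge regression with matched penalty", {
  set.seed(20)
  for (rep in 1:5) {
    n <- sample(20:40, 1); m <- sample(30:60, 1)
    std <- random_standardized(n, m, seed = 100 + rep)
    M <- build_similarity(std)
    y <- simulate_from_model(M, 1, 0.5, mu = 2)
    tr <- std$plot_ids[seq_len(n - 5)]
    va <- setdiff(std$plot_ids, tr)
    vc <- reml_fit(y[tr], subset_kernel(M, tr))
    pred <- blup_predict(vc, y[tr], M, tr, va)
    # ridge with penalty m * lambda on centered response, same intercept
    lambda <- vc$sigma2_e / vc$sigma2_m
    Qt <- std$Q[tr, , drop = FALSE]
    A <- solve(M$M[tr, tr] + diag(lambda, length(tr)), rep(1, length(tr)))
    mu <- sum(A * y[tr]) / sum(A)
    oracle <- oracle_ridge_predict(Qt, y[tr], std$Q[va, , drop = FALSE],
                                   penalty = m * lambda, mu = mu)
    expect_lt(max(abs(pred - oracle)), 1e-8)
  }
})

test_that("BLUP interpolates duplicated samples as lambda -> 0", {
  std <- random_standardized(12, 40, seed = 23)
  M <- build_similarity(std)
  # make the target row duplicate training sample 3 in feature space
  Q <- std$Q
  Q[12, ] <- Q[3, ]
  M2 <- M
  M2$M <- tcrossprod(Q) / ncol(Q)
  set.seed(24)
  y <- rnorm(11)
  names(y) <- std$plot_ids[1:11]
  vc <- list(sigma2_m = 1, sigma2_e = 1e-10, mean_diag = 1)
  pred <- blup_predict(vc, y, M2, train_ids = std$plot_ids[1:11],
                       target_ids = std$plot_ids[12])
  expect_equal(unname(pred), unname(y[3]), tolerance = 1e-6)
})

test_that("BLUP collapses to the training mean when sigma2_m is zero", {
  std <- random_standardized(10, 20, seed = 25)
  M <- build_similarity(std)
  set.seed(26)
  y <- rnorm(7)
  names(y) <- std$plot_ids[1:7]
  vc <- list(sigma2_m = 0, sigma2_e = 1, mean_diag = 1)
  pred <- blup_predict(vc, y, M, std$plot_ids[1:7], std$plot_ids[8:10])
  expect_equal(unname(pred), rep(mean(y), 3))
  expect_error(blup_predict(vc, y, M, std$plot_ids[1:7], std$plot_ids[7]),
               "disjoint")
})

test_that("rvc estimation error shrinks with sample size under the model", {
  mae <- vapply(c(100, 400, 1200), function(n) {
    errs <- vapply(1:3, function(s) {
      std <- random_standardized(n, 300, seed = 1000 * s + n)
      M <- build_similarity(std)
      set.seed(2000 * s + n)
      y <- simulate_from_model(M, 0.8, 0.2, mu = 1)   # true rvc = 0.8
      abs(reml_fit(y, M)$rvc_m - 0.8)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mae[3], mae[1])
})

test_that("a non-PSD kernel is rejected", {
  M <- build_similarity(random_standardized(6, 10, seed = 27))
  M$M[1, 2] <- M$M[2, 1] <- 10   # breaks positive semidefiniteness
  y <- rnorm(6)
  names(y) <- M$sample_ids
  expect_error(reml_fit(y, M), "positive semidefinite")
})
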