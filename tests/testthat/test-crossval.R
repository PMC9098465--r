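make_meta <- function(n_lines, plots_per_line, locations = c("A", "B")) {
  data.frame(
    plot_id = sprintf("p%03d", seq_len(n_lines * plots_per_line)),
    line_id = rep(sprintf("l%02d", seq_len(n_lines)), each = plots_per_line),
    location = rep_len(locations, n_lines * plots_per_line),
    stringsAsFactors = FALSE)
}

test_that("LINE folds partition plots by line", {
  meta <- make_meta(3, 4)
  fp <- make_folds("LINE", meta)
  expect_length(fp$folds, 3L)
  for (f in fp$folds) {
    expect_setequal(f$validation, meta$plot_id[meta$line_id == f$label])
    expect_length(intersect(f$train, f$validation), 0L)
  }
  pooled <- unlist(lapply(fp$folds, `[[`, "validation"))
  expect_setequal(pooled, meta$plot_id)
  expect_equal(anyDuplicated(pooled), 0L)
})

test_that("LOC folds leave out one location each", {
  meta <- make_meta(4, 4)
  fp <- make_folds("LOC", meta)
  expect_length(fp$folds, 2L)
  pooled <- unlist(lapply(fp$folds, `[[`, "validation"))
  expect_setequal(pooled, meta$plot_id)
  expect_equal(anyDuplicated(pooled), 0L)
  expect_error(make_folds("LOC", transform(meta, location = "A")),
               "at least 2")
})

test_that("SIZE folds have the requested size, are disjoint and seeded", {
  meta <- make_meta(20, 5)   # 100 plots
  fp <- make_folds("SIZE", meta, tp_size = 50, n_replicates = 15, seed = 11)
  expect_length(fp$folds, 15L)
  for (f in fp$folds) {
    expect_length(f$train, 50L)
    expect_length(f$validation, 50L)
    expect_length(intersect(f$train, f$validation), 0L)
  }
  fp2 <- make_folds("SIZE", meta, tp_size = 50, n_replicates = 15, seed = 11)
  expect_identical(fp$folds, fp2$folds)
  fp3 <- make_folds("SIZE", meta, tp_size = 50, n_replicates = 15, seed = 12)
  expect_false(identical(fp$folds, fp3$folds))
  expect_error(make_folds("SIZE", meta, tp_size = 100), "smaller")
  expect_error(make_folds("SIZE", meta), "tp_size")
})

test_that("a stub predictor sees only training data", {
  meta <- make_meta(10, 3)
  set.seed(1)
  y <- rnorm(30)
  names(y) <- meta$plot_id
  fp <- make_folds("LINE", meta)
  stub <- function(y_train, train_ids, target_ids) {
    p <- rep(mean(y_train), length(target_ids))
    names(p) <- target_ids
    p
  }
  cv <- run_cv(fp, y, meta, predictor = stub)
  for (f in fp$folds) {
    rows <- cv$plots[cv$plots$fold == f$label, ]
    expect_equal(rows$predicted, rep(mean(y[f$train]), nrow(rows)))
  }
})

test_that("MBLUP and PLSR receive identical partitions", {
  d <- simulate_dataset(tiny_config(seed = 33))
  pp <- preprocess_pipeline(d$spectra, max_shift = 0L)
  M <- build_similarity(pp$standardized)
  y <- setNames(d$phenotypes$WC, d$phenotypes$plot_id)
  fp <- make_folds("SIZE", d$meta, tp_size = 30, n_replicates = 2, seed = 3)
  cvb <- run_cv(fp, y, d$meta, "mblup", kernel = M)
  cvp <- run_cv(fp, y, d$meta, "plsr", Q = pp$standardized,
                n_components = 5)
  expect_identical(cvb$plots[, c("plot_id", "fold")],
                   cvp$plots[, c("plot_id", "fold")])
})

test_that("held-out lines cannot leak into their own predictions", {
  d <- simulate_dataset(tiny_config(seed = 35))
  pp <- preprocess_pipeline(d$spectra, max_shift = 0L)
  M <- build_similarity(pp$standardized)
  y <- setNames(d$phenotypes$FS, d$phenotypes$plot_id)
  fp <- make_folds("LINE", d$meta)
  target_line <- d$meta$line_id[1]
  target_plots <- d$meta$plot_id[d$meta$line_id == target_line]
  cv1 <- run_cv(fp, y, d$meta, "mblup", kernel = M)
  y2 <- y
  y2[target_plots] <- y2[target_plots] + 100
  cv2 <- run_cv(fp, y2, d$meta, "mblup", kernel = M)
  p1 <- cv1$plots[cv1$plots$line_id == target_line, ]
  p2 <- cv2$plots[cv2$plots$line_id == target_line, ]
  expect_equal(p1$predicted, p2$predicted[match(p1$plot_id, p2$plot_id)],
               tolerance = 1e-12)
})

test_that("missing trait values are excluded per trait, and failures degrade", {
  meta <- make_meta(10, 3)
  set.seed(2)
  y <- rnorm(30)
  names(y) <- meta$plot_id
  y[c(2, 17)] <- NA
  fp <- make_folds("LINE", meta)
  stub <- function(y_train, train_ids, target_ids) {
    expect_false(anyNA(y_train))
    p <- rep(mean(y_train), length(target_ids))
    names(p) <- target_ids
    p
  }
  expect_message(cv <- run_cv(fp, y, meta, predictor = stub), "missing")
  expect_equal(nrow(cv$plots), 28L)
  failing <- function(y_train, train_ids, target_ids) {
    if ("p004" %in% target_ids) stop("boom")
    p <- rep(0, length(target_ids)); names(p) <- target_ids; p
  }
  expect_warning(cvf <- run_cv(fp, y, meta, predictor = failing), "failed")
  expect_length(cvf$failed_folds, 1L)
})

test_that("plot-level accuracy is the Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(accuracy_plot(x, x), 1)
  expect_equal(accuracy_plot(x, -x), -1)
  expect_equal(accuracy_plot(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  expect_warning(a <- accuracy_plot(x, rep(1, 4)), "zero variance")
  expect_true(is.na(a))
})

test_that("line-mean accuracy averages within line first", {
  set.seed(3)
  obs <- rnorm(4)
  expect_equal(accuracy_line_mean(obs, obs * 2 + 1, letters[1:4]),
               accuracy_plot(obs, obs * 2 + 1))
  lines <- rep(c("a", "b", "c", "d", "e"), each = 3)
  lm_obs <- rep(c(1, 3, 2, 5, 4), each = 3) + rnorm(15, 0, 0.3)
  lm_pred <- rep(c(1, 3, 2, 5, 4), each = 3) + rnorm(15, 0, 0.3)
  om <- tapply(lm_obs, lines, mean)
  pm <- tapply(lm_pred, lines, mean)
  expect_equal(accuracy_line_mean(lm_obs, lm_pred, lines),
               cor(as.numeric(om), as.numeric(pm)), tolerance = 1e-12)
  expect_warning(a <- accuracy_line_mean(obs, obs, c("a", "a", "b", "b")),
                 "fewer than 3")
  expect_true(is.na(a))
})

test_that("noise-free line means correlate perfectly", {
  lines <- rep(c("a", "b", "c"), each = 4)
  means <- rep(c(1, 5, 3), each = 4)
  set.seed(4)
  # within-line noise with exactly zero line-mean perturbation
  noise_o <- unlist(lapply(1:3, function(i) { z <- rnorm(4); z - mean(z) }))
  noise_p <- unlist(lapply(1:3, function(i) { z <- rnorm(4); z - mean(z) }))
  expect_equal(accuracy_line_mean(means + noise_o, means + noise_p, lines), 1)
})

test_that("replicate summaries use the sample standard deviation", {
  s <- summarize_replicates(c(0.8, 0.8, 0.8))
  expect_equal(s$mean, 0.8)
  expect_equal(s$sd, 0)
  s2 <- summarize_replicates(c(0.7, 0.9))
  expect_equal(s2$mean, 0.8)
  expect_equal(s2$sd, sqrt(0.02), tolerance = 1e-12)
  set.seed(5)
  a <- runif(9)
  s3 <- summarize_replicates(a)
  expect_equal(s3$mean, sum(a) / 9, tolerance = 1e-15)
  expect_equal(s3$sd, sqrt(sum((a - mean(a))^2) / 8), tolerance = 1e-15)
  s1 <- summarize_replicates(0.5)
  expect_true(is.na(s1$sd))
})
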