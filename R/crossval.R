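#' Build a leave-set-out fold plan
#'
#' Three strategies: `"SIZE"` draws a random training population of a fixed
#' size (validation = the complement), repeated over replicates with
#' deterministically derived per-replicate seeds; `"LINE"` leaves out all
#' plots of one line per fold (one fold per line); `"LOC"` leaves out all
#' plots of one location per fold (one fold per location).
#'
#' @param strategy one of `"SIZE"`, `"LINE"`, `"LOC"`.
#' @param meta data frame with columns `plot_id`, `line_id`, `location`.
#' @param tp_size training-population size (SIZE only), `< nrow(meta)`.
#' @param n_replicates number of random replicates (SIZE only).
#' @param seed base seed; replicate `r` uses the derived seed
#'   `(seed + 7919 r) mod (2^31 - 1)` so any replicate is reproducible in
#'   isolation.
#' @return A `fold_plan`: list with `strategy`, `folds` (each a list
#'   `train`, `validation`, `replicate`, `label`), `seed`, `tp_size`.
#' @export
make_folds <- function(strategy = c("SIZE", "LINE", "LOC"), meta,
                       tp_size = NULL, n_replicates = 15L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(all(c("plot_id", "line_id", "location") %in% names(meta)))
  ids <- as.character(meta$plot_id)
  n <- length(ids)
  folds <- switch(strategy,
    SIZE = {
      if (is.null(tp_size)) stop("SIZE strategy requires tp_size")
      if (tp_size >= n) stop("tp_size must be smaller than the number of plots")
      lapply(seq_len(n_replicates), function(r) {
        set.seed((seed + 7919L * r) %% 2147483647L)
        tr <- sort(sample(ids, tp_size))
        list(train = tr, validation = setdiff(ids, tr), replicate = r,
             label = sprintf("rep%02d", r))
      })
    },
    LINE = {
      lines <- unique(as.character(meta$line_id))
      if (length(lines) < 2L) stop("LINE strategy requires at least 2 lines")
      lapply(lines, function(l) {
        v <- ids[meta$line_id == l]
        if (length(v) == 0L) stop("line with zero plots: ", l)
        list(train = setdiff(ids, v), validation = v, replicate = NA_integer_,
             label = l)
      })
    },
    LOC = {
      locs <- unique(as.character(meta$location))
      if (length(locs) < 2L) stop("LOC strategy requires at least 2 locations")
      lapply(locs, function(l) {
        v <- ids[meta$location == l]
        if (length(v) == 0L) stop("location with zero plots: ", l)
        list(train = setdiff(ids, v), validation = v, replicate = NA_integer_,
             label = l)
      })
    })
  structure(list(strategy = strategy, folds = folds, seed = seed,
                 tp_size = if (strategy == "SIZE") tp_size else NA_integer_),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %s, %d folds%s\n", x$strategy, length(x$folds),
              if (!is.na(x$tp_size)) sprintf(", tp_size %d", x$tp_size) else ""))
  invisible(x)
}

#' Plot-level prediction accuracy
#'
#' Pearson correlation between observed and predicted values.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return The correlation, or `NA` (with a warning) if either vector has
#'   zero variance.
#' @export
accuracy_plot <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3L) stop("need at least 3 pairs")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}

#' Line-mean prediction accuracy
#'
#' Averages observed and predicted values within line, then correlates the
#' line means.
#'
#' @param observed,predicted numeric vectors.
#' @param line_ids line identifier per element.
#' @return The correlation across line means, or `NA` with fewer than 3
#'   distinct lines.
#' @export
accuracy_line_mean <- function(observed, predicted, line_ids) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(line_ids))
  if (length(unique(line_ids)) < 3L) {
    warning("fewer than 3 lines; line-mean accuracy undefined")
    return(NA_real_)
  }
  om <- tapply(observed, line_ids, mean)
  pm <- tapply(predicted, line_ids, mean)
  accuracy_plot(as.numeric(om), as.numeric(pm[names(om)]))
}

#' Summarize accuracies across replicates
#'
#' @param accuracies numeric vector of per-replicate accuracies.
#' @return List with `mean`, `sd` (sample standard deviation, divisor
#'   n - 1; `NA` with a single replicate) and `n`.
#' @export
summarize_replicates <- function(accuracies) {
  accuracies <- accuracies[is.finite(accuracies)]
  if (length(accuracies) == 0L) stop("no finite accuracies to summarize")
  list(mean = mean(accuracies),
       sd = if (length(accuracies) >= 2L) stats::sd(accuracies) else NA_real_,
       n = length(accuracies))
}

#' Run a cross-validation over a fold plan
#'
#' Drives a predictor over every fold: the predictor is fit on the training
#' plots only (REML variance components and PLS centering computed on
#' training data only) and predicts the validation plots. No validation
#' information enters any fit. A failing fold is logged and skipped, not
#' fatal.
#'
#' @param folds a [make_folds()] plan.
#' @param y named numeric trait vector (names = plot ids); `NA` entries are
#'   excluded from both training and validation with a logged count.
#' @param meta plot metadata (`plot_id`, `line_id`, ...).
#' @param predictor `"mblup"`, `"plsr"`, or a function
#'   `function(y_train, train_ids, target_ids)` returning named predictions
#'   (for testing with stub predictors).
#' @param kernel [build_similarity()] kernel (required for `"mblup"`).
#' @param Q [standardized_matrix()] or matrix with rownames (required for
#'   `"plsr"`).
#' @param n_components PLS component count (fixed-count mode), default 20.
#' @param tune_components if `TRUE`, run [loo_tune()] inside each training
#'   set and use the selected count (slower); default `FALSE`.
#' @param component_grid grid for `tune_components`.
#' @param refit_per_fold if `TRUE` (default) REML is re-estimated within
#'   every fold's training set; if `FALSE`, variance components `vc` (or a
#'   one-off full-data fit) are reused across folds.
#' @param vc optional `mblup_vc` used when `refit_per_fold = FALSE`.
#' @return A `cv_result`: list with `plots` (per-plot data frame: plot_id,
#'   line_id, fold, replicate, observed, predicted), `fold_accuracy`,
#'   `pooled_plot`, `pooled_line` (LINE/LOC), `replicate_summary` (SIZE),
#'   `failed_folds`, and the settings used.
#' @export
run_cv <- function(folds, y, meta, predictor = "mblup", kernel = NULL,
                   Q = NULL, n_components = 20L, tune_components = FALSE,
                   component_grid = c(5, 10, 20, 50),
                   refit_per_fold = TRUE, vc = NULL) {
  stopifnot(inherits(folds, "fold_plan"))
  if (is.null(names(y))) stop("y must be named by plot_id")
  meta <- as.data.frame(meta)
  usable <- names(y)[is.finite(y)]
  n_missing <- sum(!is.finite(y))
  if (n_missing > 0L) {
    message(n_missing, " plot(s) with missing trait values excluded")
  }
  if (inherits(Q, "standardized_matrix")) Q <- Q$Q

  pred_fun <- predictor
  mode_label <- if (is.function(predictor)) "custom" else predictor
  if (identical(predictor, "mblup")) {
    if (is.null(kernel)) stop("mblup predictor requires a kernel")
    if (!refit_per_fold && is.null(vc)) {
      vc <- reml_fit(y[intersect(kernel$sample_ids, usable)],
                     subset_kernel(kernel,
                                   intersect(kernel$sample_ids, usable)))
    }
    pred_fun <- function(y_train, train_ids, target_ids) {
      vc_fold <- if (refit_per_fold) {
        reml_fit(y_train, subset_kernel(kernel, train_ids))
      } else vc
      blup_predict(vc_fold, y_train, kernel, train_ids, target_ids)
    }
  } else if (identical(predictor, "plsr")) {
    if (is.null(Q)) stop("plsr predictor requires Q")
    pred_fun <- function(y_train, train_ids, target_ids) {
      Qt <- Q[train_ids, , drop = FALSE]
      nc <- if (tune_components) {
        loo_tune(Qt, y_train, component_grid)$selected
      } else min(n_components, length(train_ids) - 2L, ncol(Qt))
      fit <- pls1_fit(Qt, y_train, nc)
      p <- pls1_predict(fit, Q[target_ids, , drop = FALSE])
      names(p) <- target_ids
      p
    }
  } else if (!is.function(pred_fun)) {
    stop("unknown predictor: ", predictor)
  }

  rows <- list()
  fold_acc <- list()
  failed <- character(0)
  for (k in seq_along(folds$folds)) {
    f <- folds$folds[[k]]
    stopifnot(length(intersect(f$train, f$validation)) == 0L)
    tr <- intersect(f$train, usable)
    va <- intersect(f$validation, usable)
    if (length(va) == 0L) next
    p <- tryCatch(pred_fun(y[tr], tr, va), error = function(e) {
      warning("fold ", f$label, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(p)) {
      failed <- c(failed, f$label)
      next
    }
    li <- meta$line_id[match(va, meta$plot_id)]
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = va, line_id = li, fold = f$label,
      replicate = f$replicate, observed = as.numeric(y[va]),
      predicted = as.numeric(p[va]), stringsAsFactors = FALSE)
    fold_acc[[length(fold_acc) + 1L]] <- data.frame(
      fold = f$label, replicate = f$replicate, n_validation = length(va),
      accuracy = if (length(va) >= 3L)
        suppressWarnings(accuracy_plot(y[va], p[va])) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("all folds failed")
  plots <- do.call(rbind, rows)
  fold_accuracy <- do.call(rbind, fold_acc)

  pooled_plot <- NA_real_; pooled_line <- NA_real_; rep_summary <- NULL
  if (folds$strategy == "SIZE") {
    rep_summary <- summarize_replicates(fold_accuracy$accuracy)
  } else {
    pooled_plot <- suppressWarnings(
      accuracy_plot(plots$observed, plots$predicted))
    pooled_line <- suppressWarnings(
      accuracy_line_mean(plots$observed, plots$predicted, plots$line_id))
  }
  structure(list(strategy = folds$strategy, predictor = mode_label,
                 refit_per_fold = refit_per_fold,
                 n_components = if (identical(mode_label, "plsr"))
                   n_components else NA_integer_,
                 tp_size = folds$tp_size, plots = plots,
                 fold_accuracy = fold_accuracy, pooled_plot = pooled_plot,
                 pooled_line = pooled_line, replicate_summary = rep_summary,
                 failed_folds = failed, n_missing_y = n_missing),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s / %s", x$strategy, x$predictor))
  if (!is.null(x$replicate_summary)) {
    cat(sprintf(" (tp_size %d): accuracy %.3f +/- %.3f over %d replicates\n",
                x$tp_size, x$replicate_summary$mean, x$replicate_summary$sd,
                x$replicate_summary$n))
  } else {
    cat(sprintf(": pooled plot accuracy %.3f, line-mean accuracy %.3f\n",
                x$pooled_plot, x$pooled_line))
  }
  if (length(x$failed_folds)) {
    cat("  failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  }
  invisible(x)
}
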