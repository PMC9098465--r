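# Tab-delimited UTF-8 tables, '.' decimal separator. Intensities and trait
# values are serialized with 17 significant digits (lossless for doubles);
# ppm headers with 4 decimal places (exact for axes whose spacing is a
# multiple of 1e-4 ppm, as the synthetic default is).

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

#' Write a spectra table
#'
#' First column `plot_id`; remaining column headers are the ppm values
#' (ascending, 4 decimal places).
#'
#' @param spectra a [spectra_matrix()].
#' @param path output file.
#' @export
write_spectra_table <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  header <- paste(c("plot_id", sprintf("%.4f", spectra$ppm)), collapse = "\t")
  rows <- vapply(seq_along(spectra$plot_ids), function(i) {
    paste(c(spectra$plot_ids[i], fmt_num(spectra$intensities[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a spectra table
#'
#' @param path file written by [write_spectra_table()] (or compatible:
#'   delimited text, first column `plot_id`, remaining headers numeric ppm).
#' @return A [spectra_matrix()]. Columns are re-sorted to ascending ppm with
#'   a warning if needed; duplicate plot ids and non-numeric cells are
#'   errors.
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "plot_id") {
    stop("expected first column 'plot_id' followed by ppm columns")
  }
  ppm <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(ppm)) {
    stop("non-numeric ppm headers: ",
         paste(names(df)[-1][is.na(ppm)], collapse = ", "))
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate plot_id: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "))
  }
  for (j in seq_along(ppm)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric intensity at row ", bad, ", column ", j + 1L)
    }
  }
  X <- as.matrix(df[, -1, drop = FALSE])
  if (is.unsorted(ppm, strictly = TRUE)) {
    warning("ppm columns not ascending; re-sorting")
    o <- order(ppm)
    ppm <- ppm[o]
    X <- X[, o, drop = FALSE]
  }
  spectra_matrix(ids, ppm, X)
}

#' Write the plot metadata + phenotype table
#'
#' Columns: plot_id, line_id, location, year, trial, then one column per
#' trait.
#'
#' @param meta data frame with plot_id, line_id, location, year, trial.
#' @param phenotypes data frame with plot_id and trait columns.
#' @param path output file.
#' @export
write_phenotype_table <- function(meta, phenotypes, path) {
  stopifnot(identical(meta$plot_id, phenotypes$plot_id))
  traits <- setdiff(names(phenotypes), "plot_id")
  out <- meta[, c("plot_id", "line_id", "location", "year", "trial")]
  for (tr in traits) out[[tr]] <- fmt_num(phenotypes[[tr]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the plot metadata + phenotype table
#'
#' @param path file with required columns plot_id, line_id, location, year
#'   (trial optional) and at least one trait column. Plots with a missing
#'   trait value are retained; downstream analyses exclude them per trait.
#' @param spectra_ids optional plot ids of the matching spectra table; any
#'   mismatch is an error listing the offenders.
#' @return List with `meta` (data frame) and `phenotypes` (data frame of
#'   plot_id + numeric trait columns).
#' @export
read_phenotype_table <- function(path, spectra_ids = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("plot_id", "line_id", "location", "year")
  if (!all(req %in% names(df))) {
    stop("missing required columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  if (!"trial" %in% names(df)) df$trial <- NA_character_
  df$plot_id <- as.character(df$plot_id)
  traits <- setdiff(names(df), c(req, "trial"))
  if (length(traits) == 0L) stop("no trait columns found")
  if (!is.null(spectra_ids)) {
    off <- c(setdiff(df$plot_id, spectra_ids), setdiff(spectra_ids, df$plot_id))
    if (length(off) > 0L) {
      stop("plot_ids do not match the spectra table: ",
           paste(utils::head(off, 10), collapse = ", "))
    }
  }
  phen <- data.frame(plot_id = df$plot_id, stringsAsFactors = FALSE)
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    n_miss <- sum(is.na(v))
    if (n_miss > 0L) {
      message("trait ", tr, ": ", n_miss, " missing value(s)")
    }
    phen[[tr]] <- v
  }
  list(meta = df[, c(req[1], "line_id", "location", "year", "trial")],
       phenotypes = phen)
}

#' Write a synthetic dataset's ground truth
#'
#' Per-plot dilution factor, applied shift, and per-trait metabolomic (m)
#' and residual (e) components.
#'
#' @param dataset a `synthetic_dataset`.
#' @param path output file.
#' @export
write_truth_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  out <- data.frame(plot_id = dataset$meta$plot_id,
                    dilution = fmt_num(dataset$truth$dilution),
                    shift = dataset$truth$shift,
                    stringsAsFactors = FALSE)
  for (tr in names(dataset$truth$traits)) {
    out[[paste0("m_", tr)]] <- fmt_num(dataset$truth$traits[[tr]]$m)
    out[[paste0("e_", tr)]] <- fmt_num(dataset$truth$traits[[tr]]$e)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a kernel matrix as a square delimited table
#'
#' @param kernel a [build_similarity()] result.
#' @param path output file.
#' @export
write_kernel_table <- function(kernel, path) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  header <- paste(c("sample_id", kernel$sample_ids), collapse = "\t")
  rows <- vapply(seq_along(kernel$sample_ids), function(i) {
    paste(c(kernel$sample_ids[i], fmt_num(kernel$M[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Write variance-component fit summaries
#'
#' One row per trait: sigma2_m, sigma2_e, mean_diag, rvc_m, rvc_se, mu_hat,
#' loglik, converged, at_bound.
#'
#' @param vc_list named list of `mblup_vc`, one per trait.
#' @param path output file.
#' @export
write_vc_table <- function(vc_list, path) {
  out <- do.call(rbind, lapply(names(vc_list), function(tr) {
    v <- vc_list[[tr]]
    data.frame(trait = tr, sigma2_m = v$sigma2_m, sigma2_e = v$sigma2_e,
               mean_diag = v$mean_diag, rvc_m = v$rvc_m, rvc_se = v$rvc_se,
               mu_hat = v$mu_hat, loglik = v$reml_loglik,
               converged = v$converged, at_bound = v$at_bound,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write cross-validation results
#'
#' Two tables: per-plot predictions and a one-row summary.
#'
#' @param cv a `cv_result`.
#' @param prefix path prefix; writes `<prefix>_predictions.tsv` and
#'   `<prefix>_summary.tsv`.
#' @param trait trait label recorded in the tables.
#' @export
write_cv_tables <- function(cv, prefix, trait = "trait") {
  pred_path <- paste0(prefix, "_predictions.tsv")
  sum_path <- paste0(prefix, "_summary.tsv")
  p <- cv$plots
  p$trait <- trait
  utils::write.table(p, pred_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  s <- data.frame(strategy = cv$strategy, trait = trait,
                  predictor = cv$predictor,
                  tp_size = cv$tp_size,
                  refit_per_fold = cv$refit_per_fold,
                  accuracy_plot = cv$pooled_plot,
                  accuracy_line_mean = cv$pooled_line,
                  mean = if (!is.null(cv$replicate_summary))
                    cv$replicate_summary$mean else NA_real_,
                  sd = if (!is.null(cv$replicate_summary))
                    cv$replicate_summary$sd else NA_real_,
                  n_failed = length(cv$failed_folds),
                  stringsAsFactors = FALSE)
  utils::write.table(s, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(pred_path, sum_path))
}

# known RunConfig keys, nested
run_config_schema <- function() {
  list(paths = c("spectra", "phenotypes", "output_dir"),
       preprocess = c("max_shift", "interval_width", "regions"),
       mblup = c("bounds", "tol", "refit_per_fold"),
       plsr = c("n_components", "component_grid", "tune_components"),
       cv = c("strategy", "tp_sizes", "replicates", "traits"),
       seed = NULL, log_level = NULL)
}

#' Read and validate a run configuration
#'
#' YAML configuration with sections `paths`, `preprocess`, `mblup`, `plsr`,
#' `cv` plus top-level `seed` and `log_level`. Unknown keys (top level or
#' nested) are rejected. Missing keys fall back to package defaults.
#'
#' @param path YAML file.
#' @return A named list (class `run_config`) with all defaults resolved.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read run configurations")
  }
  raw <- yaml::read_yaml(path)
  schema <- run_config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  for (sec in names(raw)) {
    if (is.list(raw[[sec]]) && !is.null(schema[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), schema[[sec]])
      if (length(bad) > 0L) {
        stop("unknown keys in '", sec, "': ", paste(bad, collapse = ", "))
      }
    }
  }
  cfg <- default_run_config()
  for (sec in names(raw)) {
    if (is.list(raw[[sec]])) {
      for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
    } else {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Default run configuration
#'
#' @return The fully resolved default `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    paths = list(spectra = "spectra.tsv", phenotypes = "phenotypes.tsv",
                 output_dir = "."),
    preprocess = list(max_shift = 3L, interval_width = 50L,
                      regions = "default"),
    mblup = list(bounds = c(1e-6, 1 - 1e-6), tol = 1e-8,
                 refit_per_fold = TRUE),
    plsr = list(n_components = 20L, component_grid = c(5, 10, 20, 50),
                tune_components = FALSE),
    cv = list(strategy = "SIZE", tp_sizes = c(50, 100, 200, 400),
              replicates = 15L, traits = c("FS", "EY", "WC", "BG", "WV")),
    seed = 1L, log_level = "info"), class = "run_config")
}

#' Write a resolved run configuration next to its outputs
#'
#' @param cfg a `run_config`.
#' @param path output YAML file.
#' @export
write_run_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write run configurations")
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
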