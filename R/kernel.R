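#' Build the metabolomic similarity matrix
#'
#' Computes `M = Q Q' / m` from the standardized feature matrix, the same
#' construction as a VanRaden-type genomic relationship matrix but on binned
#' NMR features. With divisor-n standardization the mean diagonal of `M` is
#' exactly 1. An optional feature mask restricts the kernel to a subset of
#' bins (the divisor becomes the masked feature count), supporting
#' heritability-screened subset kernels generically.
#'
#' @param Q a [standardized_matrix()].
#' @param feature_mask optional logical or integer subset of the columns of
#'   `Q` (at least 2 columns).
#' @param label text label describing the mask, stored on the result.
#' @return A `kernel_matrix`: list with `sample_ids`, symmetric `M`,
#'   `m_features` and `feature_mask_label`.
#' @examples
#' sp <- spectra_matrix(letters[1:4], 1:6, matrix(rnorm(24), 4))
#' M <- build_similarity(standardize_features(sp))
#' mean(diag(M$M))
#' @export
build_similarity <- function(Q, feature_mask = NULL, label = "all") {
  stopifnot(inherits(Q, "standardized_matrix"))
  Qm <- Q$Q
  if (!is.null(feature_mask)) {
    Qm <- Qm[, feature_mask, drop = FALSE]
    if (ncol(Qm) < 2L) stop("feature_mask must select at least 2 features")
  }
  m <- ncol(Qm)
  M <- tcrossprod(Qm) / m
  M <- (M + t(M)) / 2
  structure(list(sample_ids = Q$plot_ids, M = M, m_features = m,
                 feature_mask_label = label),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d samples, %d features (%s), mean diag %.6f\n",
              nrow(x$M), x$m_features, x$feature_mask_label,
              mean(diag(x$M))))
  invisible(x)
}

#' Restrict a kernel to a subset of samples
#'
#' Extracts the sub-kernel for the given sample ids, in the given order
#' (used per cross-validation fold).
#'
#' @param kernel a `kernel_matrix`.
#' @param ids subset of `kernel$sample_ids`.
#' @return A `kernel_matrix` over `ids`.
#' @export
subset_kernel <- function(kernel, ids) {
  idx <- match(ids, kernel$sample_ids)
  if (anyNA(idx)) stop("unknown sample ids in kernel subset")
  structure(list(sample_ids = kernel$sample_ids[idx],
                 M = kernel$M[idx, idx, drop = FALSE],
                 m_features = kernel$m_features,
                 feature_mask_label = kernel$feature_mask_label),
            class = "kernel_matrix")
}
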