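#' Construct a spectra matrix
#'
#' The basic container for binned 1D 1H-NMR data: one row per plot (sample),
#' one column per chemical-shift bin, with an explicit ppm axis.
#'
#' @param plot_ids character vector of unique sample identifiers (length n).
#' @param ppm numeric vector of bin centers in ppm, strictly increasing
#'   (length p).
#' @param intensities numeric n x p matrix of binned intensities.
#' @return An object of class `spectra_matrix`: a list with elements
#'   `plot_ids`, `ppm` and `intensities` (row names set to `plot_ids`).
#' @examples
#' sp <- spectra_matrix(c("a", "b"), c(1, 2, 3), rbind(1:3, 4:6))
#' dim(sp$intensities)
#' @export
spectra_matrix <- function(plot_ids, ppm, intensities) {
  plot_ids <- as.character(plot_ids)
  ppm <- as.numeric(ppm)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (anyDuplicated(plot_ids)) {
    stop("duplicate plot_ids: ",
         paste(unique(plot_ids[duplicated(plot_ids)]), collapse = ", "))
  }
  if (length(ppm) != ncol(intensities)) {
    stop("length(ppm) must equal ncol(intensities)")
  }
  if (length(plot_ids) != nrow(intensities)) {
    stop("length(plot_ids) must equal nrow(intensities)")
  }
  if (length(ppm) > 1L && any(diff(ppm) <= 0)) {
    stop("ppm axis must be strictly increasing")
  }
  if (!all(is.finite(intensities))) {
    stop("intensities must be finite")
  }
  rownames(intensities) <- plot_ids
  colnames(intensities) <- NULL
  structure(list(plot_ids = plot_ids, ppm = ppm, intensities = intensities),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("spectra_matrix: %d plots x %d bins, ppm %.4f..%.4f\n",
              length(x$plot_ids), length(x$ppm),
              min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$intensities)

# internal: new spectra with same ids/ppm but different intensities
replace_intensities <- function(spectra, intensities) {
  spectra$intensities <- intensities
  rownames(spectra$intensities) <- spectra$plot_ids
  spectra
}

#' Construct a standardized feature matrix
#'
#' Holds the matrix Q of centered and scaled metabolomic features, together
#' with the per-feature statistics used, so the transformation is invertible
#' and auditable.
#'
#' @param plot_ids sample identifiers (length n).
#' @param ppm ppm values of the retained bins (length m).
#' @param Q n x m matrix, each column mean 0 and population (divisor n)
#'   standard deviation 1.
#' @param feature_means,feature_sds length-m statistics removed per feature.
#' @param dropped_ppm ppm values of bins dropped for zero variance.
#' @return An object of class `standardized_matrix`.
#' @export
standardized_matrix <- function(plot_ids, ppm, Q, feature_means, feature_sds,
                                dropped_ppm = numeric(0)) {
  Q <- as.matrix(Q)
  storage.mode(Q) <- "double"
  stopifnot(length(ppm) == ncol(Q), length(plot_ids) == nrow(Q),
            length(feature_means) == ncol(Q), length(feature_sds) == ncol(Q))
  rownames(Q) <- as.character(plot_ids)
  structure(list(plot_ids = as.character(plot_ids), ppm = as.numeric(ppm),
                 Q = Q, feature_means = as.numeric(feature_means),
                 feature_sds = as.numeric(feature_sds),
                 dropped_ppm = as.numeric(dropped_ppm)),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("standardized_matrix: %d plots x %d features (%d zero-variance bins dropped)\n",
              nrow(x$Q), ncol(x$Q), length(x$dropped_ppm)))
  invisible(x)
}
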