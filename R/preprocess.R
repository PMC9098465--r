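#' Default spectral exclusion regions
#'
#' Signal-free ends of the axis (below 0.70 and above 9.00 ppm), the residual
#' water peak (4.7--4.9 ppm) and the chemical-shift reference standard
#' (-0.2--0.2 ppm).
#'
#' @return A list of closed ppm intervals `c(low, high)`.
#' @export
default_exclusion_regions <- function() {
  list(c(-Inf, 0.70), c(4.7, 4.9), c(-0.2, 0.2), c(9.00, Inf))
}

#' Drop bins inside exclusion regions
#'
#' Removes all bins whose ppm value falls inside any of the given closed
#' intervals, preserving the order of the remaining bins.
#'
#' @param spectra a [spectra_matrix()].
#' @param regions list of `c(low, high)` ppm intervals (closed). Defaults to
#'   [default_exclusion_regions()].
#' @return A [spectra_matrix()] with the retained bins.
#' @export
exclude_regions <- function(spectra, regions = default_exclusion_regions()) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  drop <- rep(FALSE, length(spectra$ppm))
  for (r in regions) {
    if (length(r) != 2L || r[2] < r[1]) stop("invalid region: ",
                                             paste(r, collapse = ", "))
    drop <- drop | (spectra$ppm >= r[1] & spectra$ppm <= r[2])
  }
  if (all(drop)) stop("all bins fall inside exclusion regions")
  keep <- which(!drop)
  spectra_matrix(spectra$plot_ids, spectra$ppm[keep],
                 spectra$intensities[, keep, drop = FALSE])
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution: each sample's quotient is the median over
#' bins of sample/reference intensity (bins where the reference is zero are
#' excluded), and the sample is divided by its quotient.
#'
#' @param spectra a [spectra_matrix()]; run [exclude_regions()] first so
#'   solvent/reference regions cannot distort the quotients.
#' @param reference numeric reference spectrum of length `ncol`; default is
#'   the element-wise median spectrum across samples.
#' @return A list with `spectra` (normalized [spectra_matrix()]), `quotients`
#'   (named per-sample) and `reference`.
#' @export
pqn_normalize <- function(spectra, reference = NULL) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  X <- spectra$intensities
  if (is.null(reference)) {
    reference <- apply(X, 2, stats::median)
  }
  stopifnot(length(reference) == ncol(X))
  usable <- reference != 0
  if (!any(usable)) stop("reference spectrum is identically zero")
  q <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    if (all(X[i, ] == 0)) {
      stop("sample has all-zero intensities: ", spectra$plot_ids[i])
    }
    q[i] <- stats::median(X[i, usable] / reference[usable])
    if (!is.finite(q[i]) || q[i] == 0) {
      stop("degenerate quotient for sample ", spectra$plot_ids[i])
    }
  }
  names(q) <- spectra$plot_ids
  list(spectra = replace_intensities(spectra, X / q),
       quotients = q, reference = reference)
}

#' Build contiguous alignment intervals
#'
#' Splits the bin axis into consecutive intervals of roughly `width` bins; a
#' final remainder shorter than `2 * max_shift + 1` is merged into the
#' previous interval.
#'
#' @param n_bins number of bins.
#' @param width target interval width in bins.
#' @param max_shift the shift budget the intervals must accommodate.
#' @return List of integer vectors `c(start, end)` (1-based, inclusive).
#' @export
make_alignment_intervals <- function(n_bins, width = 50L, max_shift = 3L) {
  width <- max(as.integer(width), 2L * max_shift + 1L)
  starts <- seq.int(1L, n_bins, by = width)
  iv <- lapply(starts, function(s) c(s, min(s + width - 1L, n_bins)))
  last <- iv[[length(iv)]]
  if (length(iv) > 1L && (last[2] - last[1] + 1L) < 2L * max_shift + 1L) {
    iv[[length(iv) - 1L]][2] <- last[2]
    iv[[length(iv)]] <- NULL
  }
  iv
}

#' Interval correlation alignment
#'
#' A simplified interval-wise spectral alignment: within each interval, every
#' sample segment is shifted by the integer number of bins (within
#' `max_shift`) that maximizes its cross-correlation with the reference
#' (median spectrum) segment, where the correlation is computed on the
#' overlapping (non-padded) part of the two segments so edge padding cannot
#' inflate the score. Vacated edge positions are filled with the segment's
#' boundary value. Ties are broken toward the smallest absolute shift, then
#' toward the negative shift. Unlike full icoshift there is no variable
#' segment optimization or interpolation.
#'
#' @param spectra a [spectra_matrix()].
#' @param intervals list of `c(start, end)` bin-index ranges; default chunks
#'   the axis via [make_alignment_intervals()].
#' @param max_shift maximum shift in bins; 0 returns the input unchanged.
#' @param reference optional reference spectrum (default median spectrum).
#' @return The aligned [spectra_matrix()] with an attribute `"shifts"`
#'   (samples x intervals matrix of applied corrections, in bins).
#' @export
align_segments <- function(spectra, intervals = NULL, max_shift = 3L,
                           reference = NULL) {
  stopifnot(inherits(spectra, "spectra_matrix"), max_shift >= 0)
  X <- spectra$intensities
  if (is.null(intervals)) {
    intervals <- make_alignment_intervals(ncol(X), max_shift = max_shift)
  }
  for (iv in intervals) {
    if ((iv[2] - iv[1] + 1L) < 2L * max_shift + 1L) {
      stop("interval [", iv[1], ", ", iv[2], "] shorter than 2*max_shift+1")
    }
  }
  applied <- matrix(0L, nrow(X), length(intervals),
                    dimnames = list(spectra$plot_ids, NULL))
  if (max_shift == 0L) {
    out <- replace_intensities(spectra, X)
    attr(out, "shifts") <- applied
    return(out)
  }
  if (is.null(reference)) reference <- apply(X, 2, stats::median)
  # candidate order encodes the tie-break: smallest |s| first, negative first
  cand <- order(abs(seq.int(-max_shift, max_shift)),
                seq.int(-max_shift, max_shift))
  cand <- seq.int(-max_shift, max_shift)[cand]
  for (j in seq_along(intervals)) {
    iv <- intervals[[j]]
    idx <- iv[1]:iv[2]
    ref_seg <- reference[idx]
    L <- length(idx)
    for (i in seq_len(nrow(X))) {
      seg <- X[i, idx]
      best <- -Inf; best_s <- 0L
      for (s in cand) {
        # overlap of the segment shifted by s with the reference
        if (s >= 0L) {
          xs <- seg[seq_len(L - s)]; rs <- ref_seg[seq.int(1L + s, L)]
        } else {
          xs <- seg[seq.int(1L - s, L)]; rs <- ref_seg[seq_len(L + s)]
        }
        sc <- suppressWarnings(stats::cor(xs, rs))
        if (is.finite(sc) && sc > best) { best <- sc; best_s <- s }
      }
      if (best_s != 0L) X[i, idx] <- shift_vector(seg, best_s)
      applied[i, j] <- best_s
    }
  }
  out <- replace_intensities(spectra, X)
  attr(out, "shifts") <- applied
  out
}

#' Center and scale features
#'
#' Standardizes every retained bin to mean 0 and standard deviation 1 using
#' the population convention (divisor n). Under this convention the mean
#' diagonal of the similarity matrix `QQ'/m` is exactly 1. Zero-variance bins
#' are dropped with a warning and recorded.
#'
#' @param spectra a [spectra_matrix()] with `n >= 2` samples.
#' @return A [standardized_matrix()].
#' @export
standardize_features <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  X <- spectra$intensities
  n <- nrow(X)
  if (n < 2L) stop("standardization needs at least 2 samples")
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  scale0 <- pmax(abs(mu), 1)
  zero_var <- sd_pop <= 1e-13 * scale0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance bin(s) dropped")
  }
  keep <- which(!zero_var)
  if (length(keep) == 0L) stop("all bins have zero variance")
  Q <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd_pop[keep], "/")
  standardized_matrix(spectra$plot_ids, spectra$ppm[keep], Q,
                      mu[keep], sd_pop[keep],
                      dropped_ppm = spectra$ppm[zero_var])
}

#' Full preprocessing pipeline
#'
#' Runs the canonical stage order exclude -> PQN -> align -> standardize and
#' collects a report. Plot order is preserved throughout.
#'
#' @param spectra raw [spectra_matrix()].
#' @param regions exclusion regions for [exclude_regions()].
#' @param max_shift alignment budget in bins; 0 disables alignment.
#' @param interval_width alignment interval width in bins.
#' @return List with `standardized` (a [standardized_matrix()]), `spectra`
#'   (the processed but unstandardized [spectra_matrix()]), `quotients`, and
#'   `shifts`.
#' @export
preprocess_pipeline <- function(spectra, regions = default_exclusion_regions(),
                                max_shift = 3L, interval_width = 50L) {
  sp <- exclude_regions(spectra, regions)
  pq <- pqn_normalize(sp)
  sp <- pq$spectra
  shifts <- NULL
  if (max_shift > 0L) {
    sp <- align_segments(sp,
                         make_alignment_intervals(length(sp$ppm),
                                                  width = interval_width,
                                                  max_shift = max_shift),
                         max_shift = max_shift)
    shifts <- attr(sp, "shifts")
  }
  list(standardized = standardize_features(sp), spectra = sp,
       quotients = pq$quotients, shifts = shifts)
}
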