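#' Random Lorentzian peak library
#'
#' Draws a set of metabolite line shapes for the synthetic generator. Each
#' metabolite gets 1--`max_peaks` Lorentzian peaks (width = half-width at
#' half-maximum) with random centers and relative amplitudes. Drawn from the
#' current RNG state; `simulate_dataset()` seeds before calling.
#'
#' @param n_metabolites number of metabolites.
#' @param ppm_range numeric length-2, low/high of the simulated axis.
#' @param max_peaks maximum peaks per metabolite.
#' @param width_range half-width-at-half-maximum range in ppm.
#' @return A `peak_library`: list of per-metabolite data frames with columns
#'   `center`, `width`, `amplitude`.
#' @export
peak_library <- function(n_metabolites, ppm_range = c(0, 11), max_peaks = 3L,
                         width_range = c(0.005, 0.03)) {
  stopifnot(n_metabolites >= 1, ppm_range[2] > ppm_range[1],
            width_range[1] > 0)
  pad <- 0.05 * diff(ppm_range)
  lib <- lapply(seq_len(n_metabolites), function(k) {
    np <- sample.int(max_peaks, 1L)
    data.frame(
      center = stats::runif(np, ppm_range[1] + pad, ppm_range[2] - pad),
      width = stats::runif(np, width_range[1], width_range[2]),
      amplitude = stats::runif(np, 0.2, 1))
  })
  structure(lib, class = "peak_library", ppm_range = ppm_range)
}

# internal: evaluate one metabolite's summed Lorentzian profile on the axis
peak_profile <- function(peaks, ppm) {
  out <- numeric(length(ppm))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks$amplitude[i] /
      (1 + ((ppm - peaks$center[i]) / peaks$width[i])^2)
  }
  out
}

#' Simulation configuration
#'
#' Defines the field design and spectral model of the synthetic generator.
#' Defaults give a desk-scale analogue of a multi-year, two-location barley
#' malting trial: 100 lines, each grown in one of three years at both
#' locations with three replicate plots (600 plots), spectra of 2000 bins on
#' 0--11 ppm summed from 80 metabolites (wort spectra are signal-dense once
#' signal-free regions are excluded), and five wort-quality traits (FS,
#' EY, WC, BG, WV) that are linear in the true metabolite concentrations
#' with a metabolomic variance fraction of `target_rvc`.
#'
#' @param n_lines number of breeding lines.
#' @param locations,years character labels of locations and years; lines are
#'   split evenly over years and every line is grown at every location of its
#'   year.
#' @param replicates_per_line replicate plots per line per location.
#' @param n_bins,ppm_range spectral axis definition.
#' @param n_metabolites number of simulated metabolites.
#' @param traits character vector of trait names.
#' @param target_rvc metabolomic variance fraction per trait, strictly in
#'   (0, 1); recycled to `length(traits)`.
#' @param trait_means,trait_sds phenotype intercept and total standard
#'   deviation per trait; recycled.
#' @param sd_line,sd_location,sd_year,sd_plot standard deviations of the
#'   line, location, year and plot-level components of each metabolite
#'   concentration (concentration units).
#' @param dilution_sd standard deviation of log dilution factors (log-normal
#'   with median 1).
#' @param max_true_shift largest whole-spectrum misalignment, in bins.
#' @param noise_sd additive per-bin intensity noise standard deviation.
#' @param trial_lines lines per field trial (trials chunk lines within each
#'   location x year; no trial effect enters phenotypes by default).
#' @param trial_effect_sd optional trial effect on concentrations, default 0.
#' @param seed integer RNG seed; all randomness in `simulate_dataset()` flows
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 100L,
                       locations = c("L1", "L2"),
                       years = c("Y1", "Y2", "Y3"),
                       replicates_per_line = 3L,
                       n_bins = 2000L,
                       ppm_range = c(0, 11),
                       n_metabolites = 80L,
                       traits = c("FS", "EY", "WC", "BG", "WV"),
                       target_rvc = 0.95,
                       trait_means = c(FS = 4.83, EY = 82.66, WC = 5.83,
                                       BG = 217.10, WV = 1.47),
                       trait_sds = c(FS = 0.61, EY = 1.82, WC = 0.83,
                                     BG = 115.23, WV = 0.06),
                       sd_line = 1, sd_location = 0.3, sd_year = 0.3,
                       sd_plot = 0.3,
                       dilution_sd = 0.15,
                       max_true_shift = 2L,
                       noise_sd = 0.02,
                       trial_lines = 30L,
                       trial_effect_sd = 0,
                       seed = 1L) {
  target_rvc <- rep_len(as.numeric(target_rvc), length(traits))
  names(target_rvc) <- traits
  if (any(target_rvc <= 0 | target_rvc >= 1)) {
    stop("target_rvc must be strictly inside (0, 1)")
  }
  trait_means <- rep_len(as.numeric(trait_means), length(traits))
  trait_sds <- rep_len(as.numeric(trait_sds), length(traits))
  names(trait_means) <- names(trait_sds) <- traits
  cfg <- list(n_lines = as.integer(n_lines), locations = locations,
              years = years,
              replicates_per_line = as.integer(replicates_per_line),
              n_bins = as.integer(n_bins), ppm_range = as.numeric(ppm_range),
              n_metabolites = as.integer(n_metabolites), traits = traits,
              target_rvc = target_rvc, trait_means = trait_means,
              trait_sds = trait_sds, sd_line = sd_line,
              sd_location = sd_location, sd_year = sd_year,
              sd_plot = sd_plot, dilution_sd = dilution_sd,
              max_true_shift = as.integer(max_true_shift),
              noise_sd = noise_sd, trial_lines = as.integer(trial_lines),
              trial_effect_sd = trial_effect_sd, seed = as.integer(seed))
  stopifnot(cfg$n_lines >= 1, cfg$replicates_per_line >= 1, cfg$n_bins >= 2,
            cfg$n_metabolites >= 1, cfg$max_true_shift >= 0,
            cfg$dilution_sd >= 0, cfg$noise_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# internal: shift a vector by s bins (s > 0 moves content right), padding
# with the boundary value
shift_vector <- function(x, s) {
  L <- length(x)
  s <- as.integer(s)
  if (s == 0L || abs(s) >= L) return(if (s == 0L) x else rep(x[1L], L))
  if (s > 0L) c(rep(x[1L], s), x[seq_len(L - s)])
  else c(x[seq.int(1L - s, L)], rep(x[L], -s))
}

#' Simulate a plot-structured metabolomic dataset
#'
#' Generates spectra, plot metadata and phenotypes with full ground truth.
#' Per-plot metabolite concentrations are line value + location effect +
#' year effect + plot noise; the clean spectrum is the concentration-weighted
#' sum of Lorentzian peak profiles; the observed spectrum is
#' dilution x shifted clean spectrum + per-bin noise. Each phenotype is
#' `intercept + sum_k beta_k c_ik + e_i`, with the coefficient vector scaled
#' so that the metabolomic share of the phenotypic variance equals the
#' configured `target_rvc` (residual variance solved analytically from the
#' realized variance of the metabolomic term).
#'
#' @param config a [sim_config()].
#' @return A `synthetic_dataset`: list with `spectra` (a
#'   [spectra_matrix()]), `meta` (data frame: plot_id, line_id, location,
#'   year, trial), `phenotypes` (data frame: plot_id + one column per trait)
#'   and `truth` (list: peak library, concentrations, per-trait `beta`,
#'   `intercept`, `m`, `e`, plus `dilution` and `shift` per plot).
#' @examples
#' cfg <- sim_config(n_lines = 6, n_bins = 200, n_metabolites = 5, seed = 2)
#' d <- simulate_dataset(cfg)
#' nrow(d$meta)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_bins < 10L * config$n_metabolites) {
    stop("n_bins too small to place all metabolite peaks; need >= ",
         10L * config$n_metabolites)
  }
  set.seed(config$seed)
  lo <- config$ppm_range[1]; hi <- config$ppm_range[2]
  ppm <- lo + seq_len(config$n_bins) * (hi - lo) / config$n_bins

  lib <- peak_library(config$n_metabolites, config$ppm_range)
  profiles <- t(vapply(lib, peak_profile, numeric(config$n_bins), ppm = ppm))

  # field layout: lines chunked over years; every line at every location
  line_ids <- sprintf("LINE%03d", seq_len(config$n_lines))
  line_year <- config$years[1L + (seq_len(config$n_lines) - 1L) %%
                              length(config$years)]
  meta <- do.call(rbind, lapply(seq_len(config$n_lines), function(i) {
    expand.grid(line_id = line_ids[i], location = config$locations,
                year = line_year[i], rep = seq_len(config$replicates_per_line),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  meta$plot_id <- sprintf("PLOT%04d", seq_len(nrow(meta)))
  # trials: chunk lines within each location x year
  line_chunk <- 1L + (match(meta$line_id, line_ids) - 1L) %/% config$trial_lines
  meta$trial <- sprintf("%s_%s_T%d", meta$year, meta$location, line_chunk)
  meta <- meta[, c("plot_id", "line_id", "location", "year", "trial")]
  n <- nrow(meta)
  K <- config$n_metabolites

  # concentrations: base + line + location + year (+ trial) + plot deviations
  base <- stats::runif(K, 1, 3)
  dev_line <- matrix(stats::rnorm(config$n_lines * K, 0, config$sd_line),
                     config$n_lines, K, dimnames = list(line_ids, NULL))
  dev_loc <- matrix(stats::rnorm(length(config$locations) * K, 0,
                                 config$sd_location),
                    length(config$locations), K,
                    dimnames = list(config$locations, NULL))
  dev_year <- matrix(stats::rnorm(length(config$years) * K, 0, config$sd_year),
                     length(config$years), K,
                     dimnames = list(config$years, NULL))
  trials <- unique(meta$trial)
  dev_trial <- matrix(stats::rnorm(length(trials) * K, 0,
                                   config$trial_effect_sd),
                      length(trials), K, dimnames = list(trials, NULL))
  conc <- matrix(base, n, K, byrow = TRUE) +
    dev_line[meta$line_id, , drop = FALSE] +
    dev_loc[meta$location, , drop = FALSE] +
    dev_year[meta$year, , drop = FALSE] +
    dev_trial[meta$trial, , drop = FALSE] +
    matrix(stats::rnorm(n * K, 0, config$sd_plot), n, K)
  rownames(conc) <- meta$plot_id

  clean <- conc %*% profiles
  shifts <- sample.int(2L * config$max_true_shift + 1L, n, replace = TRUE) -
    config$max_true_shift - 1L
  dilution <- exp(stats::rnorm(n, 0, config$dilution_sd))
  observed <- clean
  for (i in seq_len(n)) {
    observed[i, ] <- dilution[i] * shift_vector(clean[i, ], shifts[i])
  }
  if (config$noise_sd > 0) {
    observed <- observed +
      matrix(stats::rnorm(n * config$n_bins, 0, config$noise_sd),
             n, config$n_bins)
  }
  spectra <- spectra_matrix(meta$plot_id, ppm, observed)

  # phenotypes: y = intercept + C beta + e, beta scaled to hit target_rvc
  phen <- data.frame(plot_id = meta$plot_id, stringsAsFactors = FALSE)
  truth_traits <- list()
  for (tr in config$traits) {
    rvc <- config$target_rvc[[tr]]
    beta_raw <- stats::rnorm(K)
    g <- unname(drop(conc %*% beta_raw))
    m <- g - mean(g)
    sd_m <- stats::sd(m)
    if (sd_m > 0) {
      f <- config$trait_sds[[tr]] * sqrt(rvc) / sd_m
    } else {
      f <- 0
    }
    beta <- f * beta_raw
    m <- f * m
    var_e <- if (sd_m > 0) stats::var(m) * (1 - rvc) / rvc else
      config$trait_sds[[tr]]^2
    e <- stats::rnorm(n, 0, sqrt(var_e))
    intercept <- config$trait_means[[tr]]
    phen[[tr]] <- intercept + m + e
    truth_traits[[tr]] <- list(beta = beta, intercept = intercept,
                               m = m, e = e)
  }

  structure(list(spectra = spectra, meta = meta, phenotypes = phen,
                 truth = list(peaks = lib, profiles = profiles,
                              concentrations = conc, dilution = dilution,
                              shift = shifts, traits = truth_traits),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d plots (%d lines, %d locations, %d years), %d bins, traits: %s\n",
    nrow(x$meta), length(unique(x$meta$line_id)),
    length(unique(x$meta$location)), length(unique(x$meta$year)),
    length(x$spectra$ppm), paste(x$config$traits, collapse = ", ")))
  invisible(x)
}

#' Summarize the ground truth of a synthetic dataset
#'
#' Recomputes, from the stored truth components, the realized metabolomic
#' variance fraction per trait, per-line means of the metabolomic term, and
#' plot counts by location and year.
#'
#' @param dataset a `synthetic_dataset` with its `truth` element intact.
#' @return A list with `rvc` (named per trait: var(m) / (var(m) + var(e)),
#'   sample variances), `line_means_m` (line x trait matrix), and `counts`
#'   (location x year plot counts).
#' @export
truth_summary <- function(dataset) {
  if (!inherits(dataset, "synthetic_dataset") || is.null(dataset$truth)) {
    stop("dataset has no stored truth")
  }
  tr <- dataset$truth$traits
  rvc <- vapply(tr, function(t) {
    vm <- stats::var(t$m); ve <- stats::var(t$e)
    if (vm + ve == 0) return(NA_real_)
    vm / (vm + ve)
  }, numeric(1))
  mmat <- vapply(tr, `[[`, numeric(nrow(dataset$meta)), "m")
  line_means_m <- apply(mmat, 2, function(v)
    tapply(v, dataset$meta$line_id, mean))
  counts <- table(dataset$meta$location, dataset$meta$year)
  list(rvc = rvc, line_means_m = line_means_m, counts = counts)
}
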