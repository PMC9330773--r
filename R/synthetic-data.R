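#' Configuration for a synthetic DDA run
#'
#' Describes the simulated acquisition: Gaussian chromatographic peaks on a
#' fixed MS1 scan grid, DDA-style top-k MS2 triggering with a dynamic
#' exclusion window, multiplicative intensity noise between samples, m/z
#' jitter in ppm, a flat baseline of random noise centroids, and a
#' chimerism rate — the probability that a co-eluting contaminant's
#' fragments are merged into an MS2 scan, emulating co-isolation.
#'
#' @param n_samples Number of samples (default 3).
#' @param n_compounds Number of planted compounds (default 20).
#' @param run_length_min Run length in minutes (default 20).
#' @param ms1_interval_s MS1 scan interval in seconds (default 1).
#' @param dda_top_k MS2 events per MS1 cycle (default 4).
#' @param dynamic_exclusion_s Re-trigger exclusion per precursor (default 15).
#' @param peak_sigma_min Chromatographic peak sigma in minutes (default 0.05).
#' @param height_range Peak height range (uniform draw; default 1e5-1e6).
#' @param baseline_peaks Random noise centroids per MS1 scan (default 20).
#' @param baseline_height Mean noise centroid intensity (default 5e3).
#' @param mz_jitter_ppm Centroid m/z jitter sd in ppm (default 3).
#' @param intensity_cv Multiplicative intensity CV across samples/scans
#'   (default 0.1).
#' @param chimerism_rate Probability an MS2 scan of a co-eluting pair is
#'   chimeric (default 0).
#' @param min_mz_separation_ppm Minimum precursor separation between planted
#'   compounds (default 50 ppm), emulating a spike-in panel of distinct
#'   standards.
#' @param ms2_trigger_height Minimum MS1 intensity to trigger MS2
#'   (default 1e4).
#' @return A `run_config` list.
#' @export
run_config <- function(n_samples = 3L, n_compounds = 20L, run_length_min = 20,
                       ms1_interval_s = 1, dda_top_k = 4L,
                       dynamic_exclusion_s = 15, peak_sigma_min = 0.05,
                       height_range = c(1e5, 1e6), baseline_peaks = 20L,
                       baseline_height = 5e3, mz_jitter_ppm = 3,
                       intensity_cv = 0.1, chimerism_rate = 0,
                       min_mz_separation_ppm = 50, ms2_trigger_height = 1e4) {
  stopifnot(n_samples >= 1L, n_compounds >= 1L, run_length_min > 0,
            ms1_interval_s > 0, dda_top_k >= 1L, peak_sigma_min > 0,
            chimerism_rate >= 0, chimerism_rate <= 1,
            intensity_cv >= 0, mz_jitter_ppm >= 0)
  structure(as.list(environment()), class = "run_config")
}

#' Generate a synthetic multi-sample DDA run with known ground truth
#'
#' Plants `n_compounds` compounds drawn from a spectral library into
#' `n_samples` samples: each compound gets a true retention time (uniform
#' over the usable run), a Gaussian elution profile, and per-sample heights.
#' MS1 scans on the fixed grid carry one precursor centroid per eluting
#' compound (with ppm jitter and intensity noise) plus uniform baseline
#' noise centroids. MS2 scans are fired DDA-style: per MS1 cycle the top-k
#' eligible precursors above the trigger height, subject to dynamic
#' exclusion; each MS2 spectrum is the compound's library fragment spectrum,
#' jittered, and — with probability `chimerism_rate` when another compound
#' co-elutes within the isolation-relevant RT window — merged with the
#' co-eluting compound's fragments (a chimeric spectrum).
#'
#' All randomness flows from `seed`; the same seed gives identical output.
#'
#' @param config A [run_config()].
#' @param library A [spectral_library()] with at least `n_compounds`
#'   searchable entries.
#' @param seed Integer seed.
#' @return List with `scans_by_sample` (named list of [ms_scan()] lists),
#'   `ground_truth` (data.frame: `compound`, `precursor_mz`, `rt_true`,
#'   `height`, per-sample planted heights collapsed to the mean, `n_ms2` MS2
#'   scans fired), and `compounds` (the planted [library_entry()] list).
#' @export
generate_run <- function(config, library, seed = 1L) {
  stopifnot(inherits(config, "run_config"),
            inherits(library, "spectral_library"))
  searchable <- library$index
  if (length(searchable) < config$n_compounds) {
    stop("library has ", length(searchable), " searchable entries; need ",
         config$n_compounds)
  }
  set.seed(seed)  # base RNG (Mersenne-Twister), version-stable across OSes
  compounds <- pick_separated_compounds(library, searchable, config)
  n_c <- length(compounds)
  margin <- max(4 * config$peak_sigma_min, 0.5)
  truth <- data.frame(
    compound = vapply(compounds, `[[`, character(1), "compound_name"),
    precursor_mz = vapply(compounds, `[[`, numeric(1), "precursor_mz"),
    rt_true = sort(stats::runif(n_c, margin, config$run_length_min - margin)),
    height = stats::runif(n_c, config$height_range[1L], config$height_range[2L]),
    stringsAsFactors = FALSE)
  heights <- matrix(truth$height, nrow = n_c, ncol = config$n_samples) *
    matrix(noise_factor(n_c * config$n_samples, config$intensity_cv), nrow = n_c)
  grid <- seq(0, config$run_length_min, by = config$ms1_interval_s / 60)
  scans_by_sample <- list()
  n_ms2 <- integer(n_c)
  for (s in seq_len(config$n_samples)) {
    res <- simulate_sample(config, compounds, truth, heights[, s], grid)
    scans_by_sample[[paste0("S", s)]] <- res$scans
    n_ms2 <- n_ms2 + res$n_ms2
  }
  truth$n_ms2 <- n_ms2
  list(scans_by_sample = scans_by_sample, ground_truth = truth,
       compounds = compounds)
}

# greedy pick of library entries with pairwise precursor separation
pick_separated_compounds <- function(library, searchable, config) {
  order_ix <- sample(searchable)
  chosen <- list(); chosen_mz <- numeric()
  min_sep <- config$min_mz_separation_ppm * 1e-6
  for (i in order_ix) {
    e <- library$entries[[i]]
    if (!length(chosen_mz) ||
        all(abs(chosen_mz - e$precursor_mz) / e$precursor_mz > min_sep)) {
      chosen[[length(chosen) + 1L]] <- e
      chosen_mz <- c(chosen_mz, e$precursor_mz)
      if (length(chosen) == config$n_compounds) return(chosen)
    }
  }
  stop("library too crowded: could not pick ", config$n_compounds,
       " compounds separated by ", config$min_mz_separation_ppm, " ppm")
}

noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2))))
}

jitter_mz <- function(mz, ppm_sd) {
  if (ppm_sd <= 0) return(mz)
  mz * (1 + stats::rnorm(length(mz), 0, ppm_sd * 1e-6))
}

simulate_sample <- function(config, compounds, truth, heights, grid) {
  n_c <- nrow(truth)
  scans <- vector("list", 4L * length(grid))
  n_scans <- 0L
  scan_id <- 0L
  push <- function(s) {
    n_scans <<- n_scans + 1L
    scans[[n_scans]] <<- s
  }
  excluded_until <- rep(-Inf, n_c)
  n_ms2 <- integer(n_c)
  sigma <- config$peak_sigma_min
  for (rt in grid) {
    elut <- heights * exp(-0.5 * ((rt - truth$rt_true) / sigma)^2)
    live <- which(elut > 1)
    mz <- c(jitter_mz(truth$precursor_mz[live], config$mz_jitter_ppm),
            stats::runif(config$baseline_peaks, 80, 1200))
    intensity <- c(elut[live] * noise_factor(length(live), config$intensity_cv),
                   stats::rexp(config$baseline_peaks, 1 / config$baseline_height))
    scan_id <- scan_id + 1L
    push(ms_scan(scan_id, 1L, rt, spectrum = spectrum(mz, intensity)))
    # DDA: top-k eligible precursors, dynamic exclusion
    elig <- live[elut[live] >= config$ms2_trigger_height &
                   rt >= excluded_until[live]]
    if (!length(elig)) next
    elig <- elig[order(-elut[elig])]
    for (ci in utils::head(elig, config$dda_top_k)) {
      excluded_until[ci] <- rt + config$dynamic_exclusion_s / 60
      n_ms2[ci] <- n_ms2[ci] + 1L
      frag <- compounds[[ci]]$spectrum
      fmz <- jitter_mz(frag$mz, config$mz_jitter_ppm)
      fint <- frag$intensity * noise_factor(n_peaks(frag), config$intensity_cv)
      if (config$chimerism_rate > 0) {
        co <- setdiff(which(abs(truth$rt_true - rt) < 2 * sigma), ci)
        if (length(co) && stats::runif(1) < config$chimerism_rate) {
          cf <- compounds[[co[1L]]]$spectrum
          fmz <- c(fmz, jitter_mz(cf$mz, config$mz_jitter_ppm))
          fint <- c(fint, cf$intensity *
                      noise_factor(n_peaks(cf), config$intensity_cv))
        }
      }
      scan_id <- scan_id + 1L
      push(ms_scan(scan_id, 2L, rt, spectrum = spectrum(fmz, fint),
                precursor_mz = truth$precursor_mz[ci],
                polarity = compounds[[ci]]$polarity))
    }
  }
  list(scans = scans[seq_len(n_scans)], n_ms2 = n_ms2)
}

#' Generate planted agreement/disagreement score sets
#'
#' Draws agreement and disagreement scores from normal distributions
#' truncated at zero, emulating the unimodal score histograms whose
#' separation the Retention Balance Point recovers.
#'
#' @param n_agree,n_disagree Positive counts.
#' @param agree_dist,disagree_dist Length-2 vectors `c(mean, sd)`.
#' @param seed Integer seed.
#' @return List with `agreements`, `disagreements` (numeric vectors).
#' @export
generate_comparison_scores <- function(n_agree, n_disagree,
                                       agree_dist = c(30, 3),
                                       disagree_dist = c(10, 3), seed = 1L) {
  if (n_agree <= 0 || n_disagree <= 0) {
    stop("n_agree and n_disagree must be positive")
  }
  set.seed(seed)
  draw <- function(n, ms) {
    x <- stats::rnorm(n, ms[1L], ms[2L])
    while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), ms[1L], ms[2L])
    x
  }
  list(agreements = draw(n_agree, agree_dist),
       disagreements = draw(n_disagree, disagree_dist))
}
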