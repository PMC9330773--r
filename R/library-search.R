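#' Default search parameters
#'
#' @param precursor_tol_ppm Precursor window half-width in ppm (default 20).
#' @param fragment_tol_ppm Fragment match tolerance in ppm (default 20).
#' @param score_type One of `"hgs"`, `"mvh"`, `"dot"`, `"frac_matched"`,
#'   `"tic_fraction"` (default `"hgs"`).
#' @param min_score Acceptance threshold (default 0: accept all — choosing a
#'   threshold is the user's or the Retention Balance Point's job).
#' @param N Bucket count for hypergeometric scoring.
#' @param intensity_power Weighting exponent for the dot product.
#' @param polarity +1/-1 or NULL for both.
#' @param retain_unannotated Keep groups with no accepted hit in the
#'   annotation table (default TRUE).
#' @return A `search_params` list.
#' @export
search_params <- function(precursor_tol_ppm = 20, fragment_tol_ppm = 20,
                          score_type = "hgs", min_score = 0, N = 1e5,
                          intensity_power = 0.5, polarity = NULL,
                          retain_unannotated = TRUE) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0)
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm, score_type = score_type,
                 min_score = min_score, N = N,
                 intensity_power = intensity_power, polarity = polarity,
                 retain_unannotated = retain_unannotated),
            class = "search_params")
}

#' Precursor m/z of a peak group
#'
#' The mean of the slice's seed MS2 precursor m/z values. Slices are
#' precursor-centered, so this — rather than the peak apex m/z — is the
#' natural query m/z for precursor-window library lookup.
#'
#' @param group A `peak_group`.
#' @return Precursor m/z in Th.
#' @export
group_precursor_mz <- function(group) {
  mean(group$slice$seeds[[1L]]$precursor_mz)
}

#' Search one peak group against a spectral library
#'
#' Candidates are the library entries whose precursor m/z lies within
#' `precursor_tol_ppm` of the group's seed-precursor mean (and match the
#' polarity filter, when set). Each candidate is scored against the group's
#' consensus spectrum; results are ranked by descending score with ties
#' broken by higher matched-fragment count k, then lexicographic compound
#' name (isomers with identical spectra are NOT disambiguated — the name
#' tie-break is arbitrary and documented as such). Results below `min_score`
#' are dropped.
#'
#' @param group A `peak_group` with a consensus spectrum.
#' @param library A [spectral_library()].
#' @param params A [search_params()].
#' @return data.frame with one row per accepted candidate: `library`,
#'   `compound`, `adduct`, `score`, `k`, `m`, `n`, `rank`.
#' @export
search_group <- function(group, library, params = search_params()) {
  stopifnot(inherits(group, "peak_group"), inherits(library, "spectral_library"))
  empty <- data.frame(library = character(), compound = character(),
                      adduct = character(), score = numeric(), k = integer(),
                      m = integer(), n = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(group$consensus) || n_peaks(group$consensus) == 0L) return(empty)
  cand <- library_lookup(library, group_precursor_mz(group),
                         params$precursor_tol_ppm, params$polarity)
  if (!length(cand)) return(empty)
  rows <- lapply(cand, function(ci) {
    e <- library$entries[[ci]]
    sc <- score_spectra(group$consensus, e$spectrum, params$score_type,
                        params$fragment_tol_ppm, params$N,
                        params$intensity_power)
    data.frame(library = library$name, compound = e$compound_name,
               adduct = e$adduct, score = sc$score, k = sc$k, m = sc$m,
               n = sc$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, -res$k, res$compound), , drop = FALSE]
  res <- res[res$score >= params$min_score, , drop = FALSE]
  if (nrow(res)) res$rank <- seq_len(nrow(res))
  else res$rank <- integer()
  rownames(res) <- NULL
  res
}

#' Annotate all peak groups against one or more libraries
#'
#' Builds the annotation table consumed by the cross-library comparison: one
#' row per (group, library) best (rank-1) hit. Groups with no accepted hit in
#' a library get an NA-compound row for that library when
#' `retain_unannotated` is TRUE, and are omitted otherwise. Full ranked
#' candidate lists are available from [search_group()], not from this table.
#'
#' @param groups List of `peak_group` objects (from [group_run()]).
#' @param libraries A [spectral_library()] or list of them.
#' @param params A [search_params()].
#' @return data.frame with columns `group_id`, `mz` (seed-precursor mean),
#'   `rt` (group apex), `library`, `compound`, `adduct`, `score`, `k`, `m`,
#'   `n`.
#' @export
search_dataset <- function(groups, libraries, params = search_params()) {
  if (inherits(libraries, "spectral_library")) libraries <- list(libraries)
  stopifnot(length(libraries) >= 1L)
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    for (lib in libraries) {
      hits <- search_group(g, lib, params)
      if (nrow(hits)) {
        top <- hits[1L, c("library", "compound", "adduct", "score",
                          "k", "m", "n")]
      } else if (params$retain_unannotated) {
        top <- data.frame(library = lib$name, compound = NA_character_,
                          adduct = NA_character_, score = NA_real_,
                          k = NA_integer_, m = NA_integer_, n = NA_integer_,
                          stringsAsFactors = FALSE)
      } else next
      out[[length(out) + 1L]] <- cbind(
        data.frame(group_id = gi, mz = group_precursor_mz(g), rt = g$rt_apex),
        top)
    }
  }
  if (!length(out)) {
    return(data.frame(group_id = integer(), mz = numeric(), rt = numeric(),
                      library = character(), compound = character(),
                      adduct = character(), score = numeric(), k = integer(),
                      m = integer(), n = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Precision as a function of score threshold
#'
#' For each score type and threshold, precision = correctly annotated
#' accepted groups / all accepted groups, where an annotation is correct
#' when the compound name matches the ground truth AND the group apex lies
#' within `rt_window_min` of the true retention time. Thresholds are
#' expressed as fractions of each score's observed maximum so different
#' score types can share one axis. Thresholds that accept nothing yield an
#' absent (NA) precision, not 0.
#'
#' @param annotations Annotation table from [search_dataset()] (one score
#'   type; run once per score type to compare them).
#' @param ground_truth data.frame with columns `group_id`, `compound`,
#'   `rt_true`.
#' @param thresholds Numeric vector of scaled thresholds in [0, 1]
#'   (default `seq(0, 1, 0.05)`).
#' @param rt_window_min RT window for calling a match correct (default 0.5).
#' @return data.frame with `threshold` (scaled), `score_threshold`
#'   (absolute), `n_accepted`, `n_correct`, `precision`.
#' @export
evaluate_precision <- function(annotations, ground_truth,
                               thresholds = seq(0, 1, 0.05),
                               rt_window_min = 0.5) {
  ann <- annotations[!is.na(annotations$compound), , drop = FALSE]
  gt <- ground_truth[match(ann$group_id, ground_truth$group_id), ]
  correct <- !is.na(gt$compound) & ann$compound == gt$compound &
    abs(ann$rt - gt$rt_true) <= rt_window_min
  smax <- if (nrow(ann)) max(ann$score) else NA_real_
  res <- lapply(thresholds, function(th) {
    abs_th <- th * smax
    acc <- which(ann$score >= abs_th)
    data.frame(threshold = th, score_threshold = abs_th,
               n_accepted = length(acc), n_correct = sum(correct[acc]),
               precision = if (length(acc)) sum(correct[acc]) / length(acc)
                           else NA_real_)
  })
  do.call(rbind, res)
}
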