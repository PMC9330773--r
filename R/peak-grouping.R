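#' Extract per-sample ion chromatograms for a slice
#'
#' For each sample, every MS1 scan with retention time inside the slice RT
#' range contributes one point whose intensity is the sum of centroid
#' intensities falling inside the slice m/z window (zero when no centroid
#' does). Empty chromatograms are valid.
#'
#' @param slice One row of a slice data.frame (see [build_slices()]).
#' @param scans_by_sample Named list of per-sample scan lists.
#' @return Named list of EICs, one per sample: each a data.frame with
#'   ascending `rt` and non-negative `intensity`.
#' @export
extract_eics <- function(slice, scans_by_sample) {
  lapply(scans_by_sample, function(scans) {
    rt <- numeric(); intensity <- numeric()
    for (s in scans) {
      if (s$ms_level != 1L || s$rt < slice$rt_min || s$rt > slice$rt_max) next
      sel <- s$spectrum$mz >= slice$mz_min & s$spectrum$mz <= slice$mz_max
      rt <- c(rt, s$rt)
      intensity <- c(intensity, sum(s$spectrum$intensity[sel]))
    }
    o <- order(rt)
    data.frame(rt = rt[o], intensity = intensity[o])
  })
}

#' Sum per-sample EICs into a merged EIC
#'
#' The merged grid is the sorted union of the member RT values; at each grid
#' point the intensity is the sum over samples of that sample's intensity at
#' exactly that RT (samples with no scan at that RT contribute zero — no
#' interpolation, so no signal is invented).
#'
#' @param eics List of EIC data.frames from [extract_eics()].
#' @return A single EIC data.frame.
#' @export
merge_eics <- function(eics) {
  stopifnot(length(eics) >= 1L)
  grid <- sort(unique(unlist(lapply(eics, `[[`, "rt"))))
  total <- numeric(length(grid))
  for (e in eics) {
    if (!nrow(e)) next
    ix <- match(e$rt, grid)
    total[ix] <- total[ix] + e$intensity
  }
  data.frame(rt = grid, intensity = total)
}

#' Detect chromatographic peaks on an EIC
#'
#' The trace is smoothed with a centered moving average; peak apexes are the
#' local maxima of the smoothed trace above `min_height`, and each peak's
#' boundaries extend from the apex to the nearest local minimum or zero point
#' on either side. Plateau maxima count once (the leftmost plateau point is
#' the apex), so no two peaks share an apex.
#'
#' @param eic EIC data.frame (`rt`, `intensity`).
#' @param smoothing_window Odd positive moving-average width in scans
#'   (default 5).
#' @param min_height Minimum smoothed apex intensity (default 1e4).
#' @return data.frame with `rt_apex`, `rt_start`, `rt_end`, `height`
#'   (raw trace at apex), `area` (trapezoidal, intensity x min), sorted by
#'   `rt_apex`.
#' @export
detect_peaks <- function(eic, smoothing_window = 5L, min_height = 1e4) {
  stopifnot(smoothing_window >= 1L, smoothing_window %% 2L == 1L,
            min_height >= 0)
  n <- nrow(eic)
  empty <- data.frame(rt_apex = numeric(), rt_start = numeric(),
                      rt_end = numeric(), height = numeric(), area = numeric())
  if (n > 0L && smoothing_window > n) {
    stop("smoothing window (", smoothing_window, ") longer than EIC (", n, " scans)")
  }
  if (n == 0L || all(eic$intensity <= 0)) return(empty)
  y <- smooth_ma(eic$intensity, smoothing_window)
  # local maxima: strictly above previous, >= next (leftmost plateau point)
  left <- c(-Inf, y[-n]); right <- c(y[-1L], -Inf)
  apex <- which(y > left & y >= right & y >= min_height)
  if (!length(apex)) return(empty)
  # boundary between consecutive apexes / trace ends: nearest local min or zero
  bounds <- vapply(apex, function(a) {
    i <- a
    while (i > 1L && y[i - 1L] <= y[i] && y[i - 1L] > 0) i <- i - 1L
    j <- a
    while (j < n && y[j + 1L] <= y[j] && y[j + 1L] > 0) j <- j + 1L
    c(i, j)
  }, integer(2))
  area <- vapply(seq_along(apex), function(k) {
    ix <- bounds[1L, k]:bounds[2L, k]
    if (length(ix) < 2L) return(0)
    sum(diff(eic$rt[ix]) * (utils::head(eic$intensity[ix], -1) +
                              utils::tail(eic$intensity[ix], -1)) / 2)
  }, numeric(1))
  out <- data.frame(rt_apex = eic$rt[apex], rt_start = eic$rt[bounds[1L, ]],
                    rt_end = eic$rt[bounds[2L, ]],
                    height = eic$intensity[apex], area = area)
  out[order(out$rt_apex), , drop = FALSE]
}

smooth_ma <- function(x, w) {
  if (w == 1L) return(x)
  # centered moving average with shrinking window at the edges
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Form cross-sample peak groups within a slice
#'
#' Peaks are picked on the merged EIC to define the group RT windows
#' ("overlapping regions of intensity"); each sample's own EIC peaks are then
#' assigned to the group whose merged-EIC window contains their apex (nearest
#' window on ties/missed containment within `rt_join_min`). Groups that end
#' up with no sample peak are dropped.
#'
#' @param slice One slice row.
#' @param eics Per-sample EICs from [extract_eics()] for this slice.
#' @param smoothing_window,min_height Passed to [detect_peaks()].
#' @param rt_join_min Max apex distance for out-of-window assignment
#'   (default 0.2 min).
#' @return List of `peak_group` objects: lists with `slice`, `rt_apex`,
#'   `rt_start`, `rt_end`, `peaks` (data.frame with `sample_id` column),
#'   `ms2_scans` (filled by [assign_ms2()]), `consensus` (NULL until built).
#' @export
form_peak_groups <- function(slice, eics, smoothing_window = 5L,
                             min_height = 1e4, rt_join_min = 0.2) {
  merged <- merge_eics(eics)
  if (!nrow(merged)) return(list())
  win <- min(smoothing_window, nrow(merged))
  if (win %% 2L == 0L) win <- win - 1L
  gpeaks <- detect_peaks(merged, win, min_height)
  if (!nrow(gpeaks)) return(list())
  groups <- lapply(seq_len(nrow(gpeaks)), function(i) {
    structure(list(slice = slice, rt_apex = gpeaks$rt_apex[i],
                   rt_start = gpeaks$rt_start[i], rt_end = gpeaks$rt_end[i],
                   peaks = NULL, ms2_scans = NULL, consensus = NULL),
              class = "peak_group")
  })
  members <- vector("list", length(groups))
  for (sid in names(eics)) {
    e <- eics[[sid]]
    if (!nrow(e)) next
    w <- min(smoothing_window, nrow(e))
    if (w %% 2L == 0L) w <- w - 1L
    sp <- detect_peaks(e, w, min_height)
    if (!nrow(sp)) next
    for (p in seq_len(nrow(sp))) {
      inside <- which(gpeaks$rt_start <= sp$rt_apex[p] &
                        gpeaks$rt_end >= sp$rt_apex[p])
      if (length(inside)) {
        g <- inside[which.min(abs(gpeaks$rt_apex[inside] - sp$rt_apex[p]))]
      } else {
        d <- abs(gpeaks$rt_apex - sp$rt_apex[p])
        g <- which.min(d)
        if (d[g] > rt_join_min) next
      }
      row <- cbind(sample_id = sid, sp[p, , drop = FALSE])
      members[[g]] <- rbind(members[[g]], row)
    }
  }
  keep <- which(!vapply(members, is.null, logical(1)))
  groups <- groups[keep]
  for (i in seq_along(groups)) {
    m <- members[[keep[i]]]
    rownames(m) <- NULL
    groups[[i]]$peaks <- m
  }
  groups
}

#' Assign a slice's seed MS2 scans to its peak groups
#'
#' Each MS2 scan that seeded (or was merged into) the slice is assigned to
#' the peak group whose merged-EIC apex is nearest in retention time,
#' provided the distance is within `rt_tolerance_min`; each scan goes to at
#' most one group. Groups left with no MS2 scan are dropped or kept as
#' explicitly unannotated according to `retain_unassigned`.
#'
#' @param groups List of peak groups from [form_peak_groups()].
#' @param slice The slice row the groups came from.
#' @param rt_tolerance_min Max |scan rt - group apex| in minutes (default 0.5).
#' @param retain_unassigned Keep groups with no MS2 scan, flagged via an
#'   empty `ms2_scans` table (default FALSE: discard them).
#' @return The groups, each with an `ms2_scans` data.frame
#'   (`sample_id`, `scan_id`, `rt`, `precursor_mz`).
#' @export
assign_ms2 <- function(groups, slice, rt_tolerance_min = 0.5,
                       retain_unassigned = FALSE) {
  seeds <- slice$seeds[[1L]]
  empty <- seeds[0L, , drop = FALSE]
  for (i in seq_along(groups)) groups[[i]]$ms2_scans <- empty
  if (length(groups) && nrow(seeds)) {
    apexes <- vapply(groups, `[[`, numeric(1), "rt_apex")
    for (k in seq_len(nrow(seeds))) {
      d <- abs(apexes - seeds$rt[k])
      g <- which.min(d)
      if (d[g] <= rt_tolerance_min) {
        groups[[g]]$ms2_scans <- rbind(groups[[g]]$ms2_scans,
                                       seeds[k, , drop = FALSE])
      }
    }
  }
  if (!retain_unassigned) {
    groups <- Filter(function(g) nrow(g$ms2_scans) > 0L, groups)
  }
  groups
}

#' Combine MS2 spectra into a consensus spectrum
#'
#' Fragments pooled across scans are clustered greedily: taking fragments in
#' descending intensity order, each unclaimed fragment seeds a cluster that
#' absorbs all unclaimed fragments within `fragment_tol_ppm` of the seed.
#' Each cluster becomes one consensus peak at the intensity-weighted mean m/z
#' with the mean member intensity. Clusters present in fewer than
#' `min_presence_fraction` of the scans are dropped, unless only one scan was
#' given. The default keeps every fragment: downstream hypergeometric scoring
#' tolerates chimeric contamination, so discarding real low-presence
#' fragments costs more than keeping noise.
#'
#' @param spectra List of [spectrum()] objects (one per assigned MS2 scan).
#' @param fragment_tol_ppm Cluster half-width in ppm (default 20).
#' @param min_presence_fraction Minimum fraction of scans a cluster must
#'   appear in (default 0).
#' @return A [spectrum()] sorted by m/z (empty if all inputs are empty).
#' @export
build_consensus <- function(spectra, fragment_tol_ppm = 20,
                            min_presence_fraction = 0) {
  stopifnot(length(spectra) >= 1L)
  mz <- unlist(lapply(spectra, `[[`, "mz"))
  if (!length(mz)) return(spectrum())
  intensity <- unlist(lapply(spectra, `[[`, "intensity"))
  scan_of <- rep(seq_along(spectra),
                 vapply(spectra, n_peaks, integer(1)))
  claimed <- logical(length(mz))
  out_mz <- numeric(); out_int <- numeric(); out_pres <- numeric()
  n_scans <- length(spectra)
  for (i in order(-intensity, mz)) {
    if (claimed[i]) next
    tol <- mz[i] * fragment_tol_ppm * 1e-6
    memb <- which(!claimed & abs(mz - mz[i]) <= tol)
    claimed[memb] <- TRUE
    w <- intensity[memb]
    cmz <- if (sum(w) > 0) sum(mz[memb] * w) / sum(w) else mean(mz[memb])
    out_mz <- c(out_mz, cmz)
    out_int <- c(out_int, mean(w))
    out_pres <- c(out_pres, length(unique(scan_of[memb])) / n_scans)
  }
  keep <- if (n_scans == 1L) rep(TRUE, length(out_mz)) else
    out_pres >= min_presence_fraction
  spectrum(out_mz[keep], out_int[keep])
}

#' Run slicing and peak grouping over a whole multi-sample run
#'
#' Convenience driver: builds and merges slices from the MS2 scans, extracts
#' and groups EIC peaks per merged slice, assigns MS2 scans, and attaches a
#' consensus spectrum to every group with at least one assigned scan.
#'
#' @param scans_by_sample Named list of per-sample scan lists.
#' @param mz_half_width_ppm,rt_half_width_min Slice geometry (see
#'   [build_slices()]).
#' @param smoothing_window,min_height Peak detection (see [detect_peaks()]).
#' @param rt_tolerance_min MS2 assignment window (see [assign_ms2()]).
#' @param fragment_tol_ppm,min_presence_fraction Consensus construction (see
#'   [build_consensus()]).
#' @param retain_unassigned Keep MS2-less groups (default FALSE).
#' @return List of `peak_group` objects across all slices, each carrying its
#'   slice, member peaks, assigned MS2 scans and consensus spectrum.
#' @export
group_run <- function(scans_by_sample, mz_half_width_ppm = 20,
                      rt_half_width_min = 0.5, smoothing_window = 5L,
                      min_height = 1e4, rt_tolerance_min = 0.5,
                      fragment_tol_ppm = 20, min_presence_fraction = 0,
                      retain_unassigned = FALSE) {
  slices <- merge_slices(build_slices(scans_by_sample, mz_half_width_ppm,
                                      rt_half_width_min))
  ms2_index <- index_ms2_scans(scans_by_sample)
  all_groups <- list()
  for (i in seq_len(nrow(slices))) {
    slice <- slices[i, , drop = FALSE]
    eics <- extract_eics(slice, scans_by_sample)
    groups <- form_peak_groups(slice, eics, smoothing_window, min_height)
    groups <- assign_ms2(groups, slice, rt_tolerance_min, retain_unassigned)
    for (g in groups) {
      if (nrow(g$ms2_scans)) {
        key <- paste(g$ms2_scans$sample_id, g$ms2_scans$scan_id)
        g$consensus <- build_consensus(ms2_index[key], fragment_tol_ppm,
                                       min_presence_fraction)
      }
      all_groups[[length(all_groups) + 1L]] <- g
    }
  }
  all_groups
}

index_ms2_scans <- function(scans_by_sample) {
  out <- list()
  for (sid in names(scans_by_sample)) {
    for (s in scans_by_sample[[sid]]) {
      if (s$ms_level == 2L) out[[paste(sid, s$scan_id)]] <- s$spectrum
    }
  }
  out
}
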