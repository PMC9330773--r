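#' Build precursor-seeded slices from MS2 scans
#'
#' Every MS2 scan seeds one rectangular block ("slice") in (m/z, retention
#' time) space, centered on its precursor m/z and scan retention time. The
#' m/z half-width is given in ppm and converted to Th at the seed precursor
#' (and frozen there: later merging unions Th bounds without re-applying
#' ppm). Slices, not full scan ranges, are the search space for peak
#' detection: requiring every peak group to carry at least one MS2 scan both
#' raises identification quality and prunes the MS1 search space.
#'
#' @param scans_by_sample Named list: one list of [ms_scan()] per sample.
#' @param mz_half_width_ppm Slice m/z half-width in ppm (default 20).
#' @param rt_half_width_min Slice RT half-width in minutes (default 0.5).
#' @return A data.frame of slices with columns `mz_min`, `mz_max`, `rt_min`,
#'   `rt_max` and a list-column `seeds` of data.frames
#'   (`sample_id`, `scan_id`, `rt`, `precursor_mz`). Runs with no MS2 scans
#'   yield a zero-row frame (valid: there is nothing to group).
#' @export
build_slices <- function(scans_by_sample, mz_half_width_ppm = 20,
                         rt_half_width_min = 0.5) {
  stopifnot(mz_half_width_ppm > 0, rt_half_width_min > 0)
  if (is.null(names(scans_by_sample))) {
    names(scans_by_sample) <- paste0("S", seq_along(scans_by_sample))
  }
  rows <- list()
  for (sid in names(scans_by_sample)) {
    for (s in scans_by_sample[[sid]]) {
      if (s$ms_level != 2L) next
      half <- s$precursor_mz * mz_half_width_ppm * 1e-6
      rows[[length(rows) + 1L]] <- data.frame(
        mz_min = s$precursor_mz - half, mz_max = s$precursor_mz + half,
        rt_min = max(0, s$rt - rt_half_width_min),
        rt_max = s$rt + rt_half_width_min,
        sample_id = sid, scan_id = s$scan_id, rt = s$rt,
        precursor_mz = s$precursor_mz, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_slices())
  df <- do.call(rbind, rows)
  out <- df[, c("mz_min", "mz_max", "rt_min", "rt_max")]
  out$seeds <- lapply(seq_len(nrow(df)), function(i)
    df[i, c("sample_id", "scan_id", "rt", "precursor_mz")])
  out
}

empty_slices <- function() {
  data.frame(mz_min = numeric(), mz_max = numeric(),
             rt_min = numeric(), rt_max = numeric(),
             seeds = I(list()))
}

#' Merge overlapping slices to a non-overlapping set
#'
#' Slices are progressively merged whenever they overlap in \emph{both} m/z
#' and retention time range, regardless of the sample they derive from, until
#' no two slices overlap. A merged slice's bounds are the coordinate-wise
#' union of its members and its seed list is the concatenation of theirs, so
#' every input seed scan survives in exactly one output slice. Intervals are
#' closed: a shared endpoint counts as overlap, which makes endpoint ties
#' merge deterministically. Because union bounds can create new overlaps,
#' merging iterates to a fixed point; the result is independent of input
#' order.
#'
#' @param slices A slice data.frame from [build_slices()].
#' @return A slice data.frame with pairwise non-overlapping rows, sorted by
#'   (`mz_min`, `rt_min`).
#' @export
merge_slices <- function(slices) {
  n <- nrow(slices)
  if (n <= 1L) return(slices)
  repeat {
    comp <- overlap_components(slices)
    if (max(comp) == nrow(slices)) break  # all singletons: no overlaps left
    slices <- union_by_component(slices, comp)
  }
  slices[order(slices$mz_min, slices$rt_min), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# connected components of the both-axes overlap graph (label propagation on
# sorted mz intervals; only pairs overlapping in m/z are inspected)
overlap_components <- function(s) {
  n <- nrow(s)
  o <- order(s$mz_min)
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i] <<- comp[comp[i]]
    i
  }
  mzmin <- s$mz_min[o]; mzmax <- s$mz_max[o]
  rtmin <- s$rt_min[o]; rtmax <- s$rt_max[o]
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (mzmin[b] > mzmax[a]) break  # sorted by mz_min: no further mz overlap
      if (rtmin[b] <= rtmax[a] && rtmax[b] >= rtmin[a]) {
        ra <- find(o[a]); rb <- find(o[b])
        if (ra != rb) comp[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

union_by_component <- function(s, comp) {
  groups <- split(seq_len(nrow(s)), comp)
  out <- lapply(groups, function(ix) {
    data.frame(mz_min = min(s$mz_min[ix]), mz_max = max(s$mz_max[ix]),
               rt_min = min(s$rt_min[ix]), rt_max = max(s$rt_max[ix]))
  })
  res <- do.call(rbind, out)
  res$seeds <- lapply(groups, function(ix) {
    do.call(rbind, s$seeds[ix])
  })
  rownames(res) <- NULL
  res
}

# TRUE if any pair of rows overlaps in both axes (closed intervals)
slices_overlap_any <- function(s) {
  n <- nrow(s)
  if (n <= 1L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    hit <- s$mz_min[j] <= s$mz_max[i] & s$mz_max[j] >= s$mz_min[i] &
      s$rt_min[j] <= s$rt_max[i] & s$rt_max[j] >= s$rt_min[i]
    if (any(hit)) return(TRUE)
  }
  FALSE
}
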