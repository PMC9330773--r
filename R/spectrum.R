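#' Construct a centroided mass spectrum
#'
#' The atomic data structure of the package: a pair of parallel numeric
#' vectors holding fragment (or centroid) m/z values in Thomson and their
#' abundances in arbitrary units. All downstream matching, scoring and
#' consensus building operates on this type. Spectra are always treated as
#' centroided; no profile-mode peak picking is performed.
#'
#' @param mz Numeric vector of m/z values (Th), strictly increasing.
#' @param intensity Numeric vector of non-negative abundances, same length.
#' @param sort If TRUE (default), peaks are sorted by m/z before validation.
#' @return An object of class `spectrum`: a list with elements `mz` and
#'   `intensity`. The empty spectrum (zero peaks) is valid.
#' @examples
#' sp <- spectrum(c(100.1, 200.2), c(50, 100))
#' n_peaks(sp)
#' @export
spectrum <- function(mz = numeric(), intensity = numeric(), sort = TRUE) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (sort && length(mz) > 1L && is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    # merge exact duplicates (can arise from symmetric fragment rules)
    key <- !duplicated(mz)
    intensity <- as.numeric(tapply(intensity, match(mz, mz[key]), max))
    mz <- mz[key]
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("mz and intensity must be finite")
  }
  structure(list(mz = mz, intensity = intensity), class = "spectrum")
}

#' @rdname spectrum
#' @param x Object to test or query.
#' @export
is_spectrum <- function(x) inherits(x, "spectrum")

#' @rdname spectrum
#' @export
n_peaks <- function(x) length(x$mz)

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d peaks", n_peaks(x)))
  if (n_peaks(x) > 0) {
    cat(sprintf(", m/z %.4f-%.4f, base peak %.4f",
                min(x$mz), max(x$mz), x$mz[which.max(x$intensity)]))
  }
  cat(">\n")
  invisible(x)
}

#' Normalize a spectrum to base peak 100
#'
#' Rescales intensities so the most abundant peak has intensity 100.0; peak
#' order is preserved. This is the intensity convention used throughout the
#' package (it makes a "0.2% of base peak" cutoff a plain threshold of 0.2).
#'
#' @param sp A non-empty [spectrum()].
#' @return A `spectrum` with max intensity exactly 100.
#' @export
normalize_spectrum <- function(sp) {
  stopifnot(is_spectrum(sp))
  if (n_peaks(sp) == 0L) stop("cannot normalize an empty spectrum")
  base <- max(sp$intensity)
  if (base <= 0) stop("cannot normalize a spectrum with all-zero intensities")
  spectrum(sp$mz, sp$intensity * (100 / base), sort = FALSE)
}

#' Construct a single MS scan
#'
#' @param scan_id Integer scan identifier, unique within a sample.
#' @param ms_level 1 (survey) or 2 (fragmentation).
#' @param rt Retention time in minutes (>= 0).
#' @param polarity +1 or -1.
#' @param spectrum A [spectrum()] (may be empty).
#' @param precursor_mz Precursor m/z in Th; required and > 0 for MS2 scans.
#' @param precursor_isolation_width Isolation window full width in Th
#'   (MS2 only; default 1).
#' @return An object of class `scan`.
#' @export
ms_scan <- function(scan_id, ms_level, rt, polarity = 1L, spectrum = NULL,
                 precursor_mz = NA_real_, precursor_isolation_width = 1) {
  if (is.null(spectrum)) spectrum <- lcmsmatch::spectrum()
  stopifnot(is_spectrum(spectrum), ms_level %in% c(1L, 2L), rt >= 0,
            polarity %in% c(-1L, 1L))
  if (ms_level == 2L && (is.na(precursor_mz) || precursor_mz <= 0)) {
    stop("MS2 scans require a positive precursor_mz")
  }
  structure(list(scan_id = as.integer(scan_id), ms_level = as.integer(ms_level),
                 rt = as.numeric(rt), polarity = as.integer(polarity),
                 spectrum = spectrum, precursor_mz = as.numeric(precursor_mz),
                 precursor_isolation_width = as.numeric(precursor_isolation_width)),
            class = "scan")
}

#' Construct a spectral library entry
#'
#' A named reference compound spectrum with its precursor m/z, adduct and
#' free-form metadata (lipid class, summed composition, collision energy, ...).
#'
#' @param compound_name Compound name (text).
#' @param precursor_mz Precursor m/z in Th (> 0); `NA` is tolerated on import
#'   but flags the entry unsearchable.
#' @param adduct Adduct string, e.g. `"[M+H]+"`.
#' @param polarity +1 or -1.
#' @param spectrum A non-empty [spectrum()].
#' @param formula Optional elemental formula string.
#' @param metadata Named character list/vector of additional fields; keys are
#'   lower-cased.
#' @return An object of class `library_entry`.
#' @export
library_entry <- function(compound_name, precursor_mz, adduct = "",
                          polarity = 1L, spectrum, formula = NA_character_,
                          metadata = list()) {
  stopifnot(is_spectrum(spectrum))
  if (n_peaks(spectrum) == 0L) stop("library entries require a non-empty spectrum")
  if (!is.na(precursor_mz) && precursor_mz <= 0) {
    stop("precursor_mz must be positive")
  }
  md <- as.list(metadata)
  if (length(md)) names(md) <- tolower(names(md))
  structure(list(compound_name = as.character(compound_name),
                 precursor_mz = as.numeric(precursor_mz),
                 adduct = as.character(adduct), polarity = as.integer(polarity),
                 spectrum = spectrum, formula = as.character(formula),
                 metadata = md),
            class = "library_entry")
}

#' Construct a spectral library
#'
#' Holds a list of [library_entry()] objects together with a sorted precursor
#' m/z index so precursor-window candidate lookup is O(log n + hits). Entries
#' without a precursor m/z are kept but never returned by window queries.
#'
#' @param entries List of [library_entry()].
#' @param name Library name (used in annotation tables).
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(entries = list(), name = "library") {
  stopifnot(all(vapply(entries, inherits, logical(1), "library_entry")))
  prec <- vapply(entries, function(e) e$precursor_mz, numeric(1))
  searchable <- which(!is.na(prec))
  idx <- searchable[order(prec[searchable])]
  structure(list(name = as.character(name), entries = entries,
                 index = idx, index_mz = prec[idx]),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library '%s': %d entries (%d searchable)>\n",
              x$name, length(x$entries), length(x$index)))
  invisible(x)
}

#' @rdname spectral_library
#' @param x A `spectral_library`.
#' @export
library_size <- function(x) length(x$entries)

#' Look up library entries in a precursor m/z window
#'
#' Binary search on the precursor index; returns exactly the searchable
#' entries whose precursor m/z lies in `[mz - tol, mz + tol]` (tolerance from
#' ppm), optionally restricted to one polarity.
#'
#' @param lib A [spectral_library()].
#' @param mz Query m/z (Th).
#' @param tol_ppm Window half-width in ppm of `mz`.
#' @param polarity Optional +1/-1 filter; NULL matches both.
#' @return Integer vector of entry positions in `lib$entries`.
#' @export
library_lookup <- function(lib, mz, tol_ppm, polarity = NULL) {
  stopifnot(inherits(lib, "spectral_library"), mz > 0, tol_ppm > 0)
  tol <- mz * tol_ppm * 1e-6
  lo <- findInterval(mz - tol, lib$index_mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + tol, lib$index_mz)
  if (hi < lo) return(integer())
  hits <- lib$index[lo:hi]
  if (!is.null(polarity)) {
    pol <- vapply(lib$entries[hits], function(e) e$polarity, integer(1))
    hits <- hits[pol == as.integer(polarity)]
  }
  hits
}
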