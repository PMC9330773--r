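#' Read a centroided DDA run from an mzML file
#'
#' Thin wrapper over the proteowizard-based reader in \pkg{mzR}. All MS1 and
#' MS2 scans are returned in retention-time order; precursor m/z and the
#' isolation window are captured for MS2 scans. Profile-mode spectra are
#' accepted as-is with a warning (the pipeline assumes vendor centroiding).
#'
#' @param path Path to an mzML file.
#' @return A list of [ms_scan()] objects ordered by retention time.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("cannot read mzML file: ", path)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("mzML parse error for '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  if (nrow(hdr) == 0L) return(list())
  if (!is.null(hdr$centroided) && any(!hdr$centroided, na.rm = TRUE)) {
    warning("profile-mode spectra in '", path, "' are treated as centroided")
  }
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- pk[[i]]
    iso <- NA_real_
    if (!is.null(hdr$isolationWindowLowerOffset)) {
      iso <- hdr$isolationWindowLowerOffset[i] + hdr$isolationWindowUpperOffset[i]
    }
    ms_scan(scan_id = hdr$acquisitionNum[i],
         ms_level = hdr$msLevel[i],
         rt = hdr$retentionTime[i] / 60,  # mzR reports seconds; minutes throughout
         polarity = if (!is.null(hdr$polarity) && !is.na(hdr$polarity[i]) &&
                        hdr$polarity[i] == 0) -1L else 1L,
         spectrum = spectrum(p[, 1L], p[, 2L]),
         precursor_mz = if (hdr$msLevel[i] >= 2L) hdr$precursorMZ[i] else NA_real_,
         precursor_isolation_width = if (is.na(iso)) 1 else iso)
  })
  scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
}

#' Write a list of scans to an mzML file
#'
#' Serialises in-memory [ms_scan()] lists (typically from [generate_run()])
#' through \pkg{mzR}'s proteowizard writer so they round-trip through
#' [read_mzml()].
#'
#' @param scans List of [ms_scan()] objects.
#' @param path Output mzML path.
#' @return Invisibly, `path`.
#' @export
write_mzml <- function(scans, path) {
  stopifnot(length(scans) > 0L, all(vapply(scans, inherits, logical(1), "scan")))
  n <- length(scans)
  num <- function(f) vapply(scans, function(s) as.numeric(f(s)), numeric(1))
  int <- function(f) vapply(scans, function(s) as.integer(f(s)), integer(1))
  ms2 <- int(function(s) s$ms_level) == 2L
  tic <- num(function(s) sum(s$spectrum$intensity))
  base_i <- vapply(scans, function(s) {
    if (n_peaks(s$spectrum) == 0L) return(c(0, 0))
    j <- which.max(s$spectrum$intensity)
    c(s$spectrum$mz[j], s$spectrum$intensity[j])
  }, numeric(2))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = int(function(s) s$scan_id),
    msLevel = int(function(s) s$ms_level),
    polarity = int(function(s) if (s$polarity > 0) 1L else 0L),
    peaksCount = int(function(s) n_peaks(s$spectrum)),
    totIonCurrent = tic, retentionTime = num(function(s) s$rt) * 60,
    basePeakMZ = base_i[1L, ], basePeakIntensity = base_i[2L, ],
    collisionEnergy = ifelse(ms2, 30, NA_real_), ionisationEnergy = 0,
    lowMZ = num(function(s) if (n_peaks(s$spectrum)) min(s$spectrum$mz) else 0),
    highMZ = num(function(s) if (n_peaks(s$spectrum)) max(s$spectrum$mz) else 0),
    precursorScanNum = ifelse(ms2, NA_integer_, NA_integer_),
    precursorMZ = ifelse(ms2, num(function(s) s$precursor_mz), NA_real_),
    precursorCharge = ifelse(ms2, 1L, NA_integer_),
    precursorIntensity = ifelse(ms2, 0, NA_real_),
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_, mergedResultEndScanNum = NA_integer_,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", int(function(s) s$scan_id)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(ms2, num(function(s) s$precursor_mz), NA_real_),
    isolationWindowLowerOffset = ifelse(ms2, num(function(s) s$precursor_isolation_width) / 2, NA_real_),
    isolationWindowUpperOffset = ifelse(ms2, num(function(s) s$precursor_isolation_width) / 2, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  pks <- lapply(scans, function(s) cbind(mz = s$spectrum$mz,
                                         intensity = s$spectrum$intensity))
  mzR::writeMSData(pks, path, header = hdr)
  invisible(path)
}
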