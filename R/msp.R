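#' Read a spectral library in NIST msp format
#'
#' Parses the msp dialect used by the common free metabolomics and lipidomics
#' libraries (MoNA, LipidBlast, MS-DIAL exports): a `Name:` line starts a
#' record; `PrecursorMZ:` (any capitalisation, also `PRECURSORMZ`) gives the
#' precursor; optional header lines (`Comment:`, `Formula:`, `Adduct:` /
#' `Precursor_type:`, `Ion_mode:`, ...) become metadata; `Num Peaks: n` is
#' followed by n peak lines of `mz<sep>intensity` with whitespace, tab or
#' semicolon separators.
#'
#' Records whose peak count does not match the declared `Num Peaks` are
#' dropped with a warning naming the record; parsing continues. Records with
#' no precursor m/z are retained but flagged unsearchable (their
#' `precursor_mz` is `NA` and window queries never return them).
#'
#' Lipid class / summed composition metadata are taken from `Comment:`
#' key=value pairs when present, otherwise inferred from the record name via
#' [parse_lipid_name()] (msp has no standard fields for them).
#'
#' @param path Path to an msp file.
#' @param name Library name; defaults to the file name without extension.
#' @return A [spectral_library()].
#' @export
read_msp <- function(path, name = NULL) {
  if (!file.exists(path)) stop("msp file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^[Nn][Aa][Mm][Ee]:", lines)
  entries <- vector("list", length(starts))
  n_ok <- 0L
  ends <- c(starts[-1L] - 1L, length(lines))
  for (i in seq_along(starts)) {
    rec <- lines[starts[i]:ends[i]]
    e <- tryCatch(parse_msp_record(rec), error = function(err) {
      warning("skipping msp record '", sub("^[^:]*:\\s*", "", rec[1L]),
              "': ", conditionMessage(err), call. = FALSE)
      NULL
    })
    if (!is.null(e)) {
      n_ok <- n_ok + 1L
      entries[[n_ok]] <- e
    }
  }
  spectral_library(entries[seq_len(n_ok)], name = name)
}

parse_msp_record <- function(rec) {
  rec <- rec[nzchar(trimws(rec))]
  np_line <- grep("^[Nn][Uu][Mm][ _]?[Pp][Ee][Aa][Kk][Ss]\\s*:", rec)
  if (length(np_line) != 1L) stop("missing 'Num Peaks' line")
  header <- rec[seq_len(np_line)]
  npeaks <- as.integer(trimws(sub("^[^:]*:", "", rec[np_line])))
  peak_lines <- if (np_line < length(rec)) rec[(np_line + 1L):length(rec)] else character()
  if (length(peak_lines) != npeaks) {
    stop(sprintf("declares %d peaks but has %d peak lines",
                 npeaks, length(peak_lines)))
  }
  keys <- tolower(trimws(sub(":.*$", "", header)))
  vals <- trimws(sub("^[^:]*:", "", header))
  meta <- as.list(vals)
  names(meta) <- keys
  compound <- meta[["name"]]
  prec_key <- intersect(c("precursormz", "precursor_mz", "precursor m/z"), keys)
  precursor <- if (length(prec_key)) as.numeric(meta[[prec_key[1L]]]) else NA_real_
  adduct_key <- intersect(c("adduct", "precursor_type", "precursortype"), keys)
  adduct <- if (length(adduct_key)) meta[[adduct_key[1L]]] else ""
  polarity <- 1L
  if ("ion_mode" %in% keys) {
    polarity <- if (grepl("^[Nn]", meta[["ion_mode"]])) -1L else 1L
  } else if (grepl("\\]-\\s*$|-$", adduct)) polarity <- -1L
  formula <- if ("formula" %in% keys) meta[["formula"]] else NA_character_
  # fold Comment: key=value pairs into metadata
  if ("comment" %in% keys) {
    kv <- regmatches(meta[["comment"]],
                     gregexpr("[A-Za-z_][A-Za-z0-9_ ]*=[^;\"]+", meta[["comment"]]))[[1L]]
    for (pair in kv) {
      k <- tolower(trimws(sub("=.*$", "", pair)))
      meta[[k]] <- trimws(sub("^[^=]*=", "", pair))
    }
  }
  meta[c("name", prec_key, adduct_key, "ion_mode", "formula",
         "num peaks", "num_peaks", "numpeaks")] <- NULL
  pk <- do.call(rbind, lapply(peak_lines, function(l) {
    f <- strsplit(trimws(l), "[\t; ]+")[[1L]]
    as.numeric(f[1:2])
  }))
  if (npeaks > 0L && any(is.na(pk))) stop("unparseable peak line")
  sp <- if (npeaks > 0L) spectrum(pk[, 1L], pk[, 2L]) else spectrum()
  library_entry(compound, precursor, adduct = adduct, polarity = polarity,
                spectrum = sp, formula = formula, metadata = meta)
}

#' Write a spectral library to NIST msp format
#'
#' Inverse of [read_msp()]: the written file re-reads to a numerically
#' identical library (names, precursors, adducts and peaks round-trip within
#' 1e-6 relative). Metadata is emitted as individual header lines.
#'
#' @param lib A [spectral_library()]; all entries must have a precursor m/z.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msp <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  prec <- vapply(lib$entries, function(e) e$precursor_mz, numeric(1))
  if (anyNA(prec)) stop("all entries must have a precursor_mz to write msp")
  con <- file(path, "w")
  on.exit(close(con))
  for (e in lib$entries) {
    writeLines(c(
      paste0("Name: ", e$compound_name),
      sprintf("PrecursorMZ: %.6f", e$precursor_mz),
      paste0("Adduct: ", e$adduct),
      paste0("Ion_mode: ", if (e$polarity < 0) "Negative" else "Positive"),
      if (!is.na(e$formula)) paste0("Formula: ", e$formula),
      if (length(e$metadata)) paste0(names(e$metadata), ": ",
                                     vapply(e$metadata, as.character, character(1))),
      sprintf("Num Peaks: %d", n_peaks(e$spectrum)),
      sprintf("%.6f %.6f", e$spectrum$mz, e$spectrum$intensity),
      ""), con)
  }
  invisible(path)
}

#' Read a spectral library from the flat CSV dialect
#'
#' One row per peak with columns `compound,precursor_mz,adduct,mz,intensity`
#' (extra columns become per-entry metadata, taken from each compound's first
#' row). Rows sharing (compound, adduct) form one entry.
#'
#' @param path CSV file path.
#' @param name Library name; defaults to the file name.
#' @return A [spectral_library()].
#' @export
read_csv_library <- function(path, name = NULL) {
  if (!file.exists(path)) stop("csv library not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "precursor_mz", "adduct", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("csv library requires columns: ", paste(need, collapse = ", "))
  }
  key <- paste(df$compound, df$adduct, sep = "\r")
  extra <- setdiff(names(df), need)
  entries <- lapply(split(seq_len(nrow(df)), key), function(ix) {
    d <- df[ix, , drop = FALSE]
    md <- as.list(d[1L, extra, drop = FALSE])
    polarity <- if (grepl("-$|\\]-", d$adduct[1L])) -1L else 1L
    library_entry(d$compound[1L], d$precursor_mz[1L], adduct = d$adduct[1L],
                  polarity = polarity, spectrum = spectrum(d$mz, d$intensity),
                  metadata = md)
  })
  spectral_library(unname(entries), name = name)
}
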