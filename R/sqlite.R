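SCHEMA_VERSION <- 1L

#' Store a spectral library in an on-disk SQLite database
#'
#' The store uses a single `compounds` table (one row per entry) with peaks
#' stored as two `;`-delimited text columns (`mz_list`, `intensity_list`,
#' written at full double precision with `%.9g`), an index on `precursor_mz`
#' for window queries, and a `meta` table carrying the schema version.
#' Loading a database written with a different schema version is an explicit
#' error; there is no silent migration.
#'
#' @param lib A [spectral_library()].
#' @param db_path Path for the SQLite file (overwritten if present).
#' @return Invisibly, `db_path`.
#' @export
library_to_sqlite <- function(lib, db_path) {
  stopifnot(inherits(lib, "spectral_library"))
  if (file.exists(db_path)) file.remove(db_path)
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('schema_version', :v),
                       ('library_name', :n)",
                 params = list(v = as.character(SCHEMA_VERSION), n = lib$name))
  DBI::dbExecute(con, "CREATE TABLE compounds (
      id INTEGER PRIMARY KEY,
      compound_name TEXT NOT NULL,
      precursor_mz REAL,
      adduct TEXT,
      polarity INTEGER,
      formula TEXT,
      metadata TEXT,
      mz_list TEXT NOT NULL,
      intensity_list TEXT NOT NULL)")
  if (library_size(lib) > 0L) {
    rows <- data.frame(
      id = seq_along(lib$entries),
      compound_name = vapply(lib$entries, `[[`, character(1), "compound_name"),
      precursor_mz = vapply(lib$entries, `[[`, numeric(1), "precursor_mz"),
      adduct = vapply(lib$entries, `[[`, character(1), "adduct"),
      polarity = vapply(lib$entries, `[[`, integer(1), "polarity"),
      formula = vapply(lib$entries, `[[`, character(1), "formula"),
      metadata = vapply(lib$entries, function(e) pack_metadata(e$metadata),
                        character(1)),
      mz_list = vapply(lib$entries, function(e) pack_num(e$spectrum$mz),
                       character(1)),
      intensity_list = vapply(lib$entries, function(e) pack_num(e$spectrum$intensity),
                              character(1)),
      stringsAsFactors = FALSE)
    DBI::dbWriteTable(con, "compounds", rows, append = TRUE)
  }
  DBI::dbExecute(con, "CREATE INDEX idx_precursor ON compounds (precursor_mz)")
  invisible(db_path)
}

pack_num <- function(x) paste(sprintf("%.9g", x), collapse = ";")
unpack_num <- function(s) if (!nzchar(s)) numeric() else as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
pack_metadata <- function(md) {
  if (!length(md)) return("")
  paste(paste0(names(md), "=", vapply(md, as.character, character(1))),
        collapse = "\x1f")
}
unpack_metadata <- function(s) {
  if (!nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, "\x1f", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) paste(p[-1L], collapse = "=")),
                  vapply(kv, `[[`, character(1), 1L))
}

#' Load a spectral library from its SQLite store
#'
#' @param db_path Path to a database written by [library_to_sqlite()].
#' @return A [spectral_library()] equal to the stored one on all fields.
#' @export
load_library_sqlite <- function(db_path) {
  if (!file.exists(db_path)) stop("SQLite library not found: ", db_path)
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  meta <- DBI::dbGetQuery(con, "SELECT key, value FROM meta")
  ver <- as.integer(meta$value[meta$key == "schema_version"])
  if (!identical(ver, SCHEMA_VERSION)) {
    stop(sprintf("library schema version mismatch: file has %s, package expects %d",
                 ver, SCHEMA_VERSION))
  }
  lib_name <- meta$value[meta$key == "library_name"]
  rows <- DBI::dbGetQuery(con, "SELECT * FROM compounds ORDER BY id")
  entries <- lapply(seq_len(nrow(rows)), function(i) {
    library_entry(rows$compound_name[i], rows$precursor_mz[i],
                  adduct = rows$adduct[i], polarity = rows$polarity[i],
                  spectrum = spectrum(unpack_num(rows$mz_list[i]),
                                      unpack_num(rows$intensity_list[i])),
                  formula = rows$formula[i],
                  metadata = unpack_metadata(rows$metadata[i]))
  })
  spectral_library(entries, name = lib_name)
}
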