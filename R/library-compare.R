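#' Parse a lipid shorthand name
#'
#' Understands the common shorthand grammar `CLASS C:D` (summed composition,
#' e.g. `"PC 34:1"`) and `CLASS c1:d1/c2:d2[/c3:d3]` (chain composition,
#' e.g. `"PC 16:0/18:1"`), including sphingoid-base chains with a `d`/`t`
#' prefix (`"SM d18:1/16:0"`). For chain-level names the summed composition
#' is the element-wise chain sum. Names outside the grammar yield a
#' class-only annotation with `parsed = FALSE`.
#'
#' @param name Lipid name string (non-empty).
#' @return A `lipid_annotation` list: `lipid_class`, `summed_carbons`,
#'   `summed_double_bonds`, `chains` (data.frame or NULL), `compound_name`,
#'   `parsed`.
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(trimws(name))) stop("empty lipid name")
  name <- trimws(name)
  ann <- structure(list(lipid_class = strsplit(name, "[ (]")[[1L]][1L],
                        summed_carbons = NA_integer_,
                        summed_double_bonds = NA_integer_, chains = NULL,
                        compound_name = name, parsed = FALSE),
                   class = "lipid_annotation")
  m <- regmatches(name, regexec(
    "^([A-Za-z][A-Za-z0-9]*)[ (]([dto]?\\d+:\\d+(?:/[dto]?\\d+:\\d+)*)\\)?$",
    name))[[1L]]
  if (length(m) != 3L) return(ann)
  parts <- strsplit(m[3L], "/", fixed = TRUE)[[1L]]
  cd <- do.call(rbind, lapply(parts, function(p) {
    as.integer(strsplit(sub("^[dto]", "", p), ":", fixed = TRUE)[[1L]])
  }))
  ann$parsed <- TRUE
  ann$summed_carbons <- sum(cd[, 1L])
  ann$summed_double_bonds <- sum(cd[, 2L])
  if (length(parts) > 1L || grepl("/", m[3L], fixed = TRUE)) {
    chains <- data.frame(carbons = cd[, 1L], double_bonds = cd[, 2L],
                         prefix = sub("^([dto]?).*$", "\\1", parts),
                         stringsAsFactors = FALSE)
    chains <- chains[order(chains$prefix == "", chains$carbons,
                           chains$double_bonds), , drop = FALSE]
    rownames(chains) <- NULL
    ann$chains <- chains
  }
  ann
}

#' Classify the agreement level between two annotations of one feature
#'
#' Returns the highest satisfied level of the agreement hierarchy: same
#' lipid class -> `"class"`; additionally same adduct -> `"class_adduct"`;
#' additionally same summed composition -> `"summed_adduct"`; additionally
#' same chain composition (or identical compound names when chains are not
#' resolved) -> `"full_agreement"`; different class ->
#' `"full_disagreement"`. Adducts compare by strict string equality. The
#' levels are monotone: full agreement implies all weaker levels.
#'
#' @param a,b `lipid_annotation` objects (or name strings, parsed on the
#'   fly); each may carry an `adduct` attribute/element set via `adduct_a`,
#'   `adduct_b`.
#' @param adduct_a,adduct_b Adduct strings for the two annotations.
#' @return One of `"full_disagreement"`, `"class"`, `"class_adduct"`,
#'   `"summed_adduct"`, `"full_agreement"`.
#' @export
classify_agreement <- function(a, b, adduct_a = "", adduct_b = "") {
  if (is.character(a)) a <- parse_lipid_name(a)
  if (is.character(b)) b <- parse_lipid_name(b)
  if (!identical(a$lipid_class, b$lipid_class)) return("full_disagreement")
  level <- "class"
  if (!identical(adduct_a, adduct_b)) return(level)
  level <- "class_adduct"
  if (is.na(a$summed_carbons) || is.na(b$summed_carbons) ||
      a$summed_carbons != b$summed_carbons ||
      a$summed_double_bonds != b$summed_double_bonds) return(level)
  level <- "summed_adduct"
  same_chains <- if (!is.null(a$chains) && !is.null(b$chains)) {
    isTRUE(all.equal(a$chains, b$chains, check.attributes = FALSE))
  } else {
    identical(a$compound_name, b$compound_name)
  }
  if (same_chains) "full_agreement" else level
}

AGREEMENT_LEVELS <- c("full_disagreement", "class", "class_adduct",
                      "summed_adduct", "full_agreement")

#' Retention Balance Point of an agreement/disagreement score set
#'
#' Given the match scores of features where two libraries agree and where
#' they disagree, finds the score threshold maximizing
#' \deqn{\frac{\#\{agreements \ge t\}}{\#agreements} -
#'       \frac{\#\{disagreements \ge t\}}{\#disagreements}.}
#' The objective is a step function changing only at observed scores, so
#' candidate thresholds are the distinct observed values (union of both
#' lists); ties resolve to the lowest such threshold, which retains the most
#' annotations at equal objective. The returned threshold serves as a
#' library-specific annotation acceptance cutoff in lieu of a formal FDR.
#'
#' @param agreement_scores,disagreement_scores Non-empty numeric vectors.
#' @return List with `threshold` and `objective` (in [-1, 1]).
#' @examples
#' compute_rbp(c(10, 20, 30), c(5, 15))  # threshold 20, objective 2/3
#' @export
compute_rbp <- function(agreement_scores, disagreement_scores) {
  if (!length(agreement_scores) || !length(disagreement_scores)) {
    stop("RBP requires non-empty agreement and disagreement score lists")
  }
  stopifnot(all(is.finite(agreement_scores)), all(is.finite(disagreement_scores)))
  cand <- sort(unique(c(agreement_scores, disagreement_scores)))
  a_sorted <- sort(agreement_scores)
  d_sorted <- sort(disagreement_scores)
  n_a <- length(a_sorted); n_d <- length(d_sorted)
  # #{x >= t} computed by binary search on the sorted lists
  frac_ge <- function(sorted, n, t) (n - findInterval(t, sorted, left.open = TRUE)) / n
  obj <- frac_ge(a_sorted, n_a, cand) - frac_ge(d_sorted, n_d, cand)
  best <- which.max(obj)  # which.max takes the first (lowest) maximizer
  list(threshold = cand[best], objective = obj[best])
}

#' Reconcile a two-library annotation table with RBP thresholds
#'
#' Applies each library's Retention Balance Point as its acceptance cutoff:
#' an annotation is discarded when its score falls below its own library's
#' RBP. Every feature is then classified as unannotated, annotated by one
#' library only (including "both matched, one fell below its threshold"),
#' or annotated by both — in which case the agreement level of the two
#' surviving annotations is recorded. Feature counts partition: the category
#' counts sum to the number of features. Compound-level counts de-duplicate
#' adduct forms (a compound = class + chain composition, or summed
#' composition when chains are unresolved).
#'
#' @param annotation_table Table from [search_dataset()] run with exactly two
#'   libraries.
#' @param rbp_by_library Named numeric vector of RBP thresholds, one per
#'   library.
#' @return List with `features` (per-feature classification data.frame) and
#'   `summary` (category counts, percentages, and compound-level counts).
#' @export
reconcile <- function(annotation_table, rbp_by_library) {
  libs <- sort(unique(annotation_table$library))
  if (length(libs) != 2L) stop("reconcile requires annotations from exactly 2 libraries")
  if (!all(libs %in% names(rbp_by_library))) {
    stop("rbp_by_library must name both libraries: ", paste(libs, collapse = ", "))
  }
  a <- annotation_table[annotation_table$library == libs[1L], , drop = FALSE]
  b <- annotation_table[annotation_table$library == libs[2L], , drop = FALSE]
  ids <- sort(unique(annotation_table$group_id))
  a <- a[match(ids, a$group_id), , drop = FALSE]
  b <- b[match(ids, b$group_id), , drop = FALSE]
  pass <- function(x, lib) !is.na(x$compound) & !is.na(x$score) &
    x$score >= rbp_by_library[[lib]]
  ok_a <- pass(a, libs[1L]); ok_b <- pass(b, libs[2L])
  category <- ifelse(ok_a & ok_b, "both",
                     ifelse(ok_a, "only_a", ifelse(ok_b, "only_b", "unannotated")))
  level <- rep(NA_character_, length(ids))
  for (i in which(category == "both")) {
    level[i] <- classify_agreement(a$compound[i], b$compound[i],
                                   a$adduct[i], b$adduct[i])
  }
  features <- data.frame(
    group_id = ids, mz = ifelse(is.na(a$mz), b$mz, a$mz),
    rt = ifelse(is.na(a$rt), b$rt, a$rt),
    compound_a = a$compound, score_a = a$score, adduct_a = a$adduct,
    compound_b = b$compound, score_b = b$score, adduct_b = b$adduct,
    category = category, agreement_level = level, stringsAsFactors = FALSE)
  names(features) <- sub("_a$", paste0("_", make.names(libs[1L])), names(features))
  names(features) <- sub("_b$", paste0("_", make.names(libs[2L])), names(features))
  summary <- reconcile_summary(features, category, level, a, b, libs)
  list(features = features, summary = summary)
}

compound_key <- function(name) {
  ann <- parse_lipid_name(name)
  if (!is.null(ann$chains)) {
    paste(ann$lipid_class,
          paste(sprintf("%s%d:%d", ann$chains$prefix, ann$chains$carbons,
                        ann$chains$double_bonds), collapse = "/"))
  } else if (ann$parsed) {
    paste(ann$lipid_class,
          sprintf("%d:%d", ann$summed_carbons, ann$summed_double_bonds))
  } else name
}

reconcile_summary <- function(features, category, level, a, b, libs) {
  n <- length(category)
  rows <- list()
  add <- function(label, sel, compounds) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = label, n_features = sum(sel),
      pct_features = round(100 * sum(sel) / n, 1),
      n_compounds = length(unique(compounds)), stringsAsFactors = FALSE)
  }
  both_compounds <- function(sel) {
    vapply(a$compound[sel], compound_key, character(1), USE.NAMES = FALSE)
  }
  for (lv in rev(AGREEMENT_LEVELS)) {
    sel <- category == "both" & !is.na(level) & level == lv
    add(paste0("both_", lv), sel, both_compounds(sel))
  }
  sel_a <- category == "only_a"
  add(paste0("only_", libs[1L]), sel_a,
      vapply(a$compound[sel_a], compound_key, character(1), USE.NAMES = FALSE))
  sel_b <- category == "only_b"
  add(paste0("only_", libs[2L]), sel_b,
      vapply(b$compound[sel_b], compound_key, character(1), USE.NAMES = FALSE))
  add("unannotated", category == "unannotated", character())
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(category = "all_features", n_features = n,
                               pct_features = 100,
                               n_compounds = NA_integer_,
                               stringsAsFactors = FALSE))
  out
}
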