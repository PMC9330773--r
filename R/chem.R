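# Monoisotopic atomic masses (Da), CODATA/IUPAC-derived, 1e-6 Da precision.
# Single source of truth for all formula arithmetic in the package.
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.007825032,
  N = 14.003074005,
  O = 15.994914620,
  P = 30.973761998,
  S = 31.972071174,
  Na = 22.989769282,
  K = 38.963706487,
  Cl = 34.968852682
)

ELECTRON_MASS <- 0.000548580
PROTON_MASS <- ATOMIC_MASS[["H"]] - ELECTRON_MASS  # 1.007276

#' Parse an elemental formula string
#'
#' Supports plain element/count formulas such as `"C42H82NO8P"`.
#'
#' @param s Formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(s)) {
    stop("cannot parse formula: ", s)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  unknown <- setdiff(el, names(ATOMIC_MASS))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))
}

# formula arithmetic on named integer vectors
formula_add <- function(a, b) {
  el <- union(names(a), names(b))
  out <- stats::setNames(integer(length(el)), el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

formula_subtract <- function(a, b) {
  nb <- stats::setNames(-as.integer(b), names(b))
  out <- formula_add(a, nb)
  if (any(out < 0)) stop("formula subtraction went negative")
  out[out > 0]
}

formula_scale <- function(a, k) stats::setNames(as.integer(a * k), names(a))

#' Monoisotopic mass of a formula
#'
#' @param f Named integer vector from [parse_formula()], or a formula string.
#' @return Monoisotopic mass in Da.
#' @export
formula_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(ATOMIC_MASS[names(f)] * f)
}

#' Render a formula in Hill order
#' @param f Named integer vector of element counts.
#' @return Formula string (C, H, then alphabetical).
#' @export
formula_string <- function(f) {
  f <- f[f > 0]
  el <- names(f)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  paste0(ord, ifelse(f[ord] == 1L, "", f[ord]), collapse = "")
}

# Supported ESI adducts: mass delta added to the neutral monoisotopic mass
# for the singly charged ion (electron mass included).
ADDUCTS <- data.frame(
  adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+",
             "[M-H]-", "[M+FA-H]-", "[M+AcOH-H]-", "[M+Cl]-"),
  polarity = c(1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L),
  delta = c(
    ATOMIC_MASS[["H"]] - ELECTRON_MASS,
    ATOMIC_MASS[["Na"]] - ELECTRON_MASS,
    ATOMIC_MASS[["K"]] - ELECTRON_MASS,
    ATOMIC_MASS[["N"]] + 4 * ATOMIC_MASS[["H"]] - ELECTRON_MASS,
    -(ATOMIC_MASS[["H"]] - ELECTRON_MASS),
    formula_mass("CH2O2") - ATOMIC_MASS[["H"]] + ELECTRON_MASS,
    formula_mass("C2H4O2") - ATOMIC_MASS[["H"]] + ELECTRON_MASS,
    ATOMIC_MASS[["Cl"]] + ELECTRON_MASS),
  stringsAsFactors = FALSE)

#' Adduct mass delta and polarity
#'
#' @param adduct Adduct name, e.g. `"[M+H]+"`.
#' @return List with `delta` (Da added to M for the singly charged ion) and
#'   `polarity` (+1/-1).
#' @export
adduct_info <- function(adduct) {
  i <- match(adduct, ADDUCTS$adduct)
  if (is.na(i)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(ADDUCTS$adduct, collapse = ", "))
  }
  list(delta = ADDUCTS$delta[i], polarity = ADDUCTS$polarity[i])
}

# fatty acyl building blocks for a chain with c carbons, d double bonds
chain_fa_formula <- function(carbons, double_bonds) {
  stats::setNames(as.integer(c(carbons, 2 * carbons - 2 * double_bonds, 2)),
                  c("C", "H", "O"))
}
chain_fa_mass <- function(carbons, double_bonds) {
  # vectorized over chains
  ATOMIC_MASS[["C"]] * carbons +
    ATOMIC_MASS[["H"]] * (2 * carbons - 2 * double_bonds) +
    2 * ATOMIC_MASS[["O"]]
}
# ketene R-CH=C=O (fatty acid minus water), the common ester-cleavage loss
chain_ketene_mass <- function(carbons, double_bonds) {
  chain_fa_mass(carbons, double_bonds) - formula_mass("H2O")
}
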