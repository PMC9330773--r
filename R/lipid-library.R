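#' Load lipid fragmentation rules
#'
#' Class rules (backbone formula, per-adduct fragment templates) live in a
#' plain YAML file so new classes can be added without code changes; the
#' packaged default covers PC, PE, PG, TG, SM and CE. See the packaged file
#' (`system.file("extdata", "lipid_rules.yaml", package = "lcmsmatch")`) for
#' the rule grammar: fragment kinds, the `retains_adduct` flag driving
#' borrowed-template m/z shifts, and the intensity template convention.
#'
#' @param path Optional path to a user rule file; default: packaged rules.
#' @return Named list of class rule definitions.
#' @export
load_lipid_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lipid_rules.yaml", package = "lcmsmatch")
  }
  if (!file.exists(path)) stop("lipid rule file not found: ", path)
  rules <- yaml::read_yaml(path)$classes
  stopifnot(length(rules) > 0L)
  rules
}

#' Enumerate lipid species over a chain-composition range
#'
#' Builds every distinct species of a class from the cross product of chain
#' carbon counts and double-bond counts, de-duplicated at the chain
#' composition level: chains are unordered (sn-position-agnostic), so
#' PC 16:0/18:1 and PC 18:1/16:0 are one species. The species count equals
#' the multiset coefficient `choose(t + n_chains - 1, n_chains)` for t valid
#' chain types. Chain types whose double-bond count is chemically impossible
#' (more than floor(carbons / 2)) are skipped with a warning.
#'
#' @param lipid_class Class name present in the rule set (e.g. `"PC"`).
#' @param carbons Integer vector of chain carbon counts (default even 12-22).
#' @param double_bonds Integer vector of double-bond counts (default 0-6).
#' @param rules Rule set from [load_lipid_rules()].
#' @return List of `lipid_species` objects: class, chains (data.frame
#'   `carbons`, `double_bonds`, sorted), formula (element counts), name,
#'   summed composition.
#' @export
enumerate_species <- function(lipid_class, carbons = seq(12L, 22L, 2L),
                              double_bonds = 0:6,
                              rules = load_lipid_rules()) {
  cls <- rules[[lipid_class]]
  if (is.null(cls)) stop("no rules for lipid class '", lipid_class, "'")
  stopifnot(length(carbons) > 0L, length(double_bonds) > 0L)
  grid <- expand.grid(carbons = as.integer(carbons),
                      double_bonds = as.integer(double_bonds))
  bad <- grid$double_bonds > grid$carbons %/% 2L
  if (any(bad)) {
    warning(sum(bad), " impossible chain type(s) skipped for ", lipid_class)
    grid <- grid[!bad, , drop = FALSE]
  }
  grid <- grid[order(grid$carbons, grid$double_bonds), , drop = FALSE]
  nch <- cls$n_chains
  combos <- multiset_combinations(nrow(grid), nch)
  lapply(seq_len(nrow(combos)), function(i) {
    chains <- grid[combos[i, ], , drop = FALSE]
    rownames(chains) <- NULL
    make_species(lipid_class, chains, cls)
  })
}

# all non-decreasing index tuples of length k from 1..t (multisets)
multiset_combinations <- function(t, k) {
  if (k == 1L) return(matrix(seq_len(t), ncol = 1L))
  g <- do.call(expand.grid, rep(list(seq_len(t)), k))
  keep <- rowSums(g[, -1L, drop = FALSE] >= g[, -k, drop = FALSE]) == k - 1L
  m <- as.matrix(g[keep, , drop = FALSE])
  dimnames(m) <- NULL
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

make_species <- function(lipid_class, chains, cls) {
  backbone <- parse_formula(cls$backbone)
  f <- backbone
  for (i in seq_len(nrow(chains))) {
    f <- formula_add(f, chain_fa_formula(chains$carbons[i],
                                         chains$double_bonds[i]))
  }
  f <- formula_subtract(f, formula_scale(parse_formula("H2O"), nrow(chains)))
  base <- cls$sphingoid_base
  sum_c <- sum(chains$carbons) + if (is.null(base)) 0L else base$carbons
  sum_d <- sum(chains$double_bonds) + if (is.null(base)) 0L else base$double_bonds
  chain_str <- paste(sprintf("%d:%d", chains$carbons, chains$double_bonds),
                     collapse = "/")
  if (!is.null(base)) {
    chain_str <- paste0(sprintf("d%d:%d", base$carbons, base$double_bonds),
                        "/", chain_str)
  }
  structure(list(lipid_class = lipid_class, chains = chains, formula = f,
                 name = paste(lipid_class, chain_str),
                 summed_carbons = sum_c, summed_double_bonds = sum_d),
            class = "lipid_species")
}

#' Predict the fragmentation spectrum of a lipid species
#'
#' Evaluates the class's fragment rules for the given adduct: the precursor
#' m/z is (monoisotopic species mass + adduct delta) for the singly charged
#' ion, fragment m/z values come from the rule kinds (fixed product ions,
#' fixed neutral losses, per-chain acyl losses and carboxylates), and
#' intensities come from the class template. The spectrum is normalized to
#' base peak 100 and peaks below 0.2% of the base peak (i.e. < 0.2) are
#' removed. Adducts declared `template: borrow` reuse the donor adduct's
#' fragment list, shifting charge-carrier-retaining fragments by the
#' difference of the two adduct mass deltas.
#'
#' @param species A `lipid_species` from [enumerate_species()].
#' @param adduct Adduct name, e.g. `"[M+H]+"`.
#' @param rules Rule set from [load_lipid_rules()].
#' @param intensity_cutoff Relative cutoff on the 0-100 scale (default 0.2,
#'   i.e. 0.2% of the base peak).
#' @return A [library_entry()] with class, summed composition, chain
#'   composition and adduct in its metadata.
#' @export
fragment_spectrum <- function(species, adduct, rules = load_lipid_rules(),
                              intensity_cutoff = 0.2) {
  stopifnot(inherits(species, "lipid_species"))
  cls <- rules[[species$lipid_class]]
  if (is.null(cls)) stop("no rules for lipid class '", species$lipid_class, "'")
  ad <- cls$adducts[[adduct]]
  if (is.null(ad)) {
    stop("class ", species$lipid_class, " has no fragmentation template for ",
         adduct)
  }
  info <- adduct_info(adduct)
  shift <- 0
  if (identical(ad$template, "borrow")) {
    donor <- cls$adducts[[ad$from]]
    if (is.null(donor) || !identical(donor$template, "own")) {
      stop("borrowed template for ", adduct, " references missing/borrowed donor ",
           ad$from)
    }
    shift <- info$delta - adduct_info(ad$from)$delta
    ad <- donor
  }
  mass <- formula_mass(species$formula)
  precursor <- mass + info$delta
  mz <- numeric(); intensity <- numeric()
  emit <- function(x, frag_int) {
    mz <<- c(mz, x)
    intensity <<- c(intensity, rep(frag_int, length(x)))
  }
  for (fr in ad$fragments) {
    frag_shift <- if (isTRUE(fr$retains_adduct)) shift else 0
    val <- if (isTRUE(cls$mass_only) || isTRUE(ad$mass_only)) 100 else fr$intensity
    switch(fr$kind,
      precursor = emit(precursor, val),
      ion_formula = emit(formula_mass(fr$formula) -
                           info$polarity * ELECTRON_MASS + frag_shift, val),
      nl_formula = emit(precursor - formula_mass(fr$formula), val),
      nl_chain_fa = emit(precursor - chain_fa_mass(species$chains$carbons,
                                                   species$chains$double_bonds),
                         val),
      nl_chain_ketene = emit(precursor -
                               chain_ketene_mass(species$chains$carbons,
                                                 species$chains$double_bonds),
                             val),
      chain_fa_anion = emit(chain_fa_mass(species$chains$carbons,
                                          species$chains$double_bonds) -
                              PROTON_MASS + frag_shift, val),
      stop("unknown fragment rule kind: ", fr$kind))
  }
  if (any(mz > precursor + 1e-6)) {
    stop("rule produced a fragment above the precursor m/z for ", species$name)
  }
  sp <- normalize_spectrum(spectrum(mz, intensity))
  keep <- sp$intensity >= intensity_cutoff
  sp <- spectrum(sp$mz[keep], sp$intensity[keep], sort = FALSE)
  library_entry(
    species$name, precursor, adduct = adduct, polarity = info$polarity,
    spectrum = sp, formula = formula_string(species$formula),
    metadata = list(
      class = species$lipid_class,
      summed_composition = sprintf("%d:%d", species$summed_carbons,
                                   species$summed_double_bonds),
      chain_composition = sub("^[A-Za-z0-9]+ ", "", species$name),
      adduct = adduct))
}

#' Build an in-silico lipid fragmentation library
#'
#' Enumerates species for each requested class over the chain space and
#' emits one entry per species x supported adduct, in deterministic
#' (class, species name, adduct) order. Optionally writes the library as an
#' msp file parseable by [read_msp()].
#'
#' @param classes Character vector of class names (default: all classes in
#'   the rule set).
#' @param carbons,double_bonds Chain space (defaults: even 12-22, 0-6).
#' @param adducts Optional character vector restricting adduct forms; default
#'   all adducts declared for each class.
#' @param rules Rule set from [load_lipid_rules()].
#' @param msp_path Optional output msp path.
#' @param name Library name (default "insilico-lipids").
#' @return A [spectral_library()].
#' @examples
#' lib <- build_lipid_library("CE", carbons = c(16L, 18L), double_bonds = 0:1)
#' library_size(lib)
#' @export
build_lipid_library <- function(classes = NULL, carbons = seq(12L, 22L, 2L),
                                double_bonds = 0:6, adducts = NULL,
                                rules = load_lipid_rules(), msp_path = NULL,
                                name = "insilico-lipids") {
  if (is.null(classes)) classes <- names(rules)
  entries <- list()
  for (cl in classes) {
    if (is.null(rules[[cl]])) stop("no rules for lipid class '", cl, "'")
    cl_adducts <- names(rules[[cl]]$adducts)
    if (!is.null(adducts)) cl_adducts <- intersect(cl_adducts, adducts)
    species <- enumerate_species(cl, carbons, double_bonds, rules)
    species <- species[order(vapply(species, `[[`, character(1), "name"))]
    for (sp in species) {
      for (ad in sort(cl_adducts)) {
        entries[[length(entries) + 1L]] <- fragment_spectrum(sp, ad, rules)
      }
    }
  }
  lib <- spectral_library(entries, name = name)
  if (!is.null(msp_path)) write_msp(lib, msp_path)
  lib
}
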