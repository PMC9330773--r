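# Independent oracles and small fixture builders shared across tests.

# Exact big-integer oracle for the hypergeometric score: binomials as exact
# Python integers (math.comb), the log taken last. Independent of the
# package's lchoose-based path.
exact_hgs_oracle <- function(k, m, n, N) {
  stopifnot(length(k) == length(m), length(m) == length(n))
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".txt")
  utils::write.csv(data.frame(k = k, m = m, n = n, N = N), infile,
                   row.names = FALSE)
  code <- paste(
    "import sys, csv, math",
    "from fractions import Fraction",
    "rows = list(csv.DictReader(open(sys.argv[1])))",
    "with open(sys.argv[2], 'w') as out:",
    "    for r in rows:",
    "        k, m, n, N = (int(float(r[c])) for c in 'kmnN')",
    "        p = Fraction(math.comb(m, k) * math.comb(N - m, n - k),",
    "                     math.comb(N, n))",
    "        # exact rational, log taken last (log1p keeps precision at p ~ 1)",
    "        if p > Fraction(1, 2):",
    "            s = -math.log1p(float(p - 1))",
    "        else:",
    "            s = -math.log(float(p))",
    "        out.write(repr(s) + '\\n')",
    sep = "\n")
  status <- system2("python", c("-c", shQuote(code), infile, outfile))
  stopifnot(status == 0L)
  as.numeric(readLines(outfile))
}

# Fixed-point union oracle for slice merging: repeatedly find ANY pair
# overlapping in both axes (closed intervals), replace it by the
# coordinate-wise union, until stable. Defines correctness for merge_slices.
merge_slices_oracle <- function(s) {
  s <- s[, c("mz_min", "mz_max", "rt_min", "rt_max")]
  repeat {
    n <- nrow(s)
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      hit <- which(s$mz_min[rest] <= s$mz_max[i] & s$mz_max[rest] >= s$mz_min[i] &
                     s$rt_min[rest] <= s$rt_max[i] & s$rt_max[rest] >= s$rt_min[i])
      if (length(hit)) {
        j <- rest[hit[1L]]
        s$mz_min[i] <- min(s$mz_min[i], s$mz_min[j])
        s$mz_max[i] <- max(s$mz_max[i], s$mz_max[j])
        s$rt_min[i] <- min(s$rt_min[i], s$rt_min[j])
        s$rt_max[i] <- max(s$rt_max[i], s$rt_max[j])
        s <- s[-j, , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(s) <- NULL
  s[order(s$mz_min, s$rt_min), , drop = FALSE]
}

# random slice set with a controlled overlap rate (dense enough that a few
# hundred merges happen at n = 1000, including multi-slice chains)
random_slices <- function(n, seed = 1L) {
  set.seed(seed)
  mz_min <- runif(n, 100, 120)
  rt_min <- runif(n, 0, 10)
  df <- data.frame(mz_min = mz_min, mz_max = mz_min + runif(n, 0.005, 0.05),
                   rt_min = rt_min, rt_max = rt_min + runif(n, 0.2, 1.2))
  df$seeds <- lapply(seq_len(n), function(i)
    data.frame(sample_id = "S1", scan_id = i, rt = df$rt_min[i] + 0.1,
               precursor_mz = df$mz_min[i] + 0.001))
  df
}

slice_bounds <- function(s) {
  b <- s[, c("mz_min", "mz_max", "rt_min", "rt_max")]
  b <- b[order(b$mz_min, b$rt_min), , drop = FALSE]
  rownames(b) <- NULL
  b
}

# brute-force RBP sweep on a dense grid of candidate thresholds
rbp_sweep_oracle <- function(agree, disagree, extra_grid = TRUE) {
  cand <- sort(unique(c(agree, disagree)))
  if (extra_grid) {
    cand <- sort(unique(c(cand, seq(min(cand), max(cand), length.out = 501))))
  }
  obj <- vapply(cand, function(t) mean(agree >= t) - mean(disagree >= t),
                numeric(1))
  list(threshold = cand[which.max(obj)], objective = max(obj))
}

# deterministic toy spectra
toy_spectrum <- function(mz, intensity = rep(100, length(mz))) {
  spectrum(mz, intensity)
}

# a tiny two-record msp text fixture
write_msp_fixture <- function(path) {
  writeLines(c(
    "Name: Alanine",
    "PrecursorMZ: 90.054950",
    "Adduct: [M+H]+",
    "Comment: class=amino acid; origin=fixture",
    "Num Peaks: 3",
    "44.049480 100.0",
    "62.060040 35.5",
    "90.054950 12.1",
    "",
    "Name: Citrate",
    "PRECURSORMZ: 191.019727",
    "Ion_mode: Negative",
    "Num Peaks: 2",
    "87.008770\t55.0",
    "111.008770;100.0",
    ""), path)
  path
}

# small deterministic library for pipeline tests
small_lipid_library <- function() {
  build_lipid_library(c("PC", "PE", "TG"), carbons = seq(14L, 18L, 2L),
                      double_bonds = 0:2)
}
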