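#' Match fragments between an observed and a reference spectrum
#'
#' Deterministic greedy one-to-one matching: reference fragments are
#' processed in descending intensity order (ties toward lower m/z) and each
#' claims the nearest still-unmatched observed fragment within `tol_ppm` of
#' the reference m/z; distance ties also resolve to the lower observed m/z.
#' One-to-one matching is what makes the matched-fragment count k in the
#' hypergeometric model well defined.
#'
#' @param observed,reference [spectrum()] objects, sorted by m/z.
#' @param tol_ppm Match tolerance in ppm of the reference fragment m/z.
#' @return A `fragment_match_set`: list with `k` (matches), `m` (observed
#'   fragment count), `n` (reference fragment count), `pairs` (data.frame
#'   `obs_index`, `ref_index`, `ppm_error`), `matched_ref_intensity_sum`,
#'   `total_ref_intensity_sum`.
#' @export
match_fragments <- function(observed, reference, tol_ppm = 20) {
  stopifnot(is_spectrum(observed), is_spectrum(reference), tol_ppm > 0)
  m <- n_peaks(observed)
  n <- n_peaks(reference)
  pairs <- data.frame(obs_index = integer(), ref_index = integer(),
                      ppm_error = numeric())
  taken <- logical(m)
  if (m > 0L && n > 0L) {
    for (r in order(-reference$intensity, reference$mz)) {
      rmz <- reference$mz[r]
      tol <- rmz * tol_ppm * 1e-6
      cand <- which(!taken & abs(observed$mz - rmz) <= tol)
      if (!length(cand)) next
      d <- abs(observed$mz[cand] - rmz)
      best <- cand[order(d, observed$mz[cand])][1L]
      taken[best] <- TRUE
      pairs <- rbind(pairs, data.frame(
        obs_index = best, ref_index = r,
        ppm_error = (observed$mz[best] - rmz) / rmz * 1e6))
    }
  }
  structure(list(
    k = nrow(pairs), m = m, n = n, pairs = pairs,
    matched_ref_intensity_sum = sum(reference$intensity[pairs$ref_index]),
    total_ref_intensity_sum = sum(reference$intensity)),
    class = "fragment_match_set")
}

#' Hypergeometric spectral match score
#'
#' Models spectral matching as drawing the n reference fragments from N
#' non-overlapping m/z buckets of which m are occupied by observed fragments:
#' the probability of seeing k matches by chance is
#' \deqn{P = \frac{{m \choose k}{N-m \choose n-k}}{{N \choose n}}}
#' and the score is \eqn{-\ln P}, in natural-log units, non-negative for all
#' valid tuples. Computed through log-binomials (`lchoose`), never raw
#' factorials, so it is finite and accurate for N up to 1e7 and beyond.
#'
#' The score uses no fragment intensities, which makes it usable with
#' intensity-free in-silico libraries and robust to chimeric spectra:
#' unmatched contaminant fragments enter only through m.
#'
#' N is tied to instrument resolving power — it should be large enough that
#' two fragments that ought to match land in one bucket; for high-resolution
#' data (>50,000 RP) use on the order of 1e5 or more (the default).
#'
#' @param k Matched fragment count.
#' @param m Observed-spectrum fragment count.
#' @param n Reference-spectrum fragment count.
#' @param N Bucket count (default 1e5).
#' @return Non-negative score (vectorised over its arguments).
#' @examples
#' hypergeometric_score(10, 10, 10, 10)   # perfect saturated match: 0
#' hypergeometric_score(5, 10, 10, 1e5)
#' @export
hypergeometric_score <- function(k, m, n, N = 1e5) {
  k <- as.numeric(k); m <- as.numeric(m); n <- as.numeric(n); N <- as.numeric(N)
  bad <- k < 0 | k > pmin(m, n) | m > N | n > N | (n - k) > (N - m)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("invalid hypergeometric tuple (k=%g, m=%g, n=%g, N=%g)",
                 k[i], m[i], n[i], N[i]))
  }
  mapply(hgs_one, k, m, n, N, USE.NAMES = FALSE)
}

# ln P rewritten as a product of bounded ratios,
#   P = C(m,k) * prod_i (n-i)/(N-(m-k)-i) * prod_l (N-n-l)/(N-l),
# so near-zero scores (P ~ 1) keep full relative precision via log1p
# instead of cancelling two ~lchoose(N,n)-sized logs.
hgs_one <- function(k, m, n, N) {
  lp <- lchoose(m, k)
  if (k > 0) {
    i <- 0:(k - 1)
    lp <- lp + sum(log((n - i) / (N - (m - k) - i)))
  }
  if (m - k > 0) {
    l <- 0:(m - k - 1)
    lp <- lp + sum(log1p(-n / (N - l)))
  }
  if (lp >= 0) 0 else -lp
}

#' Multivariate (intensity-class weighted) hypergeometric score
#'
#' Extends the hypergeometric score by splitting the reference fragments
#' into `n_classes` intensity classes (by intensity rank: top third, middle
#' third, bottom third for the default 3) and scoring the per-class match
#' counts jointly: with class sizes \eqn{n_c}, per-class matches \eqn{k_c},
#' m observed fragments and N buckets,
#' \deqn{P = \frac{\prod_c {n_c \choose k_c} \; {N - n \choose m - k}}{{N \choose m}}}
#' and the score is \eqn{-\ln P}. Matching an intense reference fragment is
#' thus rewarded more than matching a weak one. With a single class this
#' reduces exactly to [hypergeometric_score()] (by the symmetry of the
#' hypergeometric probability in the roles of m and n).
#'
#' @param observed,reference Non-empty [spectrum()] objects.
#' @param tol_ppm Fragment match tolerance in ppm.
#' @param N Bucket count (default 1e5).
#' @param n_classes Number of intensity classes (default 3).
#' @return Non-negative score.
#' @export
mvh_score <- function(observed, reference, tol_ppm = 20, N = 1e5,
                      n_classes = 3L) {
  stopifnot(n_peaks(observed) > 0L, n_peaks(reference) > 0L, n_classes >= 1L)
  ms <- match_fragments(observed, reference, tol_ppm)
  cls <- intensity_classes(reference$intensity, n_classes)
  n_c <- tabulate(cls, nbins = n_classes)
  k_c <- tabulate(cls[ms$pairs$ref_index], nbins = n_classes)
  mvh_from_counts(k_c, n_c, ms$m, N)
}

# per-class log multivariate hypergeometric, shared by mvh_score and tests
mvh_from_counts <- function(k_c, n_c, m, N) {
  k <- sum(k_c); n <- sum(n_c)
  if (m > N || n > N || (m - k) > (N - n) || any(k_c > n_c) || any(k_c < 0)) {
    stop(sprintf("invalid MVH tuple (k=%d, m=%d, n=%d, N=%g)", k, m, n, N))
  }
  logp <- sum(lchoose(n_c, k_c)) + lchoose(N - n, m - k) - lchoose(N, m)
  max(-logp, 0)
}

# rank-based classes: class 1 = most intense ceil(n/len) ... last = weakest
intensity_classes <- function(intensity, n_classes) {
  n <- length(intensity)
  n_classes <- min(n_classes, n)
  rk <- rank(-intensity, ties.method = "first")
  as.integer(ceiling(rk * n_classes / n))
}

#' Cosine (dot product) spectral similarity
#'
#' Cosine of the intensity-power-weighted spectra over the union of matched
#' and unmatched fragment slots: matched pairs contribute to the inner
#' product, every fragment contributes to its spectrum's norm. The default
#' power 0.5 (square-root weighting) is common practice; 1.0 recovers the
#' plain cosine. Symmetric in its arguments up to the asymmetry of greedy
#' matching; bounded in [0, 1].
#'
#' @param observed,reference [spectrum()] objects.
#' @param tol_ppm Fragment match tolerance in ppm.
#' @param intensity_power Exponent applied to intensities before the cosine
#'   (default 0.5).
#' @return Similarity in [0, 1]; 0 when either spectrum has zero norm.
#' @export
dot_product <- function(observed, reference, tol_ppm = 20,
                        intensity_power = 0.5) {
  ms <- match_fragments(observed, reference, tol_ppm)
  wo <- observed$intensity^intensity_power
  wr <- reference$intensity^intensity_power
  denom <- sqrt(sum(wo^2)) * sqrt(sum(wr^2))
  if (denom == 0) return(0)
  num <- sum(wo[ms$pairs$obs_index] * wr[ms$pairs$ref_index])
  min(num / denom, 1)
}

#' Fraction of reference fragments matched
#'
#' @param match_set A `fragment_match_set` from [match_fragments()].
#' @return k / n in [0, 1].
#' @export
fraction_ref_matched <- function(match_set) {
  stopifnot(inherits(match_set, "fragment_match_set"))
  if (match_set$n == 0L) stop("empty reference spectrum: fraction undefined")
  match_set$k / match_set$n
}

#' Fraction of reference TIC matched
#'
#' @param match_set A `fragment_match_set` from [match_fragments()].
#' @return Matched reference intensity / total reference intensity, in [0, 1].
#' @export
tic_fraction_matched <- function(match_set) {
  stopifnot(inherits(match_set, "fragment_match_set"))
  if (match_set$total_ref_intensity_sum <= 0) {
    stop("reference spectrum has zero total intensity: TIC fraction undefined")
  }
  match_set$matched_ref_intensity_sum / match_set$total_ref_intensity_sum
}

#' Score one observed spectrum against one reference spectrum
#'
#' Dispatcher used by the library search: computes the requested similarity
#' score plus the (k, m, n) matching summary.
#'
#' @param observed,reference [spectrum()] objects.
#' @param score_type One of `"hgs"`, `"mvh"`, `"dot"`, `"frac_matched"`,
#'   `"tic_fraction"`.
#' @param tol_ppm Fragment tolerance in ppm.
#' @param N Bucket count for the hypergeometric scores.
#' @param intensity_power Weighting exponent for `"dot"`.
#' @return List with `score`, `k`, `m`, `n`.
#' @export
score_spectra <- function(observed, reference,
                          score_type = c("hgs", "mvh", "dot", "frac_matched",
                                         "tic_fraction"),
                          tol_ppm = 20, N = 1e5, intensity_power = 0.5) {
  score_type <- match.arg(score_type)
  ms <- match_fragments(observed, reference, tol_ppm)
  score <- switch(score_type,
    hgs = hypergeometric_score(ms$k, ms$m, ms$n, N),
    mvh = mvh_score(observed, reference, tol_ppm, N),
    dot = dot_product(observed, reference, tol_ppm, intensity_power),
    frac_matched = fraction_ref_matched(ms),
    tic_fraction = tic_fraction_matched(ms))
  list(score = score, k = ms$k, m = ms$m, n = ms$n)
}
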