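# build a minimal one-sample run with Gaussian peaks planted directly
planted_scans <- function(compounds, rt_grid = seq(0, 20, 1 / 60),
                          sigma = 0.05) {
  scans <- list()
  id <- 0L
  for (rt in rt_grid) {
    mz <- numeric(); intensity <- numeric()
    for (cp in compounds) {
      h <- cp$height * exp(-0.5 * ((rt - cp$rt) / sigma)^2)
      if (h > 1) {
        mz <- c(mz, cp$mz)
        intensity <- c(intensity, h)
      }
    }
    id <- id + 1L
    scans[[id]] <- ms_scan(id, 1L, rt, spectrum = spectrum(mz, intensity))
  }
  scans
}

gauss_slice <- function(mz, rt, mz_half = 0.01, rt_half = 1) {
  data.frame(mz_min = mz - mz_half, mz_max = mz + mz_half,
             rt_min = rt - rt_half, rt_max = rt + rt_half,
             seeds = I(list(data.frame(sample_id = "S1", scan_id = 1L,
                                       rt = rt, precursor_mz = mz))))
}

test_that("extract_eics recovers a planted Gaussian apex within 1%", {
  cp <- list(list(mz = 500.0, rt = 10.0, height = 1e6))
  scans <- list(S1 = planted_scans(cp))
  slice <- gauss_slice(500.0, 10.0)
  eics <- extract_eics(slice, scans)
  e <- eics$S1
  expect_gt(nrow(e), 50)
  expect_false(is.unsorted(e$rt))
  apex <- e$intensity[which.min(abs(e$rt - 10.0))]
  expect_equal(apex, 1e6, tolerance = 0.01)
  # direct evaluation of the planted Gaussian at the apex scan time
  expect_equal(apex, 1e6 * exp(-0.5 * ((e$rt[which.min(abs(e$rt - 10))] - 10) / 0.05)^2),
               tolerance = 1e-9)
})

test_that("a slice with no signal yields an all-zero EIC", {
  scans <- list(S1 = planted_scans(list(list(mz = 500, rt = 10, height = 1e6))))
  eics <- extract_eics(gauss_slice(800.0, 10.0), scans)
  expect_true(all(eics$S1$intensity == 0))
})

test_that("two centroids inside the window sum at that scan", {
  sp <- spectrum(c(499.995, 500.005), c(100, 200))
  scans <- list(S1 = list(ms_scan(1L, 1L, 10.0, spectrum = sp)))
  eics <- extract_eics(gauss_slice(500.0, 10.0), scans)
  expect_equal(eics$S1$intensity, 300)
})

test_that("merge_eics sums on the union grid without interpolation", {
  e1 <- data.frame(rt = c(1, 2, 3), intensity = c(10, 20, 30))
  expect_equal(merge_eics(list(e1)), e1)                  # identity
  doubled <- merge_eics(list(e1, e1))
  expect_equal(doubled$intensity, c(20, 40, 60))          # identical -> doubled
  e2 <- data.frame(rt = c(1.5, 2.5), intensity = c(5, 7))
  m <- merge_eics(list(e1, e2))
  expect_equal(m$rt, c(1, 1.5, 2, 2.5, 3))                # union grid
  expect_equal(m$intensity, c(10, 5, 20, 7, 30))          # no interpolation
})

test_that("detect_peaks finds planted Gaussians and respects boundaries", {
  rt <- seq(0, 20, 1 / 60)
  one <- data.frame(rt = rt, intensity = 1e6 * exp(-0.5 * ((rt - 10) / 0.05)^2))
  p1 <- detect_peaks(one, 5L, 1e4)
  expect_equal(nrow(p1), 1L)
  expect_lt(abs(p1$rt_apex - 10.0), 1 / 60 + 1e-9)  # within one scan interval
  expect_true(p1$rt_start <= p1$rt_apex && p1$rt_apex <= p1$rt_end)
  expect_gt(p1$height, 0)
  # two Gaussians > 4 sigma apart -> two peaks with a boundary between
  two <- data.frame(rt = rt, intensity =
    1e6 * exp(-0.5 * ((rt - 9.0) / 0.05)^2) +
    8e5 * exp(-0.5 * ((rt - 9.5) / 0.05)^2))
  p2 <- detect_peaks(two, 5L, 1e4)
  expect_equal(nrow(p2), 2L)
  expect_lt(abs(p2$rt_apex[1L] - 9.0), 1 / 60 + 1e-9)
  expect_lt(abs(p2$rt_apex[2L] - 9.5), 1 / 60 + 1e-9)
  expect_true(p2$rt_end[1L] <= p2$rt_start[2L] + 1e-9)
  # degenerate traces
  expect_equal(nrow(detect_peaks(data.frame(rt = rt, intensity = 0), 5L, 0)), 0L)
  expect_error(detect_peaks(one[1:3, ], 5L, 0), "longer than")
  expect_error(detect_peaks(one, 4L, 0))  # even window
})

test_that("form_peak_groups groups the same compound across samples", {
  mk <- function(rt0) planted_scans(list(list(mz = 500, rt = rt0, height = 1e6)))
  scans <- list(S1 = mk(9.95), S2 = mk(10.0), S3 = mk(10.05))
  slice <- gauss_slice(500, 10)
  groups <- form_peak_groups(slice, extract_eics(slice, scans))
  expect_length(groups, 1L)
  expect_equal(sort(groups[[1L]]$peaks$sample_id), c("S1", "S2", "S3"))
  # every member peak's RT range intersects the group window
  with(groups[[1L]], expect_true(all(peaks$rt_start <= rt_end &
                                     peaks$rt_end >= rt_start)))
})

test_that("same m/z at different RTs in different samples gives two groups", {
  scans <- list(S1 = planted_scans(list(list(mz = 500, rt = 5, height = 1e6))),
                S2 = planted_scans(list(list(mz = 500, rt = 15, height = 1e6))))
  slice <- gauss_slice(500, 10, rt_half = 10)
  groups <- form_peak_groups(slice, extract_eics(slice, scans))
  expect_length(groups, 2L)
  expect_equal(vapply(groups, function(g) nrow(g$peaks), integer(1)), c(1L, 1L))
  expect_equal(sort(vapply(groups, `[[`, numeric(1), "rt_apex")), c(5, 15),
               tolerance = 0.05)
  # empty merged EIC
  expect_length(form_peak_groups(slice, list(S1 = data.frame(rt = numeric(),
                                                             intensity = numeric()))),
                0L)
})

test_that("assign_ms2 uses RT proximity with a tolerance and uniqueness", {
  slice <- gauss_slice(500, 10)
  slice$seeds <- list(data.frame(sample_id = "S1", scan_id = 1:3,
                                 rt = c(9.9, 10.1, 12.0), precursor_mz = 500))
  g <- structure(list(slice = slice, rt_apex = 10.0, rt_start = 9.8,
                      rt_end = 10.2, peaks = NULL, ms2_scans = NULL,
                      consensus = NULL), class = "peak_group")
  out <- assign_ms2(list(g), slice, rt_tolerance_min = 0.5)
  expect_equal(sort(out[[1L]]$ms2_scans$scan_id), 1:2)  # 12.0 is out of window
  # nearest-group rule between two candidate groups
  g2 <- g; g2$rt_apex <- 10.4
  slice$seeds <- list(data.frame(sample_id = "S1", scan_id = 1L, rt = 10.19,
                                 precursor_mz = 500))
  out2 <- assign_ms2(list(g, g2), slice, rt_tolerance_min = 0.5)
  expect_equal(nrow(out2[[1L]]$ms2_scans), 1L)
  # scan assigned to exactly one group: conservation
  expect_equal(nrow(out2[[1L]]$ms2_scans) +
                 if (length(out2) > 1L) nrow(out2[[2L]]$ms2_scans) else 0L, 1L)
})

test_that("consensus of identical spectra is that spectrum, for any n", {
  sp <- spectrum(c(100.0, 250.5, 399.9), c(10, 100, 50))
  expect_equal(build_consensus(list(sp)), sp)
  for (n in c(2L, 5L, 9L)) {
    cons <- build_consensus(rep(list(sp), n))
    expect_equal(cons$mz, sp$mz, tolerance = 1e-12)
    expect_equal(cons$intensity, sp$intensity, tolerance = 1e-12)
  }
})

test_that("close fragments merge at the intensity-weighted mean m/z", {
  s1 <- spectrum(100.0000, 100)
  s2 <- spectrum(100.0005, 100)
  cons <- build_consensus(list(s1, s2), fragment_tol_ppm = 20)
  expect_equal(n_peaks(cons), 1L)
  expect_equal(cons$mz, 100.00025, tolerance = 1e-9)
  # presence filtering: fragment in 1 of 3 scans dropped at threshold 0.5
  s3 <- spectrum(c(100.0, 300.0), c(100, 40))
  cons2 <- build_consensus(list(s1, s2, s3), 20, min_presence_fraction = 0.5)
  expect_equal(n_peaks(cons2), 1L)
  cons3 <- build_consensus(list(s1, s2, s3), 20, min_presence_fraction = 0)
  expect_equal(n_peaks(cons3), 2L)
  # all-empty input
  expect_equal(n_peaks(build_consensus(list(spectrum(), spectrum()))), 0L)
})

test_that("group_run keeps every group window inside its slice and conserves MS2", {
  lib <- small_lipid_library()
  run <- generate_run(run_config(n_samples = 2L, n_compounds = 10L), lib,
                      seed = 3L)
  groups <- group_run(run$scans_by_sample)
  expect_gt(length(groups), 0L)
  total_seeds <- sum(vapply(run$scans_by_sample, function(ss)
    sum(vapply(ss, function(s) s$ms_level == 2L, logical(1))), integer(1)))
  assigned <- sum(vapply(groups, function(g) nrow(g$ms2_scans), integer(1)))
  expect_lte(assigned, total_seeds)
  keys <- unlist(lapply(groups, function(g)
    paste(g$ms2_scans$sample_id, g$ms2_scans$scan_id)))
  expect_equal(anyDuplicated(keys), 0L)  # each scan in at most one group
  for (g in groups) {
    expect_gte(g$rt_apex, g$slice$rt_min)
    expect_lte(g$rt_apex, g$slice$rt_max)
    expect_gte(nrow(g$ms2_scans), 1L)
    expect_gt(n_peaks(g$consensus), 0L)
  }
})
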