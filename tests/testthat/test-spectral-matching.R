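spec1 <- function(peaks, mz = 1000, z = 1, rt = 10, id = "s1") {
  list(scan_id = id, rt_min = rt, precursor_mz = mz, precursor_z = z,
       peaks = peaks)
}

test_that("precursor filtering deconvolutes charge and is monotone in W", {
  pk <- cbind(mz = c(100, 200), intensity = c(1, 1))
  s_z1 <- spec1(pk, mz = 1008.000, z = 1)
  s_z2 <- spec1(pk, mz = 504.511, z = 2)
  ms18 <- match_settings(precursor_window = 18)
  ms1 <- match_settings(precursor_window = 1)
  expect_length(precursor_filter(list(s_z1), 1000, ms18), 1)
  expect_length(precursor_filter(list(s_z1), 1000, ms1), 0)
  expect_length(precursor_filter(list(s_z2), 1000, ms18), 1)
  # unknown charge: tried at every allowed charge
  s_un <- spec1(pk, mz = 504.511, z = NA)
  ms2 <- match_settings(precursor_window = 18, charges = c(1, 2))
  expect_length(precursor_filter(list(s_un), 1000, ms2), 1)
  # superset property
  w_small <- precursor_filter(list(s_z1, s_z2, s_un), 1000, ms1)
  w_big <- precursor_filter(list(s_z1, s_z2, s_un), 1000, ms18)
  expect_true(all(vapply(w_small, `[[`, "", "scan_id") %in%
                    vapply(w_big, `[[`, "", "scan_id")))
})

test_that("fragment matching is greedy nearest with single use of each peak", {
  s <- spec1(cbind(mz = c(133.06, 200.0), intensity = c(10, 5)))
  fr <- data.frame(mz = c(133.061, 133.071), charge = 1)
  m <- match_fragments(s, fr, match_settings(fragment_tolerance = 0.5))
  expect_equal(nrow(m), 1)
  expect_equal(m$theo_mz, 133.061)  # the nearer theoretical wins the peak
  empty <- spec1(matrix(numeric(), ncol = 2,
                        dimnames = list(NULL, c("mz", "intensity"))))
  expect_equal(nrow(match_fragments(empty, fr, match_settings())), 0)
})

test_that("P1 is the binomial upper tail on matched fragment counts", {
  s <- spec1(cbind(mz = seq(100, 1090, by = 110), intensity = 10))  # 10 peaks
  ms <- match_settings(fragment_tolerance = 0.5)
  # k = 0 scores zero
  expect_equal(unname(score_match(data.frame(peak_row = integer()), 10, s,
                                  ms)["p1"]), 0)
  # n = 10, q = 10 * 2 * 0.5 / 990, k = 3: -10 log10 upper tail
  q <- 10 * 2 * 0.5 / 990
  want <- -10 * log10(pbinom(2, 10, q, lower.tail = FALSE))
  got <- score_match(data.frame(peak_row = 1:3), 10, s, ms)
  expect_equal(unname(got["p1"]), want, tolerance = 1e-9)
  # the spec'd worked example: q = 0.01 gives ~39.4
  expect_equal(-10 * log10(pbinom(2, 10, 0.01, lower.tail = FALSE)), 39.4,
               tolerance = 0.05)
  # monotone in k
  p_prev <- -1
  for (k in 0:6) {
    p <- unname(score_match(data.frame(peak_row = seq_len(k)), 10, s, ms)["p1"])
    expect_gte(p, p_prev)
    p_prev <- p
  }
  # zero-peak spectrum scores (0, 0)
  empty <- spec1(matrix(numeric(), ncol = 2))
  expect_equal(unname(score_match(data.frame(peak_row = integer()), 5, empty,
                                  ms)),
               c(0, 0))
})

test_that("P2 rewards matches on the intensity-carrying half of the peaks", {
  pk <- cbind(mz = seq(100, 1000, length.out = 10),
              intensity = c(rep(100, 5), rep(1, 5)))
  s <- spec1(pk)
  ms <- match_settings()
  hi <- score_match(data.frame(peak_row = 1:3), 10, s, ms)   # top-half peaks
  lo <- score_match(data.frame(peak_row = 8:10), 10, s, ms)  # noise-level
  expect_gt(unname(hi["p2"]), unname(lo["p2"]))
  expect_equal(unname(lo["p2"]), 0)
})

test_that("ranking reports prediction-topped scans and applies cutoffs", {
  matches <- data.frame(
    scan_id = c("s1", "s1", "s2", "s2"), rt_min = c(12.1, 12.1, 13, 13),
    compound_id = c("pred1", "decoy1", "pred1", "decoy1"),
    n_matched = c(5, 1, 1, 4), n_theoretical = 10,
    p1 = c(40, 10, 5, 30), p2 = c(30, 5, 5, 20), stringsAsFactors = FALSE)
  rep <- rank_and_report(matches, "pred1", "decoy1",
                         match_settings(p1_cutoff = 10, p2_cutoff = 10))
  expect_equal(rep$scan_id, "s1")          # s2 topped by a decoy: excluded
  expect_equal(rep$normalized_p1, 40 / 10) # decoy mean 10
  # zero cutoffs report every prediction-topped scan
  rep0 <- rank_and_report(matches, "pred1", "decoy1",
                          match_settings(p1_cutoff = 0.001, p2_cutoff = 0.001))
  expect_equal(nrow(rep0), 1)
  # denominator floors at 1 when decoys score ~0
  m2 <- matches[matches$scan_id == "s1", ]
  m2$p1[2] <- 0; m2$p2[2] <- 0
  repf <- rank_and_report(m2, "pred1", "decoy1", match_settings())
  expect_equal(repf$normalized_p1, repf$p1)
  expect_warning(rank_and_report(matches, "pred1", character(),
                                 match_settings()), "decoy")
})

test_that("discovery chart buckets are half-open 0.25-minute windows", {
  rep <- data.frame(scan_id = c("a", "b", "c"), rt_min = c(12.10, 12.20, 12.25),
                    compound_id = "p", p1 = 1, p2 = 1, n_matched = 1,
                    decoy_mean_p1 = 1, normalized_p1 = c(3, 2, 7),
                    stringsAsFactors = FALSE)
  ch <- build_discovery_chart(rep)
  expect_equal(ch$bucket_start, c(12.00, 12.25))
  expect_equal(ch$summed_normalized_p1, c(5, 7))
  # no mass lost to bucketing
  expect_equal(sum(ch$summed_normalized_p1), sum(rep$normalized_p1))
})

test_that("mzXML and MGF round-trip through the readers", {
  sp <- list(spec1(cbind(mz = c(58.0288, 76.0393), intensity = c(100, 200)),
                   mz = 133.0608, z = 1, rt = 12.0083, id = "rt_scan"))
  f <- withr::local_tempfile(fileext = ".mzXML")
  write_mzxml(sp, f)
  back <- read_spectra(f)
  expect_length(back, 1)
  expect_equal(back[[1]]$precursor_mz, 133.0608, tolerance = 1e-4)
  expect_equal(back[[1]]$rt_min, 12.0083, tolerance = 1e-3)
  expect_equal(back[[1]]$peaks[, "mz"], c(58.0288, 76.0393), tolerance = 1e-3,
               ignore_attr = TRUE)
  g <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, g)
  backg <- read_spectra(g)
  expect_equal(backg[[1]]$peaks[, "mz"], back[[1]]$peaks[, "mz"],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(backg[[1]]$precursor_z, 1L)
  expect_error(read_spectra(withr::local_tempfile()), "no such file")
})
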