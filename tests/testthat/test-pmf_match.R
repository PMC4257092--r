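test_that("read_peaklist handles TSV and MGF dialects", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("1000.0", "842.51"), p)
  pl <- read_peaklist(p)
  expect_equal(pl$mz, c(842.51, 1000.0))  # sorted ascending

  m <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=spot1", "PEPMASS=500",
               "842.51 120.5", "1000.0 33.1", "END IONS"), m)
  pl2 <- read_peaklist(m)
  expect_equal(pl2$mz, c(842.51, 1000.0))
  expect_equal(pl2$intensity, c(120.5, 33.1))

  m2 <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=500", "END IONS"), m2)
  expect_warning(pl3 <- read_peaklist(m2), "no peaks")
  expect_length(pl3$mz, 0L)

  bad <- tempfile()
  writeLines("abc", bad)
  expect_error(read_peaklist(bad), "line 1")
})

test_that("peaklist collapses near-duplicates keeping max intensity", {
  pl <- peaklist("s", c(1000, 1000 + 5e-7, 1200),
                 intensity = c(10, 99, 1))
  expect_length(pl$mz, 2L)
  expect_equal(pl$intensity[1], 99)
  expect_error(peaklist("s", c(-1, 10)), "positive")
  expect_error(peaklist("s", c(NaN, 10)), "positive")
})

test_that("two-point calibration is the affine map through the anchors", {
  pl <- peaklist("s", c(842.00, 1526.50, 2211.00))
  refs <- rbind(c(842.00, 842.51), c(2211.00, 2211.10))
  cal <- calibrate(pl, refs)
  expect_true(cal$calibrated)
  expect_equal(cal$mz[1], 842.51, tolerance = 1e-9)
  expect_equal(cal$mz[3], 2211.10, tolerance = 1e-9)
  # midpoint maps to midpoint; cross-checked against a direct line fit
  expect_equal(cal$mz[2], mean(c(842.51, 2211.10)), tolerance = 1e-9)
  fit <- stats::lm(true ~ obs,
                   data = data.frame(obs = refs[, 1], true = refs[, 2]))
  expect_equal(cal$mz,
               unname(stats::predict(fit, data.frame(obs = pl$mz))),
               tolerance = 1e-9)

  ident <- calibrate(pl, rbind(c(842.51, 842.51), c(2211.10, 2211.10)))
  expect_equal(ident$mz, pl$mz)

  expect_error(calibrate(pl, rbind(c(842, 842.5), c(842, 842.6))),
               "degenerate")
})

test_that("calibration is invertible", {
  pl <- peaklist("s", seq(600, 3500, length.out = 7))
  refs <- rbind(c(842, 842.51), c(2211, 2211.10))
  cal <- calibrate(pl, refs)
  back <- calibrate(cal, refs[, 2:1])
  expect_equal(back$mz, pl$mz, tolerance = 1e-9)
})

test_that("match_peaks applies tolerance and reports error in ppm", {
  fp <- toy_fingerprint(1000.000)
  pl <- peaklist("s", 1000.010, calibrated = TRUE)
  mr <- match_peaks(pl, fp, tol = 50, tol_unit = "PPM")
  expect_equal(mr$matched_count, 1L)
  expect_equal(mr$assignments$error_ppm, 10, tolerance = 1e-6)
  expect_equal(match_peaks(pl, fp, tol = 5, tol_unit = "PPM")$matched_count,
               0L)
  expect_error(match_peaks(pl, fp, tol = 0), "tol")
  expect_error(match_peaks(peaklist("s", 1000), fp, 50), "uncalibrated")
})

test_that("coverage is the union of matched spans over the mature chain", {
  fp <- toy_fingerprint(c(1000, 2000), spans = rbind(c(1, 5), c(3, 10)),
                        protein_len = 20L)
  pl <- peaklist("s", c(1000, 2000), calibrated = TRUE)
  mr <- match_peaks(pl, fp, tol = 0.1, tol_unit = "DA")
  expect_equal(mr$matched_count, 2L)
  expect_equal(mr$coverage_pct, 50)  # union 1..10 of 20
})

test_that("greedy assignment equals the exhaustive optimum on small instances", {
  set.seed(41)
  for (it in 1:150) {
    npep <- sample(3:8, 1); npk <- sample(1:8, 1)
    theo <- sort(runif(npep, 800, 3000))
    peaks <- sort(sample(theo, npk, replace = TRUE) + rnorm(npk, 0, 0.03))
    tol <- 0.05
    mr <- match_peaks(peaklist("s", peaks, calibrated = TRUE),
                      toy_fingerprint(theo), tol, "DA")
    adj <- lapply(peaks, function(m) which(abs(theo - m) <= tol))
    expect_equal(mr$matched_count, oracle_max_matching(adj))
  }
})

test_that("removing a peak never increases matched_count", {
  set.seed(43)
  theo <- sort(runif(12, 600, 3500))
  peaks <- sort(c(theo[1:8] + rnorm(8, 0, 0.02), runif(4, 600, 3500)))
  fp <- toy_fingerprint(theo)
  full <- match_peaks(peaklist("s", peaks, calibrated = TRUE), fp, 0.05, "DA")
  for (drop in seq_along(peaks)) {
    mr <- match_peaks(peaklist("s", peaks[-drop], calibrated = TRUE),
                      fp, 0.05, "DA")
    expect_lte(mr$matched_count, full$matched_count)
  }
  expect_lte(full$matched_count, min(length(peaks), 12L))
})

test_that("identify_spot ranks, accepts and flags mixtures deterministically", {
  set.seed(47)
  cfg <- sim_config(seed = 47, n_proteins = 4, dropout = 0,
                    error_ppm_sd = 0, n_noise_peaks = 0)
  sim <- simulate_proteome(cfg)
  cands <- lapply(sim$proteins, function(r) digest(proteoform(r), cfg$digest))

  # no peaks: nothing accepted
  id0 <- identify_spot(peaklist("e", numeric(0), calibrated = TRUE), cands)
  expect_false(any(vapply(id0$ranked, `[[`, logical(1), "accepted")))
  expect_false(id0$mixture_flag)
  expect_error(identify_spot(peaklist("e", 1, calibrated = TRUE), list()),
               "empty candidate")

  # noiseless single-protein spot: top-1 with every observable residue
  # covered (interior fragments too heavy for the 500-4000 Da window cap
  # the attainable coverage below 100%)
  sp <- simulate_spot(proteoform(sim$proteins[[2]]), cfg, "one", seed = 1)
  id1 <- identify_spot(sp$peaklist, cands)
  expect_equal(id1$ranked[[1]]$fingerprint$form$protein$id, "SYN02")
  pep2 <- cands[[2]]$peptides
  observable <- rep(FALSE, nchar(sim$proteins[[2]]$sequence))
  for (r in seq_len(nrow(pep2))) observable[pep2$start[r]:pep2$end[r]] <- TRUE
  expect_equal(id1$ranked[[1]]$result$coverage_pct,
               100 * mean(observable), tolerance = 1e-9)
  expect_false(id1$mixture_flag)

  # two-protein mixture: both generators accepted and ranked on top,
  # mixture flagged (decoys may pick up a few chance matches)
  sp2 <- simulate_spot(list(proteoform(sim$proteins[[1]]),
                            proteoform(sim$proteins[[3]])), cfg, "mix",
                       seed = 2)
  id2 <- identify_spot(sp2$peaklist, cands)
  expect_true(id2$mixture_flag)
  top2 <- vapply(id2$ranked[1:2],
                 function(r) r$fingerprint$form$protein$id, character(1))
  expect_setequal(top2, c("SYN01", "SYN03"))
  expect_true(all(vapply(id2$ranked[1:2], `[[`, logical(1), "accepted")))

  # determinism of the full ranking
  id2b <- identify_spot(sp2$peaklist, cands)
  expect_identical(identification_table(id2), identification_table(id2b))
})

test_that("ambiguity_scan reports near-isobaric alternatives across candidates", {
  # two candidates sharing one near-isobaric mass pair 0.12 Da apart
  a <- toy_fingerprint(c(1498.7424, 2000.00), spans = rbind(c(16, 28), c(40, 60)))
  b <- toy_fingerprint(c(1498.6227, 3000.00), spans = rbind(c(73, 85), c(61, 80)))
  pl <- peaklist("s", c(1498.74, 2000.00), calibrated = TRUE)
  id <- identify_spot(pl, list(a, b), tol = 0.05, tol_unit = "DA",
                      min_matched = 1L)
  notes <- ambiguity_scan(id, tol = 0.15)
  pair <- notes[notes$alt_start == 73, ]
  expect_equal(nrow(pair), 1L)
  expect_equal(pair$start, 16L)
  expect_equal(pair$delta_da, abs(1498.74 - 1498.6227), tolerance = 1e-6)
  expect_equal(nrow(ambiguity_scan(id, tol = 0.001)), 0L)

  # duplicate candidate sequences: every matched peak yields a note
  a2 <- toy_fingerprint(c(1498.7424, 2000.00),
                        spans = rbind(c(16, 28), c(40, 60)), id = "toy2")
  id_dup <- identify_spot(pl, list(a, a2), tol = 0.05, tol_unit = "DA",
                          min_matched = 1L)
  notes_dup <- ambiguity_scan(id_dup, tol = 0.05)
  expect_equal(nrow(notes_dup), 4L)  # 2 peaks x 2 accepted candidates
})
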