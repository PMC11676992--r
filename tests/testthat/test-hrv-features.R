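test_that("time-domain indices match hand arithmetic", {
  expect_equal(time_domain(c(1000, 1000, 1000)),
               list(rr_mean = 1000, rr_tp = 0))
  expect_equal(time_domain(c(800, 1000, 1200)),
               list(rr_mean = 1000, rr_tp = 40000))
  x <- c(810, 950, 1100, 870, 990)
  td1 <- time_domain(x); td2 <- time_domain(2 * x)
  expect_equal(td2$rr_mean, 2 * td1$rr_mean)
  expect_equal(td2$rr_tp, 4 * td1$rr_tp)
})

test_that("time-domain rejects degenerate input", {
  expect_error(time_domain(numeric(0)), "empty")
  expect_error(time_domain(1000), "at least 2")
  expect_error(time_domain(c(800, -5)), "positive")
})

test_that("a flat series yields no spectral component", {
  sp <- ar_spectrum(rep(900, 300))
  expect_true(nrow(sp) == 0 || all(sp$power <= 1e-6 * 900^2))
})

test_that("AR decomposition recovers the LF and HF centre frequencies", {
  lf <- ar_spectrum(generate_rr_series(rr_gen_params(
    duration_s = 300, mean_rr = 900, lf_amp = 25, hf_amp = 0,
    noise_sd = 5, seed = 11)))
  lf_dom <- lf[lf$band == "LF", ]
  expect_gt(nrow(lf_dom), 0)
  expect_lt(abs(lf_dom$central_freq[which.max(lf_dom$power)] - 0.10), 0.01)

  hf <- ar_spectrum(generate_rr_series(rr_gen_params(
    duration_s = 300, mean_rr = 900, lf_amp = 0, hf_amp = 20,
    noise_sd = 5, seed = 12)))
  hf_dom <- hf[hf$band == "HF", ]
  expect_gt(nrow(hf_dom), 0)
  expect_lt(abs(hf_dom$central_freq[which.max(hf_dom$power)] - 0.25), 0.01)
})

test_that("equal-amplitude rhythms split power nearly equally", {
  sp <- ar_spectrum(generate_rr_series(rr_gen_params(
    duration_s = 600, mean_rr = 900, lf_amp = 25, hf_amp = 25,
    noise_sd = 2, seed = 13)))
  lf_a <- sum(sp$power[sp$band == "LF"])
  hf_a <- sum(sp$power[sp$band == "HF"])
  expect_lt(abs(lf_a - hf_a) / max(lf_a, hf_a), 0.15)
})

test_that("median frequency recovery error stays below 0.01 Hz", {
  errs <- unlist(lapply(1:50, function(s) {
    sp <- ar_spectrum(generate_rr_series(rr_gen_params(
      duration_s = 300, mean_rr = 900, lf_amp = 25, hf_amp = 20,
      noise_sd = 5, seed = 100 + s)))
    lf <- sp[sp$band == "LF", ]
    hf <- sp[sp$band == "HF", ]
    c(abs(lf$central_freq[which.max(lf$power)] - 0.10),
      abs(hf$central_freq[which.max(hf$power)] - 0.25))
  }))
  expect_lt(stats::median(errs), 0.01)
})

test_that("component powers conserve the modelled variance", {
  rr <- generate_rr_series(rr_gen_params(duration_s = 300, seed = 14))
  sp <- ar_spectrum(rr, order = 12, fs = 4)
  # independent recomputation of the detrended resampled-signal variance
  beat_t <- cumsum(rr$intervals) / 1000
  grid_t <- seq(beat_t[1], beat_t[length(beat_t)], by = 1 / 4)
  y <- stats::splinefun(beat_t, rr$intervals, method = "natural")(grid_t)
  y <- stats::residuals(stats::lm(y ~ grid_t))
  expect_equal(sum(sp$power), stats::var(y), tolerance = 0.10)
})

test_that("a level shift moves the mean but not the spectrum", {
  p <- rr_gen_params(duration_s = 300, mean_rr = 850, lf_amp = 25,
                     hf_amp = 20, noise_sd = 3, seed = 16)
  rr <- generate_rr_series(p)
  shifted <- rr$intervals + 150
  expect_equal(time_domain(shifted)$rr_mean,
               time_domain(rr$intervals)$rr_mean + 150)
  bp0 <- band_powers(ar_spectrum(rr$intervals))
  bp1 <- band_powers(ar_spectrum(shifted))
  expect_equal(bp1$lf_nu, bp0$lf_nu, tolerance = 0.05)
  expect_equal(bp1$lf_a, bp0$lf_a, tolerance = 0.15)
})

test_that("short series and low orders are rejected", {
  expect_error(ar_spectrum(rep(c(900, 950), 20)), "64 beats")
  expect_error(ar_spectrum(rep(c(900, 950), 40), order = 2), "at least 4")
})

test_that("band powers follow the definition arithmetic", {
  comps <- data.frame(central_freq = c(0.10, 0.25), power = c(400, 400),
                      band = c("LF", "HF"))
  bp <- band_powers(comps)
  expect_equal(bp[c("lf_a", "hf_a", "lf_nu", "hf_nu", "lf_hf")],
               list(lf_a = 400, hf_a = 400, lf_nu = 50, hf_nu = 50,
                    lf_hf = 1.0))
  comps2 <- data.frame(central_freq = c(0.10, 0.25), power = c(300, 100),
                       band = c("LF", "HF"))
  bp2 <- band_powers(comps2)
  expect_equal(bp2$lf_nu, 75)
  expect_equal(bp2$hf_nu, 25)
  expect_equal(bp2$lf_hf, 3.0)
})

test_that("VLF-only spectra leave normalized units undefined", {
  vlf <- data.frame(central_freq = 0.02, power = 900, band = "VLF")
  bp <- band_powers(vlf)
  expect_equal(bp$lf_a, 0)
  expect_equal(bp$hf_a, 0)
  expect_true(is.na(bp$lf_nu) && is.na(bp$hf_nu) && is.na(bp$lf_hf))
  # LF power without HF: ratio infinite, nu still defined
  lf_only <- data.frame(central_freq = 0.1, power = 500, band = "LF")
  bp2 <- band_powers(lf_only)
  expect_equal(bp2$lf_nu, 100)
  expect_identical(bp2$lf_hf, Inf)
})

test_that("normalized units always sum to 100 when defined", {
  for (s in 1:10) {
    bp <- band_powers(ar_spectrum(generate_rr_series(rr_gen_params(
      duration_s = 120, lf_amp = 20, hf_amp = 15, noise_sd = 8,
      seed = s))))
    if (!is.na(bp$lf_nu)) expect_equal(bp$lf_nu + bp$hf_nu, 100)
  }
})

test_that("the orthostatic delta follows the stand-minus-rest convention", {
  rec <- function(lf_nu, posture) {
    structure(list(lf_nu = lf_nu, subject_id = "S1", time = "T1",
                   phase = "pre", posture = posture), class = "hrv_record")
  }
  expect_equal(delta_lfnu(rec(60, "rest"), rec(80, "stand")), 20)
  expect_equal(delta_lfnu(rec(50, "rest"), rec(50, "stand")), 0)
  expect_equal(delta_lfnu(rec(70, "rest"), rec(55, "stand")), -15)
  bad <- rec(80, "stand"); bad$subject_id <- "S2"
  expect_error(delta_lfnu(rec(60, "rest"), bad), "disagree")
  expect_error(delta_lfnu(rec(60, "stand"), rec(80, "stand")),
               "posture order")
})

test_that("feature extraction from RR files assembles cohort rows", {
  dir <- tempfile(); dir.create(dir)
  meta <- do.call(rbind, lapply(1:2, function(i) {
    rest_f <- file.path(dir, sprintf("s%d_rest.txt", i))
    stand_f <- file.path(dir, sprintf("s%d_stand.txt", i))
    write_rr_series(generate_rr_series(rr_gen_params(
      duration_s = 120, mean_rr = 920, seed = 30 + i)), rest_f)
    # standing: shorter RR, more LF - the classic orthostatic shift
    write_rr_series(generate_rr_series(rr_gen_params(
      duration_s = 120, mean_rr = 780, lf_amp = 35, hf_amp = 8,
      seed = 60 + i)), stand_f)
    data.frame(subject_id = sprintf("S%02d", i), treatment = "-55C",
               age = 40 + i, sex = "F", time = "T1", phase = "pre",
               rest_file = rest_f, stand_file = stand_f,
               stringsAsFactors = FALSE)
  }))
  coh <- hrv_from_files(meta)
  expect_equal(nrow(coh), 2)
  expect_true(all(c("rr_mean", "rr_tp", "rr_lfnu", "delta_lfnu") %in%
                    names(coh)))
  expect_true(all(coh$delta_lfnu > 0))
  expect_equal(coh$rr_mean, c(920, 920), tolerance = 0.05)
})
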