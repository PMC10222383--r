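# Detector accuracy against simulator ground truth, segmentation window
# rules, and the transform pair against a naive O(N^2) oracle.

test_that("detector finds every beat of a clean record near ground truth", {
  sp <- sample_subjects(1, seed = 17, noise_sd = 0, baseline_amp = 0)[[1]]
  sp$mean_rr <- 0.9
  rec <- synth_record(sp, duration = 10, fs = 500, seed = 3)
  peaks <- detect_r_peaks(rec)
  expect_length(peaks, length(rec$r_peak_truth))
  expect_true(all(abs(peaks - rec$r_peak_truth) <= 3))
})

test_that("detector returns an empty sequence on a flat record", {
  rec <- ecg_record(rep(0.5, 1000), fs = 500, subject_id = "flat")
  expect_identical(detect_r_peaks(rec), integer(0))
})

test_that("detections respect the 200 ms refractory period", {
  for (seed in 1:3) {
    sp <- sample_subjects(1, seed = seed)[[1]]
    rec <- synth_record(sp, duration = 10, fs = 500, seed = seed + 100)
    peaks <- detect_r_peaks(rec)
    if (length(peaks) > 1) {
      expect_gte(min(diff(peaks)), 0.2 * rec$fs)
    }
  }
  expect_error(detect_r_peaks(ecg_record(rnorm(100), 500, "s")), "1 second")
})

test_that("segmentation yields one window per interior peak and drops boundary beats", {
  sp <- sample_subjects(1, seed = 23, noise_sd = 0, baseline_amp = 0)[[1]]
  rec <- synth_record(sp, duration = 10, fs = 500, seed = 2)
  interior <- rec$r_peak_truth
  L <- 256L
  pre <- floor(0.4 * L)
  ok <- interior - pre >= 1 & interior - pre + L - 1 <= length(rec$samples)
  segs <- segment_record(rec, rec$r_peak_truth, L)
  expect_length(segs, sum(ok))
  # a beat too close to the start is discarded
  expect_length(segment_record(rec, c(10L), 256L), 0L)
  expect_error(segment_record(rec, rec$r_peak_truth, 30L), "even integer")
  expect_error(segment_record(rec, rec$r_peak_truth, 33L), "even integer")
})

test_that("segments are z-scored, verified by independent recomputation", {
  sp <- sample_subjects(1, seed = 29)[[1]]
  rec <- synth_record(sp, duration = 8, fs = 500, seed = 4)
  segs <- segment_record(rec, rec$r_peak_truth, 256L)
  expect_gt(length(segs), 0)
  for (s in segs) {
    expect_length(s$values, 256L)
    expect_lt(abs(mean(s$values)), 1e-9)
    expect_lt(abs(sd(s$values) - 1), 1e-6)
    expect_equal(s$r_index, floor(0.4 * 256) + 1)
  }
  # independent recomputation of the first window from the raw record
  s1 <- segs[[1]]
  start <- rec$r_peak_truth[1] - floor(0.4 * 256)
  raw <- rec$samples[start:(start + 255)]
  expect_equal(s1$values, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
})

test_that("dft matches the naive transform on random sequences at many lengths", {
  set.seed(101)
  for (N in c(7L, 8L, 50L, 200L, 256L)) {
    for (rep in 1:20) {
      x <- rnorm(N)
      X <- dft(x)
      X0 <- naive_dft(x)
      expect_lt(max(Mod(X - X0)) / max(Mod(X0)), 1e-9)
    }
  }
})

test_that("dft handles degenerate spectra exactly", {
  X <- dft(rep(3, 8))
  expect_equal(Re(X[1]), 24)
  expect_true(all(Mod(X[-1]) < 1e-12 * 24))
  Xd <- dft(c(1, rep(0, 15)))
  expect_true(all(Mod(Xd - 1) < 1e-12))
  expect_error(dft(c(1, NA)), "finite")
})

test_that("idft inverts dft, including odd lengths, and Parseval holds", {
  set.seed(7)
  for (N in c(33L, 64L)) {
    x <- rnorm(N)
    X <- dft(x)
    expect_equal(idft(X), x, tolerance = 1e-9)
    # imaginary residue of the inverse is at floating-point level
    resid <- Mod(Im(stats::fft(X, inverse = TRUE) / N))
    expect_lt(max(resid), 1e-9)
    expect_lt(abs(sum(x^2) - sum(Mod(X)^2) / N) / sum(x^2), 1e-9)
  }
})

test_that("conjugate symmetry of the magnitude spectrum for real input", {
  set.seed(8)
  x <- rnorm(200)
  m <- Mod(dft(x))
  for (k in 1:199) expect_equal(m[1 + k], m[1 + 200 - k], tolerance = 1e-9)
})

test_that("featurize produces the exact L x 2 shape and is pure", {
  for (L in c(200L, 256L)) {
    set.seed(L)
    fm <- featurize(random_segment(L))
    expect_identical(dim(fm), c(L, 2L))
    expect_true(all(is.finite(fm)))
  }
  seg <- random_segment(64L)
  expect_identical(featurize(seg), featurize(seg))
  # channel 2 is the z-scored magnitude, independently recomputed
  fm <- featurize(seg)
  m <- Mod(naive_dft(seg$values))
  expect_equal(fm[, 2], (m - mean(m)) / sd(m), tolerance = 1e-9)
  expect_identical(fm[, 1], seg$values)
})

test_that("end-to-end preprocessing yields one feature matrix per interior beat", {
  sp <- sample_subjects(1, seed = 37, noise_sd = 0, baseline_amp = 0)[[1]]
  rec <- synth_record(sp, duration = 12, fs = 500, seed = 6)
  fms <- preprocess_record(rec, L = 256L)
  pre <- floor(0.4 * 256)
  interior <- sum(rec$r_peak_truth - pre >= 1 &
                    rec$r_peak_truth - pre + 255 <= length(rec$samples))
  expect_length(fms, interior)
  expect_true(all(vapply(fms, function(f) identical(dim(f), c(256L, 2L)),
                         logical(1))))
})
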