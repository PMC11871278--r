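make_rec <- function(n_s, fs = 64, ch = 2, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(ch * n_s), ch), fs)
}

test_that("segmentation drops the remainder and errors on short input", {
  expect_length(segment_recording(make_rec(60 * 64), window_s = 1), 60)
  expect_length(segment_recording(make_rec(60 * 64), window_s = 2), 30)
  expect_length(segment_recording(make_rec(61.5 * 64), window_s = 1), 61)
  expect_error(segment_recording(make_rec(30), window_s = 1), "shorter")
  segs <- segment_recording(make_rec(130), window_s = 1)
  expect_equal(dim(segs[[1]]), c(2L, 64L))
})

test_that("band-pass keeps in-band tones and rejects out-of-band ones", {
  fs <- 128
  x <- sin(2 * pi * 10 * (0:(4 * fs - 1)) / fs)
  in_band <- bandpass_filter(x, 8, 12, fs)
  expect_gt(sum(in_band^2) / sum(x^2), 0.9)
  out_band <- bandpass_filter(x, 31, Inf, fs)
  expect_lt(sum(out_band^2) / sum(x^2), 0.01)
  expect_equal(bandpass_filter(rep(0, 256), 8, 12, fs), rep(0, 256))
  expect_error(bandpass_filter(x, 80, 100, fs), "Nyquist")
})

test_that("Hjorth parameters follow their defining variance ratios", {
  expect_equal(unname(hjorth(rep(2, 10))), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(isTRUE(attr(hjorth(rep(2, 10)), "degenerate")))
  set.seed(5)
  x <- rnorm(256)
  h1 <- hjorth(x); h3 <- hjorth(3 * x)
  expect_equal(h3[["activity"]], 9 * h1[["activity"]])
  expect_equal(h3[["mobility"]], h1[["mobility"]])
  expect_equal(h3[["complexity"]], h1[["complexity"]])
  # direct evaluation of the definitions on the same discrete signal
  pv <- function(v) mean(v^2) - mean(v)^2
  x <- sin(2 * pi * 6 * (0:199) / 200)
  d1 <- diff(x); d2 <- diff(d1)
  expect_equal(hjorth(x)[["activity"]], pv(x))
  expect_equal(hjorth(x)[["mobility"]], sqrt(pv(d1) / pv(x)))
  expect_equal(hjorth(x)[["complexity"]],
               sqrt(pv(d2) / pv(d1)) / sqrt(pv(d1) / pv(x)))
})

test_that("spectral entropy spans tonal to broadband", {
  n <- 64
  tone <- sin(2 * pi * 5 * (0:(n - 1)) / n)       # exact DFT bin
  expect_equal(spectral_entropy(tone), 0, tolerance = 1e-10)
  impulse <- c(1, rep(0, n - 1))                  # flat spectrum
  expect_equal(spectral_entropy(impulse), 1, tolerance = 1e-12)
  two <- sin(2 * pi * 5 * (0:(n - 1)) / n) + sin(2 * pi * 13 * (0:(n - 1)) / n)
  expect_equal(spectral_entropy(two), log(2) / log(n / 2), tolerance = 1e-10)
  z <- spectral_entropy(rep(0, n))
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("signal energy is the sum of squares", {
  expect_equal(signal_energy(rep(0, 5)), 0)
  expect_equal(signal_energy(c(1, rep(0, 9))), 1)
  x <- rnorm(50)
  expect_equal(signal_energy(3 * x), 9 * signal_energy(x))
})

test_that("feature vectors have the documented dimension and layout", {
  fs <- 128
  set.seed(9)
  seg32 <- matrix(rnorm(32 * fs), 32, fs,
                  dimnames = list(paste0("ch", 1:32), NULL))
  fv <- feature_vector(seg32, fs)
  expect_length(fv, 800)   # 5 bands x 5 features x 32 channels
  expect_equal(names(fv)[1], "Delta.activity.ch1")
  seg1 <- matrix(rnorm(fs), 1, dimnames = list("Oz", NULL))
  expect_length(feature_vector(seg1, fs, bands = eeg_bands()[3, ],
                               features = "energy"), 1)
  occ <- paste0("ch", 1:3)
  expect_length(feature_vector(seg32, fs, channels = occ), 5 * 5 * 3)
  expect_error(feature_vector(seg32, fs, channels = character(0)),
               "non-empty")
  expect_error(feature_vector(seg32, fs, channels = "nope"), "unknown")
})

test_that("labels map bijectively to positions", {
  labs <- feature_labels(c("Delta", "Alpha"), c("activity", "energy"),
                         c("O1", "Oz"))
  expect_length(labs, 8)
  expect_false(anyDuplicated(labs) > 0)
  parsed <- parse_feature_labels(labs)
  expect_equal(paste(parsed$band, parsed$feature, parsed$channel, sep = "."),
               labs)
  # band-major, then feature, then channel
  expect_equal(labs[1:4], c("Delta.activity.O1", "Delta.activity.Oz",
                            "Delta.energy.O1", "Delta.energy.Oz"))
})

test_that("tensor subsetting equals slicing the full tensor", {
  spec <- small_spec(seed = 31)
  recs <- gen_eeg_cohort(spec)
  full <- eeg_feature_tensor(recs, window_s = 1)
  expect_equal(dim(full), c(6L, 30L, 5 * 5 * 4))
  sub <- eeg_feature_tensor(recs, window_s = 1, channels = c("ch1", "ch3"))
  sliced <- select_features(full, channels = c("ch1", "ch3"))
  expect_equal(sub[, , dimnames(sub)[[3]]],
               sliced[, , dimnames(sub)[[3]]])
  delta_only <- select_features(full, bands = "Delta")
  expect_equal(dim(delta_only)[3], 5 * 4)
  # determinism: identical input -> bit-identical features
  again <- eeg_feature_tensor(recs, window_s = 1)
  expect_identical(full, again)
})

test_that("per-segment filtering scope matches feature_vector exactly", {
  spec <- small_spec(seed = 32)
  recs <- gen_eeg_cohort(spec)[1:2]
  tens <- eeg_feature_tensor(recs, window_s = 1, filter_scope = "segment")
  seg5 <- segment_recording(recs[[1]], 1)[[5]]
  expect_equal(tens[1, 5, ], feature_vector(seg5, recs[[1]]$fs))
})
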