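make_fit <- function(seed = 71, n_videos = 4, coupled = TRUE) {
  set.seed(seed)
  sv <- lapply(seq_len(n_videos), function(i)
    smooth_score(runif(30), smoother("gaussian", 2)))
  sb <- lapply(sv, function(x) {
    if (coupled) pmin(pmax(x + rnorm(30, sd = 0.05), 0), 1)
    else smooth_score(runif(30), smoother("gaussian", 2))
  })
  brainsource(sv, sb, l = c(3, 5), theta_c = c(0.2, 0.4), n_perm = 6,
              seed = seed + 1)
}

test_that("the fit object carries a complete, consistent grid", {
  fit <- make_fit()
  expect_s3_class(fit, "brainsource")
  expect_equal(nrow(fit$grid), 4)
  expect_equal(dim(fit$rho), c(4L, 4L))
  expect_equal(dim(fit$rho_tilde), c(4L, 6L, 4L))
  expect_equal(fit$grid$rho_mean, colMeans(fit$rho))
  expect_true(all(fit$grid$rho_mean >= 0 & fit$grid$rho_mean <= 1))
  expect_true(all(!is.na(fit$grid$d)))
  expect_equal(fit$grid$label, effect_size_label(fit$grid$d))
})

test_that("fits are reproducible under a seed and detect coupling", {
  f1 <- make_fit(81)
  f2 <- make_fit(81)
  expect_identical(f1$grid, f2$grid)
  coupled <- make_fit(82, n_videos = 6, coupled = TRUE)
  expect_gt(max(coupled$grid$d), 0.8)
})

test_that("S3 methods print, summarise, extract and plot", {
  fit <- make_fit(83)
  expect_output(print(fit), "Brainsourcing fit")
  expect_output(print(summary(fit)), "permutations: 6")
  cf <- coef(fit)
  expect_length(cf, 4)
  expect_match(names(cf)[1], "l=3,theta_c=0.2", fixed = TRUE)
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_invisible(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(pdf_file))
  unlink(pdf_file)
})

test_that("channel groups resolve against a 32-channel montage", {
  montage <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
               "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4",
               "Fz", "F4", "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6",
               "CP2", "P4", "P8", "PO4", "O2")
  expect_identical(channel_group(montage, "all"), montage)
  occ <- channel_group(montage, "occipital")
  expect_setequal(occ, c("O1", "Oz", "O2"))
  expect_false(any(c("PO3", "PO4") %in% occ))
  expect_setequal(channel_group(montage, "no occipital"),
                  setdiff(montage, occ))
  expect_true(all(c("PO3", "PO4") %in% channel_group(montage, "parietal")))
  expect_error(channel_group(montage, "cerebellar"), "unknown")
})

test_that("file I/O round-trips salience stacks, gaze and EEG", {
  tmp <- tempfile()
  spec <- small_spec(seed = 91)
  maps <- gen_salience_stack(spec)
  write_salience_dir(maps, tmp)
  back <- read_salience_dir(tmp, video_id = maps$video_id)
  expect_equal(back$n_frames, maps$n_frames)
  # PNG quantizes to 8 bits; scores agree to quantization accuracy
  expect_equal(visual_score_series(back), visual_score_series(maps),
               tolerance = 0.01, ignore_attr = TRUE)
  gz <- gen_gaze_from_maps(maps, 5, seed = 2)
  gcsv <- tempfile(fileext = ".csv")
  write_gaze_csv(gz, gcsv)
  gz2 <- read_gaze_csv(gcsv)
  expect_equal(as.data.frame(gz2), as.data.frame(gz), tolerance = 1e-12)
  rec <- gen_eeg_cohort(spec)[[1]]
  ecsv <- tempfile(fileext = ".csv")
  write_eeg_csv(rec, ecsv)
  rec2 <- read_eeg_csv(ecsv)
  expect_equal(rec2$samples, rec$samples, tolerance = 1e-12)
  expect_equal(rec2$fs, rec$fs)
  expect_equal(rec2$channel_names, rec$channel_names)
  unlink(c(gcsv, ecsv, sub("\\.csv$", ".json", ecsv)))
  unlink(tmp, recursive = TRUE)
})

test_that("the pipeline runs end to end and writes a results bundle", {
  out <- tempfile()
  config <- list(
    seed = 7,
    synthetic = list(n_videos = 2, n_steps = 20, map_w = 32, map_h = 32,
                     n_subjects = 4, n_channels = 3, fs = 128),
    grid = list(l = 5, theta_c = 0.4),
    n_perm = 4,
    out_dir = out)
  res <- suppressMessages(run_pipeline(config))
  expect_s3_class(res$fit, "brainsource")
  expect_equal(nrow(res$fit$grid), 1)
  expect_equal(sort(unique(res$scores$video_id)),
               sort(unique(res$scores$video_id)))
  expect_true(all(file.exists(res$paths)))
  js <- jsonlite::read_json(res$paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$seed, 7)
  expect_false(is.null(js$config_hash))
  # byte-identical reproduction under the same config and seed
  out2 <- tempfile()
  config$out_dir <- out2
  res2 <- suppressMessages(run_pipeline(config))
  expect_identical(res$fit$grid, res2$fit$grid)
  expect_identical(readLines(res$paths[["scores"]])[-1],
                   readLines(res2$paths[["scores"]])[-1])
  unlink(c(out, out2), recursive = TRUE)
})
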