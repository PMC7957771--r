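dummy_rec <- function(duration, fs = 250) {
  n <- round(duration * fs)
  m <- matrix(seq_len(12 * n), nrow = 12, dimnames = list(eeg_channels(), NULL))
  eegemo:::new_recording("s", 1, m, fs, eeg_channels())
}

test_that("window counts follow the closed form over a grid of settings", {
  for (D in c(10, 30, 60, 120)) {
    rec <- dummy_rec(D)
    for (L in c(1, 2, 4, 7, 10)) {
      for (O in c(0, 1, L / 2)) {
        if (O >= L) next
        ws <- segment(rec, window_spec(L, O))
        expect_length(ws, floor((D - L) / (L - O)) + 1)
      }
    }
  }
  expect_length(segment(dummy_rec(120), window_spec(10, 0)), 12)
  expect_length(segment(dummy_rec(120), window_spec(4, 1)), 39)
  expect_length(segment(dummy_rec(3), window_spec(4, 0)), 0)
})

test_that("non-overlapping windows tile the recording disjointly", {
  rec <- dummy_rec(20)
  ws <- segment(rec, window_spec(4, 0))
  samples <- lapply(ws, function(w) w$signals[1, ])
  expect_equal(length(unique(unlist(samples))), 4 * 250 * length(ws))
  starts <- vapply(ws, `[[`, numeric(1), "start_time")
  expect_equal(starts, seq(0, 16, by = 4))
})

test_that("binarize maps the sign convention with 0 to the low class", {
  expect_equal(binarize(0.5, "valence"), "positive")
  expect_equal(binarize(-0.01, "arousal"), "low")
  expect_equal(binarize(0, "arousal"), "low")
  expect_equal(binarize(0, "valence"), "negative")
  expect_error(binarize(1.5, "valence"), "outside")
})

test_that("window labels follow majority, carry-forward and tie rules", {
  ann <- data.frame(time_s = c(1, 2, 3),
                    arousal = c(0.5, -0.2, 0.4),
                    valence = c(0.5, -0.2, 0.4))
  lab <- label_window(0, 4, ann)
  expect_equal(lab$valence_class, "positive")   # 2 of 3
  expect_equal(lab$arousal_class, "high")

  # carry-forward from the last prior click
  ann2 <- data.frame(time_s = 2, arousal = -0.3, valence = -0.3)
  lab2 <- label_window(5, 1, ann2)
  expect_equal(lab2$valence_class, "negative")

  # no event anywhere before the window -> drop
  expect_null(label_window(0, 1, ann2))

  # tie resolved by the sign of the mean raw value
  ann3 <- data.frame(time_s = c(1, 2), arousal = c(0.6, -0.4),
                     valence = c(0.6, -0.4))
  expect_equal(label_window(0, 4, ann3)$valence_class, "positive")  # mean 0.1
  ann4 <- data.frame(time_s = c(1, 2), arousal = c(0.4, -0.6),
                     valence = c(0.4, -0.6))
  expect_equal(label_window(0, 4, ann4)$valence_class, "negative")
})

test_that("window spans are half-open so boundary clicks count once", {
  ann <- data.frame(time_s = c(0, 2), arousal = c(1, -1), valence = c(1, -1))
  lab01 <- label_window(0, 2, ann)  # click at 2 s excluded
  expect_equal(lab01$valence_class, "positive")
  lab23 <- label_window(2, 2, ann)  # click at 2 s included
  expect_equal(lab23$valence_class, "negative")
})

test_that("build_dataset assembles, drops and reports consistently", {
  wd <- tiny_windows()
  expect_s3_class(wd, "windowed_dataset")
  expect_equal(dim(wd$X)[1:2], c(12, 2 * 250))
  expect_equal(dim(wd$X)[3] + wd$n_dropped, 4 * 15)  # 4 recordings x 30/2
  expect_true(all(c("subject_id", "song_id", "start_s",
                    "arousal_class", "valence_class") %in% names(wd$meta)))

  # with clicks every 2-3 s and 10 s windows the carry-forward rule labels
  # every window
  ds <- tiny_dataset()
  wd10 <- build_dataset(ds, window_spec(10, 0))
  expect_equal(wd10$n_dropped, 0)

  # a recording without annotations is skipped and reported
  ds2 <- tiny_dataset()
  ds2$annotations[[1]] <- NULL
  wd2 <- build_dataset(ds2, window_spec(10, 0))
  expect_length(wd2$errors, 1)
  expect_equal(dim(wd2$X)[3], 3 * 3)  # remaining 3 recordings x 3 windows
})

test_that("zero-noise labels match the planted blocks for interior windows", {
  cfg <- generator_config(n_subjects = 1, n_songs_per_subject = 1,
                          song_duration = 60, block_duration = c(8, 12),
                          annotation_noise_sd = 0,
                          annotation_interval = c(1, 1.5), master_seed = 5)
  ds <- generate_dataset(cfg)
  wd <- build_dataset(ds, window_spec(4, 0))
  tr <- ds$trajectories[[1]]
  checked <- 0
  for (i in seq_len(nrow(wd$meta))) {
    s0 <- wd$meta$start_s[i]; s1 <- s0 + 4
    blk <- tr$blocks[tr$blocks$start + 1 <= s0 & tr$blocks$end >= s1, ]
    # +1 skips windows overlapping the 1 s ramp at the block start
    if (nrow(blk) != 1) next
    checked <- checked + 1
    expect_equal(wd$meta$valence_class[i],
                 binarize(blk$valence_level, "valence"))
    expect_equal(wd$meta$arousal_class[i],
                 binarize(blk$arousal_level, "arousal"))
  }
  expect_gt(checked, 5)
})

test_that("windowed datasets round-trip through the tensor + CSV layout", {
  wd <- tiny_windows()
  dir <- file.path(tempdir(), "eegemo-wd")
  on.exit(unlink(dir, recursive = TRUE))
  write_windowed_dataset(wd, dir)
  back <- read_windowed_dataset(dir)
  expect_equal(back$X, wd$X)
  expect_equal(back$meta$valence_class, wd$meta$valence_class)
  expect_equal(back$window_spec$window_length, wd$window_spec$window_length)
})
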