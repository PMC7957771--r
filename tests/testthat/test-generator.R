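test_that("trajectory blocks partition the song with levels in [-1, 1]", {
  cfg <- generator_config(n_subjects = 1, n_songs_per_subject = 1,
                          song_duration = 120, block_duration = c(20, 40),
                          master_seed = 1)
  for (seed in 1:5) {
    tr <- make_trajectory(cfg, seed)
    nb <- nrow(tr$blocks)
    expect_gte(nb, 3)  # 120 s cut into 20-40 s pieces
    expect_lte(nb, 6)
    expect_equal(tr$blocks$start[1], 0)
    expect_equal(tr$blocks$end[nb], 120)
    expect_true(all(abs(tr$arousal) <= 1 & abs(tr$valence) <= 1))
    expect_length(tr$times, 120 * cfg$trajectory_rate)
  }
})

test_that("a song shorter than the minimum block yields a single block", {
  cfg <- generator_config(n_subjects = 1, n_songs_per_subject = 1,
                          song_duration = 10, block_duration = c(120, 120),
                          master_seed = 1)
  tr <- make_trajectory(cfg, 3)
  expect_equal(nrow(tr$blocks), 1)
  expect_equal(length(unique(tr$valence)), 1)
})

test_that("trajectories and annotations are deterministic in the seed", {
  cfg <- tiny_config()
  expect_identical(make_trajectory(cfg, 42), make_trajectory(cfg, 42))
  tr <- make_trajectory(cfg, 42)
  expect_identical(make_annotations(tr, cfg, 5), make_annotations(tr, cfg, 5))
  expect_false(identical(make_trajectory(cfg, 42), make_trajectory(cfg, 43)))
})

test_that("annotation click times respect the configured cadence", {
  cfg <- generator_config(n_subjects = 1, n_songs_per_subject = 1,
                          song_duration = 120, master_seed = 1,
                          annotation_noise_sd = 3)  # large, to exercise clipping
  tr <- make_trajectory(cfg, 1)
  for (seed in 1:5) {
    ann <- make_annotations(tr, cfg, seed)
    expect_gte(nrow(ann), 40)  # 120 s / 3 s
    expect_lte(nrow(ann), 60)  # 120 s / 2 s
    gaps <- diff(ann$time_s)
    expect_true(all(gaps >= 2 - 1e-9 & gaps <= 3 + 1e-9))
    expect_true(all(ann$time_s > 0 & ann$time_s < 120))
    expect_true(all(abs(ann$arousal) <= 1 & abs(ann$valence) <= 1))
  }
})

test_that("zero annotation noise reproduces the latent trajectory exactly", {
  cfg <- tiny_config(annotation_noise_sd = 0)
  tr <- make_trajectory(cfg, 2)
  ann <- make_annotations(tr, cfg, 3)
  expect_equal(ann$valence,
               eegemo:::trajectory_value(tr, ann$time_s, "valence"))
  expect_equal(ann$arousal,
               eegemo:::trajectory_value(tr, ann$time_s, "arousal"))
})

test_that("a synthesized recording has the configured geometry", {
  cfg <- tiny_config()
  tr <- make_trajectory(cfg, 1)
  rec <- synthesize_recording(subject_profile("s1"), tr, cfg, 4)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$signals), c(12, 30 * 250))
  expect_identical(rownames(rec$signals), eeg_channels())
})

test_that("extreme effect gains floor amplitudes at zero with a warning", {
  cfg <- tiny_config(valence_asym_gain = 3)
  tr <- make_trajectory(cfg, 1)
  expect_warning(synthesize_recording(subject_profile("s"), tr, cfg, 1),
                 "floored")
})

test_that("generated channels show a 1/f trend with alpha and beta peaks", {
  cfg <- tiny_config()
  tr <- make_trajectory(cfg, 9)
  rec <- synthesize_recording(subject_profile("s"), tr, cfg, 9)
  w <- welch_psd(rec$signals["Pz", ], 250)
  at <- function(f) w$psd[which.min(abs(w$freq - f))]
  expect_gt(at(2), at(40))          # 1/f decline
  expect_gt(at(10), 3 * at(7))      # alpha peak
  expect_gt(at(20), 3 * at(16))     # beta peak
})

test_that("shared-source mixing raises mean cross-channel correlation", {
  cfg_on <- tiny_config()
  cfg_off <- tiny_config(shared_source_weight = 0)
  tr <- make_trajectory(cfg_on, 5)
  rec_on <- synthesize_recording(subject_profile("s"), tr, cfg_on, 5)
  rec_off <- synthesize_recording(subject_profile("s"), tr, cfg_off, 5)
  mean_abs_od <- function(r) {
    cm <- abs(correlation_matrix(r))
    mean(cm[upper.tri(cm)])
  }
  expect_gt(mean_abs_od(rec_on), mean_abs_od(rec_off))
})

test_that("generate_dataset produces the full cohort deterministically", {
  cfg <- generator_config(n_subjects = 12, n_songs_per_subject = 16,
                          song_duration = 4, block_duration = c(2, 3),
                          annotation_interval = c(1, 1.5), master_seed = 3)
  ds <- generate_dataset(cfg)
  expect_equal(length(ds$recordings), 192)  # 12 x 16
  expect_equal(nrow(ds$manifest), 192)
  expect_equal(length(ds$profiles), 12)

  out1 <- file.path(tempdir(), "eegemo-ds1")
  out2 <- file.path(tempdir(), "eegemo-ds2")
  on.exit(unlink(c(out1, out2), recursive = TRUE), add = TRUE)
  cfg2 <- tiny_config(master_seed = 77)
  generate_dataset(cfg2, out_dir = out1)
  generate_dataset(cfg2, out_dir = out2)
  f1 <- sort(list.files(out1, full.names = TRUE))
  f2 <- sort(list.files(out2, full.names = TRUE))
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(generate_dataset(cfg2, out_dir = out1), "overwrite")
})

test_that("subject profiles are positive multipliers", {
  cfg <- tiny_config(subject_variability_sd = 0.5)
  for (s in 1:10) {
    p <- eegemo:::draw_subject_profile(s, cfg, s)
    expect_gt(p$gain, 0)
    expect_gt(p$noise_scale, 0)
    expect_gt(p$effect_multiplier, 0)
  }
})

test_that("config invariants are enforced", {
  expect_error(generator_config(sampling_rate = 100), "120 Hz")
  expect_error(generator_config(channel_labels = letters[1:12]), "montage")
  expect_error(generator_config(valence_asym_gain = -0.1), ">= 0")
})

test_that("a written dataset loads back equal to the in-memory one", {
  out <- file.path(tempdir(), "eegemo-roundtrip")
  on.exit(unlink(out, recursive = TRUE))
  cfg <- tiny_config(master_seed = 91)
  ds <- generate_dataset(cfg, out_dir = out)
  back <- load_dataset(out)
  expect_identical(names(back$recordings), names(ds$recordings))
  expect_equal(back$recordings[[2]]$signals, ds$recordings[[2]]$signals)
  expect_equal(back$annotations[[3]]$valence, ds$annotations[[3]]$valence)
  expect_equal(nrow(back$manifest), nrow(ds$manifest))
  expect_error(load_dataset(tempdir()), "manifest")
})
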