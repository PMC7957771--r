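#' Configuration for the synthetic EEG generator
#'
#' Bundles every knob of the synthetic emotion-labelled EEG model.  The
#' defaults emulate the study design the pipeline targets: 12 subjects each
#' listening to 16 songs of about two minutes, recorded from 12 frontal-ish
#' electrodes at 250 Hz, with continuous arousal-valence click annotation
#' every 2-3 s.
#'
#' The planted physiology is (i) a valence-coupled frontal alpha asymmetry:
#' for positive valence the left-frontal alpha amplitude (F3, and F7 at half
#' strength) is suppressed and the right-frontal one (F4/F8) enhanced, and
#' (ii) an arousal-coupled broadband beta gain on all channels.  A shared
#' pink-noise source with spatially smooth mixing weights induces nontrivial
#' cross-channel correlation so that correlation-based channel orderings are
#' meaningful.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_songs_per_subject Recordings (songs) per subject.
#' @param song_duration Song length in seconds.
#' @param sampling_rate Sampling rate in Hz; must exceed 120 Hz so the
#'   0.5-60 Hz analysis band is representable.
#' @param channel_labels Ordered channel labels; must be exactly the
#'   twelve-label montage of [eeg_channels()].
#' @param valence_asym_gain Dimensionless gain `k_v >= 0` of the
#'   valence -> frontal alpha asymmetry coupling.
#' @param arousal_beta_gain Dimensionless gain `k_a >= 0` of the
#'   arousal -> beta amplitude coupling.
#' @param annotation_interval Length-2 vector, min/max seconds between
#'   annotation clicks.
#' @param annotation_noise_sd SD of Gaussian noise added to each recorded
#'   click coordinate (clipped to `[-1, 1]`).
#' @param subject_variability_sd SD (log scale) of the per-subject lognormal
#'   multipliers for amplitude, noise and planted-effect strength.
#' @param block_duration Length-2 vector, min/max seconds of the
#'   piecewise-constant emotion blocks of the latent trajectory.
#' @param master_seed Integer master seed; every stream seed is derived from
#'   it deterministically.
#' @param alpha_amp Baseline alpha-tone (10 Hz) amplitude `a0`.
#' @param beta_amp Baseline beta-tone (20 Hz) amplitude `b0`.
#' @param noise_sd SD of the per-channel pink-noise floor.
#' @param shared_source_weight Overall scale of the shared-source mixing
#'   weights (0 switches the shared source off).
#' @param asym_positive_left_low Sign convention flag: if `TRUE` (default)
#'   positive valence lowers left-frontal alpha relative to right.
#' @param trajectory_rate Sample rate (Hz) of the latent trajectory grid.
#'
#' @return A `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 2, n_songs_per_subject = 2,
#'                         song_duration = 30, master_seed = 1)
generator_config <- function(n_subjects = 12,
                             n_songs_per_subject = 16,
                             song_duration = 120,
                             sampling_rate = 250,
                             channel_labels = eeg_channels(),
                             valence_asym_gain = 0.8,
                             arousal_beta_gain = 0.5,
                             annotation_interval = c(2, 3),
                             annotation_noise_sd = 0.1,
                             subject_variability_sd = 0.15,
                             block_duration = c(15, 30),
                             master_seed = 1L,
                             alpha_amp = 1.0,
                             beta_amp = 0.5,
                             noise_sd = 1.0,
                             shared_source_weight = 0.8,
                             asym_positive_left_low = TRUE,
                             trajectory_rate = 10) {
  stopifnot(n_subjects >= 1, n_songs_per_subject >= 1, song_duration > 0)
  if (sampling_rate <= 2 * 60)
    stop("sampling_rate must exceed 120 Hz so the 0.5-60 Hz passband is representable")
  if (!identical(sort(channel_labels), sort(eeg_channels())) ||
      length(channel_labels) != 12L)
    stop("channel_labels must be exactly the twelve montage labels of eeg_channels()")
  if (valence_asym_gain < 0 || arousal_beta_gain < 0)
    stop("coupling gains must be >= 0")
  stopifnot(length(annotation_interval) == 2, all(annotation_interval > 0),
            diff(annotation_interval) >= 0,
            length(block_duration) == 2, all(block_duration > 0),
            diff(block_duration) >= 0,
            annotation_noise_sd >= 0, subject_variability_sd >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_songs_per_subject = as.integer(n_songs_per_subject),
    song_duration = song_duration,
    sampling_rate = sampling_rate,
    channel_labels = channel_labels,
    valence_asym_gain = valence_asym_gain,
    arousal_beta_gain = arousal_beta_gain,
    annotation_interval = annotation_interval,
    annotation_noise_sd = annotation_noise_sd,
    subject_variability_sd = subject_variability_sd,
    block_duration = block_duration,
    master_seed = as.integer(master_seed),
    alpha_amp = alpha_amp,
    beta_amp = beta_amp,
    noise_sd = noise_sd,
    shared_source_weight = shared_source_weight,
    asym_positive_left_low = isTRUE(asym_positive_left_low),
    trajectory_rate = trajectory_rate
  ), class = "generator_config")
}

#' Per-subject variability profile
#'
#' Models the inter-subject variability that motivates subject-independent
#' evaluation: a global amplitude gain, a noise-floor scale, and a multiplier
#' on the planted valence/arousal effect gains.  All multipliers are strictly
#' positive.
#'
#' @param subject_id Subject identifier.
#' @param gain Amplitude multiplier applied to the whole recording.
#' @param noise_scale Multiplier on the pink-noise floor.
#' @param effect_multiplier Multiplier on both coupling gains.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(subject_id, gain = 1, noise_scale = 1,
                            effect_multiplier = 1) {
  stopifnot(gain > 0, noise_scale > 0, effect_multiplier > 0)
  structure(list(subject_id = subject_id, gain = gain,
                 noise_scale = noise_scale,
                 effect_multiplier = effect_multiplier),
            class = "subject_profile")
}

draw_subject_profile <- function(subject_id, config, seed) {
  set.seed(seed)
  sdv <- config$subject_variability_sd
  subject_profile(subject_id,
                  gain = exp(rnorm(1, 0, sdv)),
                  noise_scale = exp(rnorm(1, 0, sdv)),
                  effect_multiplier = exp(rnorm(1, 0, sdv)))
}

#' Latent arousal-valence trajectory for one song
#'
#' Draws a piecewise-constant emotion trajectory: block lengths uniform
#' within `config$block_duration`, arousal and valence levels uniform in
#' `[-1, 1]` per block (shared block boundaries), joined by linear 1 s ramps.
#' Piecewise-constant blocks give an unambiguous per-window majority ground
#' truth, which is what the window labeller is tested against.
#'
#' @param config A [generator_config()].
#' @param seed Integer stream seed; identical seeds give identical
#'   trajectories.
#' @return An `emotion_trajectory` list with the sampled grid (`times`,
#'   `arousal`, `valence`, all in `[-1, 1]`) and the underlying `blocks`
#'   table (`start`, `end`, `arousal_level`, `valence_level`).
#' @export
make_trajectory <- function(config, seed) {
  set.seed(seed)
  dur <- config$song_duration
  bmin <- config$block_duration[1]; bmax <- config$block_duration[2]
  starts <- 0; lens <- numeric(0); t <- 0
  while (t < dur) {
    len <- runif(1, bmin, bmax)
    lens <- c(lens, len)
    t <- t + len
    if (t < dur) starts <- c(starts, t)
  }
  ends <- pmin(cumsum(lens), dur)
  k <- length(starts)
  av <- runif(k, -1, 1)
  vv <- runif(k, -1, 1)
  blocks <- data.frame(start = starts, end = ends,
                       arousal_level = av, valence_level = vv)

  rate <- config$trajectory_rate
  n <- round(dur * rate)
  times <- (seq_len(n) - 1) / rate
  ramp <- 1  # seconds of linear transition at each block boundary
  level_at <- function(tt, levels) {
    idx <- findInterval(tt, starts)
    val <- levels[idx]
    if (k > 1) {
      for (j in 2:k) {
        b <- starts[j]
        r <- min(ramp, ends[j] - b)
        if (r > 0) {
          sel <- tt >= b & tt < b + r
          if (any(sel)) {
            w <- (tt[sel] - b) / r
            val[sel] <- (1 - w) * levels[j - 1] + w * levels[j]
          }
        }
      }
    }
    val
  }
  structure(list(times = times,
                 arousal = level_at(times, av),
                 valence = level_at(times, vv),
                 blocks = blocks,
                 rate = rate,
                 duration = dur),
            class = "emotion_trajectory")
}

# Linear interpolation of the trajectory grid at arbitrary times.
trajectory_value <- function(trajectory, t, dimension = c("arousal", "valence")) {
  dimension <- match.arg(dimension)
  approx(trajectory$times, trajectory[[dimension]], xout = t, rule = 2)$y
}

#' Simulated continuous annotation clicks
#'
#' Emulates a rater continuously clicking in arousal-valence space: inter-
#' click gaps uniform within `config$annotation_interval`, recorded values
#' equal to the latent trajectory at the click time plus Gaussian noise,
#' clipped to `[-1, 1]`.
#'
#' @param trajectory An [make_trajectory()] result covering the song.
#' @param config A [generator_config()].
#' @param seed Integer stream seed.
#' @return An `annotation_trace` data frame with columns `time_s`, `arousal`,
#'   `valence`; times strictly increasing within `[0, duration]`.
#' @export
make_annotations <- function(trajectory, config, seed) {
  set.seed(seed)
  dur <- trajectory$duration
  lo <- config$annotation_interval[1]; hi <- config$annotation_interval[2]
  times <- numeric(0); t <- 0
  repeat {
    t <- t + runif(1, lo, hi)
    if (t >= dur) break
    times <- c(times, t)
  }
  n <- length(times)
  noise_a <- rnorm(n, 0, config$annotation_noise_sd)
  noise_v <- rnorm(n, 0, config$annotation_noise_sd)
  out <- data.frame(
    time_s = times,
    arousal = pmin(1, pmax(-1, trajectory_value(trajectory, times, "arousal") + noise_a)),
    valence = pmin(1, pmax(-1, trajectory_value(trajectory, times, "valence") + noise_v))
  )
  class(out) <- c("annotation_trace", "data.frame")
  out
}

#' Pink (1/f) noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with a `1/sqrt(f)`
#' amplitude profile (power `1/f`), the DC bin zeroed, and the result
#' rescaled to unit SD.
#'
#' @param n Number of samples.
#' @param sampling_rate Sampling rate in Hz (sets the frequency axis only).
#' @return Numeric vector of length `n` with SD 1.
#' @export
pink_noise <- function(n, sampling_rate = 250) {
  w <- rnorm(n)
  X <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * sampling_rate / n
  f0 <- sampling_rate / n
  scale <- 1 / sqrt(pmax(f, f0))
  scale[1] <- 0
  x <- Re(fft(X * scale, inverse = TRUE)) / n
  x / sd(x)
}

#' Synthesize one multichannel EEG recording
#'
#' Each channel is a sum of a pink-noise floor, a 10 Hz alpha tone and a
#' 20 Hz beta tone with random phases, and a shared pink-noise source with
#' spatially smooth mixing weights.  The valence trajectory modulates the
#' frontal alpha amplitudes antisymmetrically (F3/F4 at full strength, F7/F8
#' at half strength); the arousal trajectory modulates the beta amplitude on
#' all channels.  Effect gains are multiplied by the profile's
#' `effect_multiplier`; amplitudes that would go negative are floored at 0
#' with a warning.
#'
#' @param profile A [subject_profile()].
#' @param trajectory An [make_trajectory()] result.
#' @param config A [generator_config()].
#' @param seed Integer stream seed.
#' @param song_id Song identifier stored with the recording.
#' @return An `eeg_recording`: list with `subject_id`, `song_id`, `signals`
#'   (12 x samples matrix, channel labels as rownames), `sampling_rate`,
#'   `channel_labels`.
#' @export
synthesize_recording <- function(profile, trajectory, config, seed,
                                 song_id = 1L) {
  set.seed(seed)
  fs <- config$sampling_rate
  n <- round(trajectory$duration * fs)
  t <- (seq_len(n) - 1) / fs
  labels <- config$channel_labels
  a_t <- trajectory_value(trajectory, t, "arousal")
  v_t <- trajectory_value(trajectory, t, "valence")
  sgn <- if (config$asym_positive_left_low) 1 else -1
  kv <- config$valence_asym_gain * profile$effect_multiplier
  ka <- config$arousal_beta_gain * profile$effect_multiplier

  # Spatially smooth shared-source mixing weights over the scalp grid.
  # Volume conduction is a fixed property of the head, so the weights are a
  # fixed function of the montage geometry, identical across recordings.
  layout <- default_grid_layout()
  pos <- layout$placement[match(labels, layout$placement$label), c("col", "row")]
  w <- config$shared_source_weight *
    exp(-((pos$col - 2)^2 + (pos$row - 1)^2) / (2 * 1.5^2))
  shared <- pink_noise(n, fs)

  asym <- function(label) {
    switch(label, F3 = -1, F4 = 1, F7 = -0.5, F8 = 0.5, 0) * sgn
  }
  # Oscillation phases follow a slow random walk (~0.5 Hz linewidth around
  # the nominal tone), as real narrowband rhythms do.  A constant phase
  # would make every window of a recording carry an identical tone template
  # (window lengths are whole multiples of the tone periods), turning the
  # oscillation into a recording fingerprint rather than a rhythm.
  phase_walk <- function(f0) {
    2 * pi * f0 * t + runif(1, 0, 2 * pi) + cumsum(rnorm(n, 0, 0.1))
  }
  clipped <- FALSE
  signals <- matrix(0, nrow = 12, ncol = n, dimnames = list(labels, NULL))
  for (i in seq_along(labels)) {
    noise <- pink_noise(n, fs) * config$noise_sd * profile$noise_scale
    a_alpha <- config$alpha_amp * (1 + asym(labels[i]) * kv * v_t)
    a_beta <- config$beta_amp * (1 + ka * a_t)
    if (any(a_alpha < 0) || any(a_beta < 0)) clipped <- TRUE
    a_alpha <- pmax(a_alpha, 0); a_beta <- pmax(a_beta, 0)
    signals[i, ] <- noise +
      a_alpha * sin(phase_walk(10)) +
      a_beta * sin(phase_walk(20)) +
      shared * w[i]
  }
  if (clipped)
    warning("effect gain drove an oscillation amplitude negative; floored at 0")
  signals <- signals * profile$gain
  new_recording(profile$subject_id, song_id, signals, fs, labels)
}

new_recording <- function(subject_id, song_id, signals, sampling_rate,
                          channel_labels) {
  stopifnot(nrow(signals) == 12L)
  structure(list(subject_id = subject_id, song_id = song_id,
                 signals = signals, sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, song %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$song_id, nrow(x$signals), ncol(x$signals),
              x$sampling_rate))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Draws one variability profile per subject and one
#' trajectory/annotation/recording triple per subject-song pair, with all
#' stream seeds derived deterministically from `config$master_seed`.  When
#' `out_dir` is given the recordings (RDS matrices), annotation CSVs, the
#' manifest CSV and the config are written there; an existing directory is
#' refused unless `overwrite = TRUE`.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory.
#' @param overwrite Allow writing into an existing `out_dir`.
#' @return An `eeg_dataset`: list with `recordings`, `annotations`,
#'   `trajectories`, `profiles`, `manifest` (one row per recording) and
#'   `config`.
#' @export
generate_dataset <- function(config, out_dir = NULL, overwrite = FALSE) {
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && !overwrite)
      stop("output directory exists; pass overwrite = TRUE to reuse it")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  ms <- config$master_seed
  subjects <- seq_len(config$n_subjects)
  profiles <- lapply(subjects, function(s)
    draw_subject_profile(s, config, child_seed(ms, "profile", s)))
  recordings <- list(); annotations <- list(); trajectories <- list()
  rows <- list()
  idx <- 0L
  for (s in subjects) {
    for (g in seq_len(config$n_songs_per_subject)) {
      idx <- idx + 1L
      traj <- make_trajectory(config, child_seed(ms, "trajectory", s, g))
      ann <- make_annotations(traj, config, child_seed(ms, "annotation", s, g))
      rec <- synthesize_recording(profiles[[s]], traj, config,
                                  child_seed(ms, "recording", s, g),
                                  song_id = g)
      key <- sprintf("s%02d_g%02d", s, g)
      recordings[[key]] <- rec
      annotations[[key]] <- ann
      trajectories[[key]] <- traj
      rec_path <- ann_path <- NA_character_
      if (!is.null(out_dir)) {
        # manifest paths are relative to out_dir so datasets are relocatable
        rec_path <- paste0(key, "_signals.rds")
        ann_path <- paste0(key, "_annotations.csv")
        saveRDS(rec, file.path(out_dir, rec_path))
        write.csv(ann, file.path(out_dir, ann_path), row.names = FALSE)
      }
      rows[[idx]] <- data.frame(subject_id = s, song_id = g,
                                recording_path = rec_path,
                                annotation_path = ann_path)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    yaml::write_yaml(unclass(config)[setdiff(names(config), "channel_labels")],
                     file.path(out_dir, "config.yml"))
  }
  structure(list(recordings = recordings, annotations = annotations,
                 trajectories = trajectories, profiles = profiles,
                 manifest = manifest, config = config),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d subjects x %d songs (%d recordings), %g s @ %g Hz\n",
              x$config$n_subjects, x$config$n_songs_per_subject,
              nrow(x$manifest), x$config$song_duration,
              x$config$sampling_rate))
  invisible(x)
}

#' Load a generated dataset from disk
#'
#' Reads back a dataset written by [generate_dataset()] (manifest CSV, RDS
#' signal matrices, annotation CSVs).  Latent trajectories are not part of
#' the on-disk layout; they exist only in-memory on freshly generated
#' datasets.
#'
#' @param dir Directory previously written by [generate_dataset()].
#' @return An `eeg_dataset` (without `trajectories` and `profiles`).
#' @export
load_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv under ", dir)
  manifest <- read.csv(mf_path)
  recordings <- list(); annotations <- list()
  for (i in seq_len(nrow(manifest))) {
    key <- sprintf("s%02d_g%02d", manifest$subject_id[i], manifest$song_id[i])
    recordings[[key]] <- readRDS(file.path(dir, manifest$recording_path[i]))
    ann <- read.csv(file.path(dir, manifest$annotation_path[i]))
    class(ann) <- c("annotation_trace", "data.frame")
    annotations[[key]] <- ann
  }
  cfg_path <- file.path(dir, "config.yml")
  config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  structure(list(recordings = recordings, annotations = annotations,
                 trajectories = NULL, profiles = NULL, manifest = manifest,
                 config = config),
            class = "eeg_dataset")
}
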