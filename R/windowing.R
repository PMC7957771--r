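#' Window specification
#'
#' Fixed-length segmentation parameters.  The window-size experiment uses
#' lengths 1-10 s without overlap; the electrode-sorting experiment fixes
#' 4 s windows with 1 s overlap.
#'
#' @param window_length Window length in seconds.
#' @param overlap Overlap between consecutive windows in seconds
#'   (`0 <= overlap < window_length`).
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_length, overlap = 0) {
  stopifnot(window_length > 0, overlap >= 0)
  if (overlap >= window_length) stop("overlap must be smaller than window_length")
  structure(list(window_length = window_length, overlap = overlap),
            class = "window_spec")
}

#' Segment a recording into fixed-length windows
#'
#' Windows start at 0 with stride `window_length - overlap`; every full
#' window is emitted and trailing partial samples are discarded, so the
#' count follows `floor((D - L) / (L - O)) + 1` for duration `D >= L`.
#'
#' @param recording An `eeg_recording`.
#' @param spec A [window_spec()].
#' @return List of windows, each a list with `start_time` (seconds) and
#'   `signals` (12 x L*fs matrix).  Empty list when the recording is shorter
#'   than one window.
#' @export
segment <- function(recording, spec) {
  fs <- recording$sampling_rate
  n <- ncol(recording$signals)
  len <- round(spec$window_length * fs)
  stride <- round((spec$window_length - spec$overlap) * fs)
  if (n < len) return(list())
  starts <- seq(0L, n - len, by = stride)
  lapply(starts, function(s0) {
    list(start_time = s0 / fs,
         signals = recording$signals[, (s0 + 1):(s0 + len), drop = FALSE])
  })
}

#' Binarize an arousal or valence coordinate
#'
#' Values above 0 map to the high/positive class, values at or below 0 to
#' low/negative (the boundary value 0 is assigned deterministically to the
#' low/negative class).
#'
#' @param value Numeric value(s) in `[-1, 1]`.
#' @param dimension `"arousal"` or `"valence"`.
#' @return Character class label(s): `"high"`/`"low"` for arousal,
#'   `"positive"`/`"negative"` for valence.
#' @export
binarize <- function(value, dimension = c("arousal", "valence")) {
  dimension <- match.arg(dimension)
  if (any(value < -1 | value > 1)) stop("annotation value outside [-1, 1]")
  pos <- if (dimension == "arousal") "high" else "positive"
  neg <- if (dimension == "arousal") "low" else "negative"
  ifelse(value > 0, pos, neg)
}

#' Label one window from an annotation trace
#'
#' Collects the click events falling inside the half-open span
#' `[start, start + length)` and takes, per dimension, the majority of their
#' binarized classes.  Ties are resolved by the sign of the mean raw value in
#' the window (mean `<= 0` maps to low/negative).  A window containing no
#' clicks inherits the last click before its start; if no prior click exists
#' the window is dropped (`NULL`).
#'
#' @param start Window start time in seconds.
#' @param window_length Window length in seconds.
#' @param annotations An `annotation_trace` data frame.
#' @return List with `arousal_class` and `valence_class`, or `NULL` when the
#'   window cannot be labelled.
#' @export
label_window <- function(start, window_length, annotations) {
  inside <- annotations$time_s >= start & annotations$time_s < start + window_length
  if (!any(inside)) {
    before <- which(annotations$time_s < start)
    if (!length(before)) return(NULL)
    ev <- annotations[max(before), , drop = FALSE]
  } else {
    ev <- annotations[inside, , drop = FALSE]
  }
  one <- function(values, dimension) {
    cls <- binarize(values, dimension)
    pos <- if (dimension == "arousal") "high" else "positive"
    neg <- if (dimension == "arousal") "low" else "negative"
    n_pos <- sum(cls == pos); n_neg <- sum(cls == neg)
    if (n_pos > n_neg) pos
    else if (n_neg > n_pos) neg
    else if (mean(values) > 0) pos else neg
  }
  list(arousal_class = one(ev$arousal, "arousal"),
       valence_class = one(ev$valence, "valence"))
}

#' Build a labelled windowed dataset
#'
#' Composes [segment()] and [label_window()] over every recording of an
#' `eeg_dataset` (or matched recording/annotation lists).  Recordings
#' without an annotation trace are skipped and reported; unlabelled windows
#' are dropped and counted.
#'
#' @param dataset An `eeg_dataset`, or a list of `eeg_recording`s.
#' @param spec A [window_spec()].
#' @param annotations When `dataset` is a plain recording list: a list of
#'   annotation traces with matching names.
#' @return A `windowed_dataset`: list with `X` (array
#'   `c(12, L*fs, n_windows)`), `meta` (data frame `subject_id`, `song_id`,
#'   `start_s`, `arousal_class`, `valence_class`), `window_spec`,
#'   `channel_labels`, `n_dropped`, and `errors` (character vector of skipped
#'   recordings).
#' @export
build_dataset <- function(dataset, spec, annotations = NULL) {
  if (inherits(dataset, "eeg_dataset")) {
    recordings <- dataset$recordings
    annotations <- dataset$annotations
  } else {
    recordings <- dataset
    if (is.null(annotations)) stop("annotations must be supplied")
  }
  sigs <- list(); meta <- list(); errors <- character(0)
  n_dropped <- 0L
  for (key in names(recordings)) {
    rec <- recordings[[key]]
    ann <- annotations[[key]]
    if (is.null(ann)) {
      errors <- c(errors, sprintf("recording %s has no annotation trace", key))
      next
    }
    for (w in segment(rec, spec)) {
      lab <- label_window(w$start_time, spec$window_length, ann)
      if (is.null(lab)) { n_dropped <- n_dropped + 1L; next }
      sigs[[length(sigs) + 1L]] <- w$signals
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = rec$subject_id, song_id = rec$song_id,
        start_s = w$start_time,
        arousal_class = lab$arousal_class,
        valence_class = lab$valence_class)
    }
  }
  if (!length(sigs)) stop("no labelled windows could be built")
  len <- ncol(sigs[[1]])
  X <- array(unlist(sigs, use.names = FALSE), dim = c(12L, len, length(sigs)),
             dimnames = list(rownames(sigs[[1]]), NULL, NULL))
  structure(list(X = X, meta = do.call(rbind, meta), window_spec = spec,
                 channel_labels = rownames(sigs[[1]]),
                 n_dropped = n_dropped, errors = errors),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows of %g s (overlap %g s), %d subjects; %d dropped\n",
              dim(x$X)[3], x$window_spec$window_length, x$window_spec$overlap,
              length(unique(x$meta$subject_id)), x$n_dropped))
  invisible(x)
}

# Subset a windowed dataset by window indices (internal).
subset_windows <- function(wd, idx) {
  wd$X <- wd$X[, , idx, drop = FALSE]
  wd$meta <- wd$meta[idx, , drop = FALSE]
  rownames(wd$meta) <- NULL
  wd
}

#' Write a windowed dataset to disk
#'
#' One tensor file (RDS array) plus a CSV label table with the window
#' metadata (`subject_id`, `song_id`, `start_s`, `arousal_class`,
#' `valence_class`).
#'
#' @param wd A `windowed_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_windowed_dataset <- function(wd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(wd$X, file.path(dir, "windows.rds"))
  write.csv(wd$meta, file.path(dir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(list(window_length = wd$window_spec$window_length,
                        overlap = wd$window_spec$overlap,
                        n_dropped = wd$n_dropped),
                   file.path(dir, "windows.yml"))
  invisible(dir)
}

#' Read a windowed dataset written by [write_windowed_dataset()]
#'
#' @param dir Directory containing `windows.rds`, `labels.csv`,
#'   `windows.yml`.
#' @return A `windowed_dataset`.
#' @export
read_windowed_dataset <- function(dir) {
  X <- readRDS(file.path(dir, "windows.rds"))
  meta <- read.csv(file.path(dir, "labels.csv"))
  info <- yaml::read_yaml(file.path(dir, "windows.yml"))
  structure(list(X = X, meta = meta,
                 window_spec = window_spec(info$window_length, info$overlap),
                 channel_labels = dimnames(X)[[1]],
                 n_dropped = info$n_dropped, errors = character(0)),
            class = "windowed_dataset")
}
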