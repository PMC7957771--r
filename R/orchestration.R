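`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiment configuration
#'
#' Bundles everything one of the three experiment drivers needs.  The
#' default generator profile is a reduced cohort (6 subjects, 4 songs of
#' 60 s) that keeps a full driver run desk-sized; the study-scale profile
#' (12 subjects, 16 songs, 120 s) is available by passing the corresponding
#' [generator_config()].
#'
#' @param generator A [generator_config()].
#' @param filter A [filter_spec()].
#' @param experiment One of `"window_size"`, `"electrode_sorting"`,
#'   `"subject_dependent"`.
#' @param window_lengths Window lengths in seconds (window-size and
#'   subject-dependent experiments; no overlap).
#' @param sorting_window Length-2 vector (length, overlap) for the sorting
#'   experiment; deviating from the protocol's 4 s / 1 s draws a warning.
#' @param arrangements Arrangements evaluated by the sorting experiment.
#' @param architectures Architecture names to evaluate.
#' @param train A [train_config()].
#' @param n_random Number of seeded random orderings averaged into the
#'   sorting benchmark.
#' @param kfold_k Folds for the subject-dependent protocol.
#' @param out_dir Optional output directory for the CSV tables.
#' @param master_seed Master seed; all per-cell seeds derive from it.
#' @param trainer_factory Optional `function(architecture, mode)` returning
#'   a trainer (see [cnn_trainer()]); defaults to the CNN trainer.  Injecting
#'   a light-weight classifier here exercises the full protocol cheaply.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(generator = generator_config(
                                n_subjects = 6, n_songs_per_subject = 4,
                                song_duration = 60),
                              filter = filter_spec(),
                              experiment = c("window_size",
                                             "electrode_sorting",
                                             "subject_dependent"),
                              window_lengths = 1:10,
                              sorting_window = c(4, 1),
                              arrangements = c("random", "physical3d",
                                               "maxcbo", "mincbo"),
                              architectures = cnn_architectures(),
                              train = train_config(seed = 1L),
                              n_random = 20L,
                              kfold_k = 10L,
                              out_dir = NULL,
                              master_seed = 1L,
                              trainer_factory = NULL) {
  experiment <- match.arg(experiment)
  if (experiment == "electrode_sorting" &&
      !isTRUE(all.equal(sorting_window, c(4, 1))))
    warning("sorting experiment protocol uses 4 s windows with 1 s overlap; ",
            "running with a deviating window")
  stopifnot(all(window_lengths > 0), n_random >= 1, kfold_k >= 2)
  structure(list(generator = generator, filter = filter,
                 experiment = experiment,
                 window_lengths = window_lengths,
                 sorting_window = sorting_window,
                 arrangements = arrangements,
                 architectures = architectures, train = train,
                 n_random = as.integer(n_random),
                 kfold_k = as.integer(kfold_k),
                 out_dir = out_dir,
                 master_seed = as.integer(master_seed),
                 trainer_factory = trainer_factory),
            class = "experiment_config")
}

config_hash <- function(config) {
  slim <- unclass(config)
  slim$trainer_factory <- if (is.null(config$trainer_factory)) "cnn" else "custom"
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(slim), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

get_trainer <- function(config, architecture, mode) {
  fac <- config$trainer_factory %||%
    function(a, m) cnn_trainer(a, m, config$train)
  fac(architecture, mode)
}

prepare_dataset <- function(config) {
  ds <- generate_dataset(config$generator)
  preprocess_dataset(ds, config$filter)
}

write_tables <- function(tables, out_dir, prefix) {
  if (is.null(out_dir)) return(invisible(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(tables), "provenance"))
    write.csv(tables[[nm]], file.path(out_dir, sprintf("%s_%s.csv", prefix, nm)),
              row.names = FALSE)
  jsonlite::write_json(tables$provenance,
                       file.path(out_dir, sprintf("%s_provenance.json", prefix)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tables)
}

with_condition_context <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("condition [%s] failed: %s", label, conditionMessage(e)),
         call. = FALSE))
}

#' Run the window-size experiment
#'
#' For every architecture x window length (no overlap) x emotion dimension,
#' runs LOSO cross-validation, then compares every longer window against the
#' shortest one per architecture with the Wilcoxon signed-rank test on the
#' per-subject MCC vectors, correcting over the full per-dimension family
#' (lengths-1 comparisons per model x models) with BH-FDR.
#'
#' @param config An [experiment_config()].
#' @return List of tables: `results` (per-cell means, pooled metrics and the
#'   cross-architecture average rows), `per_subject` (long format), `stats`
#'   (comparison, W, p, q, significance), `provenance`.  Written as CSV/JSON
#'   when `config$out_dir` is set.
#' @export
run_window_size_experiment <- function(config) {
  hash <- config_hash(config)
  ms <- config$master_seed
  ds <- prepare_dataset(config)
  results <- list(); per_subject <- list(); stats_rows <- list()
  counts_log <- list()
  cell <- list()  # per (dim, arch, L): experiment_result
  for (L in config$window_lengths) {
    wd <- with_condition_context(sprintf("windowing L=%g", L),
                                 build_dataset(ds, window_spec(L, 0)))
    counts_log[[as.character(L)]] <- list(windows = dim(wd$X)[3],
                                          dropped = wd$n_dropped)
    for (dim_ in c("arousal", "valence")) {
      for (arch in config$architectures) {
        label <- sprintf("%s/%s/L=%g", dim_, arch, L)
        res <- with_condition_context(label,
          loso_cv(wd, dim_, arrangement = list(method = "none"),
                  trainer = get_trainer(config, arch, "2D"),
                  seed = child_seed(ms, dim_, arch, L)))
        cell[[paste(dim_, arch, L, sep = "|")]] <- res
        results[[length(results) + 1L]] <- data.frame(
          dimension = dim_, architecture = arch, window_length = L,
          mean_accuracy = res$mean_accuracy, mean_mcc = res$mean_mcc,
          pooled_accuracy = res$pooled$accuracy, pooled_mcc = res$pooled$mcc,
          n_windows = dim(wd$X)[3], config_hash = hash, seed = ms)
        per_subject[[length(per_subject) + 1L]] <- data.frame(
          dimension = dim_, architecture = arch, window_length = L,
          subject_id = res$per_subject$id,
          accuracy = res$per_subject$accuracy, mcc = res$per_subject$mcc,
          config_hash = hash, seed = ms)
      }
    }
  }
  results <- do.call(rbind, results)
  # cross-architecture average rows
  avg <- do.call(rbind, lapply(split(results,
                                     results[c("dimension", "window_length")]),
    function(g) data.frame(dimension = g$dimension[1],
                           architecture = "Average",
                           window_length = g$window_length[1],
                           mean_accuracy = mean(g$mean_accuracy),
                           mean_mcc = mean(g$mean_mcc),
                           pooled_accuracy = mean(g$pooled_accuracy),
                           pooled_mcc = mean(g$pooled_mcc),
                           n_windows = g$n_windows[1],
                           config_hash = hash, seed = ms)))
  results <- rbind(results, avg)
  rownames(results) <- NULL

  base_L <- min(config$window_lengths)
  for (dim_ in c("arousal", "valence")) {
    rows <- list()
    for (arch in config$architectures) {
      base <- cell[[paste(dim_, arch, base_L, sep = "|")]]
      for (L in setdiff(config$window_lengths, base_L)) {
        res <- cell[[paste(dim_, arch, L, sep = "|")]]
        w <- wilcoxon_signed_rank(res$per_subject$mcc, base$per_subject$mcc)
        rows[[length(rows) + 1L]] <- data.frame(
          dimension = dim_, architecture = arch,
          comparison = sprintf("L=%g vs L=%g", L, base_L),
          statistic = w$statistic, p = w$p_value, n = w$n)
      }
    }
    fam <- do.call(rbind, rows)
    fc <- fdr_correct(fam$p, q_level = 0.05)
    fam$q <- fc$q_values
    fam$significant <- fc$reject
    fam$family_m <- nrow(fam)
    fam$config_hash <- hash; fam$seed <- ms
    stats_rows[[dim_]] <- fam
  }
  tables <- list(results = results,
                 table_arousal = format_results_wide(results, "arousal"),
                 table_valence = format_results_wide(results, "valence"),
                 per_subject = do.call(rbind, per_subject),
                 stats = do.call(rbind, stats_rows),
                 provenance = list(experiment = "window_size",
                                   config_hash = hash, master_seed = ms,
                                   window_lengths = config$window_lengths,
                                   architectures = config$architectures,
                                   stage_counts = counts_log))
  rownames(tables$stats) <- NULL
  write_tables(tables, config$out_dir, "window_size")
}

#' Run the electrode-sorting experiment
#'
#' Evaluates the random-order benchmark (averaged over `n_random` seeded
#' permutations), the 3D physical grid order, MaxCBO and MinCBO, for every
#' architecture and both dimensions, with LOSO on 4 s windows overlapped by
#' 1 s.  Each non-random arrangement is compared against the random
#' benchmark (Wilcoxon on per-subject MCC, BH-FDR over the per-dimension
#' family of 3 comparisons per model x models).
#'
#' @param config An [experiment_config()].
#' @return List of tables (`results`, `per_subject`, `stats`, `provenance`).
#' @export
run_sorting_experiment <- function(config) {
  hash <- config_hash(config)
  ms <- config$master_seed
  ds <- prepare_dataset(config)
  wd <- build_dataset(ds, window_spec(config$sorting_window[1],
                                      config$sorting_window[2]))
  random_seeds <- vapply(seq_len(config$n_random), function(i)
    child_seed(ms, "random-order", i), integer(1))
  random_orders <- lapply(random_seeds, function(s)
    order_random(wd$channel_labels, s)$order)

  results <- list(); per_subject <- list(); stats_rows <- list()
  per_subject_random <- list()  # dim|arch -> per-subject MCC/acc averaged over seeds
  cell <- list()
  for (dim_ in c("arousal", "valence")) {
    for (arch in config$architectures) {
      for (arr in config$arrangements) {
        mode <- if (arr == "physical3d") "3D" else "2D"
        label <- sprintf("%s/%s/%s", dim_, arch, arr)
        if (arr == "random") {
          runs <- lapply(seq_along(random_seeds), function(i)
            with_condition_context(sprintf("%s#%d", label, i),
              loso_cv(wd, dim_,
                      arrangement = list(method = "random",
                                         seed = random_seeds[i]),
                      trainer = get_trainer(config, arch, mode),
                      seed = child_seed(ms, dim_, arch, arr, i))))
          acc <- rowMeans(sapply(runs, function(r) r$per_subject$accuracy))
          mc <- rowMeans(sapply(runs, function(r) r$per_subject$mcc))
          subj <- runs[[1]]$per_subject$id
          key <- paste(dim_, arch, sep = "|")
          per_subject_random[[key]] <- data.frame(id = subj, accuracy = acc,
                                                  mcc = mc)
          results[[length(results) + 1L]] <- data.frame(
            dimension = dim_, architecture = arch, arrangement = arr,
            mean_accuracy = mean(acc), mean_mcc = mean(mc),
            pooled_accuracy = mean(sapply(runs, function(r) r$pooled$accuracy)),
            pooled_mcc = mean(sapply(runs, function(r) r$pooled$mcc)),
            n_runs = length(runs), config_hash = hash, seed = ms)
          per_subject[[length(per_subject) + 1L]] <- data.frame(
            dimension = dim_, architecture = arch, arrangement = arr,
            subject_id = subj, accuracy = acc, mcc = mc,
            config_hash = hash, seed = ms)
        } else {
          res <- with_condition_context(label,
            loso_cv(wd, dim_, arrangement = list(method = arr),
                    trainer = get_trainer(config, arch, mode),
                    seed = child_seed(ms, dim_, arch, arr)))
          cell[[paste(dim_, arch, arr, sep = "|")]] <- res
          results[[length(results) + 1L]] <- data.frame(
            dimension = dim_, architecture = arch, arrangement = arr,
            mean_accuracy = res$mean_accuracy, mean_mcc = res$mean_mcc,
            pooled_accuracy = res$pooled$accuracy,
            pooled_mcc = res$pooled$mcc, n_runs = 1L,
            config_hash = hash, seed = ms)
          per_subject[[length(per_subject) + 1L]] <- data.frame(
            dimension = dim_, architecture = arch, arrangement = arr,
            subject_id = res$per_subject$id,
            accuracy = res$per_subject$accuracy, mcc = res$per_subject$mcc,
            config_hash = hash, seed = ms)
        }
      }
    }
  }
  results <- do.call(rbind, results)
  avg <- do.call(rbind, lapply(split(results,
                                     results[c("dimension", "arrangement")]),
    function(g) data.frame(dimension = g$dimension[1],
                           architecture = "Average",
                           arrangement = g$arrangement[1],
                           mean_accuracy = mean(g$mean_accuracy),
                           mean_mcc = mean(g$mean_mcc),
                           pooled_accuracy = mean(g$pooled_accuracy),
                           pooled_mcc = mean(g$pooled_mcc),
                           n_runs = sum(g$n_runs), config_hash = hash,
                           seed = ms)))
  results <- rbind(results, avg)
  rownames(results) <- NULL

  non_random <- setdiff(config$arrangements, "random")
  if (length(non_random) && "random" %in% config$arrangements) {
    for (dim_ in c("arousal", "valence")) {
      rows <- list()
      for (arch in config$architectures) {
        bench <- per_subject_random[[paste(dim_, arch, sep = "|")]]
        for (arr in non_random) {
          res <- cell[[paste(dim_, arch, arr, sep = "|")]]
          w <- wilcoxon_signed_rank(res$per_subject$mcc, bench$mcc)
          rows[[length(rows) + 1L]] <- data.frame(
            dimension = dim_, architecture = arch,
            comparison = sprintf("%s vs random", arr),
            statistic = w$statistic, p = w$p_value, n = w$n)
        }
      }
      fam <- do.call(rbind, rows)
      fc <- fdr_correct(fam$p, q_level = 0.05)
      fam$q <- fc$q_values
      fam$significant <- fc$reject
      fam$family_m <- nrow(fam)
      fam$config_hash <- hash; fam$seed <- ms
      stats_rows[[dim_]] <- fam
    }
  }
  tables <- list(results = results,
                 table_arousal = format_results_wide(results, "arousal",
                                                     "arrangement"),
                 table_valence = format_results_wide(results, "valence",
                                                     "arrangement"),
                 per_subject = do.call(rbind, per_subject),
                 stats = if (length(stats_rows)) do.call(rbind, stats_rows) else NULL,
                 provenance = list(experiment = "electrode_sorting",
                                   config_hash = hash, master_seed = ms,
                                   sorting_window = config$sorting_window,
                                   n_random = config$n_random,
                                   random_seeds = random_seeds,
                                   random_orders = random_orders,
                                   architectures = config$architectures,
                                   n_windows = dim(wd$X)[3]))
  if (!is.null(tables$stats)) rownames(tables$stats) <- NULL
  tables[vapply(tables, is.null, TRUE)] <- NULL
  write_tables(tables, config$out_dir, "sorting")
}

#' Run the subject-dependent experiment
#'
#' Stratified 10-fold cross-validation within each subject, per window
#' length and dimension; exports the per-subject metric-versus-window-length
#' curves and their means.
#'
#' @param config An [experiment_config()].
#' @return List of tables (`results`, `curves`, `provenance`).
#' @export
run_subject_dependent <- function(config) {
  hash <- config_hash(config)
  ms <- config$master_seed
  ds <- prepare_dataset(config)
  rows <- list(); skipped <- character(0)
  for (L in config$window_lengths) {
    wd <- build_dataset(ds, window_spec(L, 0))
    for (s in sort(unique(wd$meta$subject_id))) {
      wds <- subset_windows(wd, which(wd$meta$subject_id == s))
      if (dim(wds$X)[3] < config$kfold_k) {
        skipped <- c(skipped, sprintf("subject %s at L=%g (%d windows < k=%d)",
                                      s, L, dim(wds$X)[3], config$kfold_k))
        next
      }
      for (dim_ in c("arousal", "valence")) {
        for (arch in config$architectures) {
          label <- sprintf("%s/%s/subject %s/L=%g", dim_, arch, s, L)
          res <- with_condition_context(label,
            kfold_cv(wds, dim_, k = config$kfold_k,
                     trainer = get_trainer(config, arch, "2D"),
                     seed = child_seed(ms, dim_, arch, s, L)))
          rows[[length(rows) + 1L]] <- data.frame(
            dimension = dim_, architecture = arch, subject_id = s,
            window_length = L, mean_accuracy = res$mean_accuracy,
            mean_mcc = res$mean_mcc, pooled_accuracy = res$pooled$accuracy,
            pooled_mcc = res$pooled$mcc, config_hash = hash, seed = ms)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  curves <- do.call(rbind, lapply(
    split(results, results[c("dimension", "architecture", "window_length")]),
    function(g) data.frame(dimension = g$dimension[1],
                           architecture = g$architecture[1],
                           window_length = g$window_length[1],
                           mean_mcc = mean(g$pooled_mcc),
                           mean_accuracy = mean(g$pooled_accuracy),
                           n_subjects = nrow(g),
                           config_hash = g$config_hash[1], seed = ms)))
  rownames(curves) <- NULL
  tables <- list(results = results, curves = curves,
                 provenance = list(experiment = "subject_dependent",
                                   config_hash = hash, master_seed = ms,
                                   kfold_k = config$kfold_k,
                                   skipped = skipped))
  write_tables(tables, config$out_dir, "subject_dependent")
}

#' Pivot a long results table into the report layout
#'
#' Rows are architectures (plus the cross-architecture average), columns the
#' manipulated condition (window length or arrangement), cells formatted as
#' `accuracy (mcc)`.
#'
#' @param results Long results table from one of the experiment drivers.
#' @param dimension Emotion dimension to pivot.
#' @param condition Column name holding the condition
#'   (`"window_length"` or `"arrangement"`).
#' @param use `"mean"` (per-subject means) or `"pooled"` counts metrics.
#' @return A data frame, one row per architecture.
#' @export
format_results_wide <- function(results, dimension,
                                condition = "window_length",
                                use = c("mean", "pooled")) {
  use <- match.arg(use)
  acc_col <- paste0(use, "_accuracy")
  mcc_col <- paste0(use, "_mcc")
  sub <- results[results$dimension == dimension, ]
  conds <- sort(unique(sub[[condition]]))
  archs <- unique(sub$architecture)
  archs <- c(setdiff(archs, "Average"), intersect("Average", archs))
  out <- data.frame(architecture = archs)
  for (cv in conds) {
    cells <- vapply(archs, function(a) {
      row <- sub[sub$architecture == a & sub[[condition]] == cv, ]
      if (!nrow(row)) return(NA_character_)
      sprintf("%.2f (%.4f)", row[[acc_col]][1], row[[mcc_col]][1])
    }, character(1))
    out[[as.character(cv)]] <- cells
  }
  out
}
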