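cheap_factory <- function(architecture, mode) centroid_trainer()

smoke_config <- function(experiment, out_dir = NULL, ...) {
  experiment_config(
    generator = tiny_config(master_seed = 21),
    experiment = experiment,
    window_lengths = c(2, 5),
    architectures = c("3Conv", "4Conv"),
    train = train_config(seed = 1),
    n_random = 3,
    kfold_k = 4,
    out_dir = out_dir,
    master_seed = 21,
    trainer_factory = cheap_factory,
    ...)
}

test_that("the window-size experiment covers its full condition grid", {
  out <- file.path(tempdir(), "eegemo-ws")
  on.exit(unlink(out, recursive = TRUE))
  tb <- run_window_size_experiment(smoke_config("window_size", out))
  res <- tb$results
  # 2 architectures x 2 lengths x 2 dimensions + average rows
  expect_equal(sum(res$architecture != "Average"), 8)
  expect_equal(sum(res$architecture == "Average"), 4)
  expect_true(all(c("mean_accuracy", "mean_mcc", "pooled_accuracy",
                    "pooled_mcc", "config_hash", "seed") %in% names(res)))
  # per dimension: (lengths - 1) x architectures comparisons
  expect_equal(nrow(tb$stats), 2 * 1 * 2)
  expect_true(all(tb$stats$family_m == 2))
  expect_true(all(file.exists(file.path(out,
    c("window_size_results.csv", "window_size_per_subject.csv",
      "window_size_stats.csv", "window_size_provenance.json")))))
})

test_that("identical configs reproduce identical result tables", {
  t1 <- run_window_size_experiment(smoke_config("window_size"))
  t2 <- run_window_size_experiment(smoke_config("window_size"))
  expect_identical(t1$results, t2$results)
  expect_identical(t1$per_subject, t2$per_subject)
  expect_identical(t1$stats, t2$stats)
})

test_that("the sorting experiment benchmarks against seeded random orders", {
  cfgs <- smoke_config("electrode_sorting")
  cfgs$window_lengths <- NULL
  tb <- run_sorting_experiment(cfgs)
  res <- tb$results
  expect_setequal(unique(res$arrangement),
                  c("random", "physical3d", "maxcbo", "mincbo"))
  # table mirrors the arrangement x (architectures + average) layout
  expect_equal(nrow(res), 2 * 4 * 2 + 2 * 4)
  rnd <- res[res$arrangement == "random" & res$architecture != "Average", ]
  expect_true(all(rnd$n_runs == 3))
  expect_length(tb$provenance$random_seeds, 3)
  expect_length(tb$provenance$random_orders, 3)
  expect_false(any(duplicated(tb$provenance$random_seeds)))
  for (o in tb$provenance$random_orders) expect_setequal(o, eeg_channels())
  # per dimension: 3 non-random arrangements x 2 architectures comparisons
  expect_equal(nrow(tb$stats), 2 * 3 * 2)
})

test_that("a deviating sorting window is allowed but warned about", {
  expect_warning(smoke_config("electrode_sorting", sorting_window = c(2, 0)),
                 "4 s windows")
})

test_that("the subject-dependent experiment produces per-subject curves", {
  tb <- run_subject_dependent(smoke_config("subject_dependent"))
  res <- tb$results
  # 2 subjects x 2 lengths x 2 dimensions x 2 architectures
  expect_equal(nrow(res), 16)
  expect_true(all(res$window_length %in% c(2, 5)))
  curves <- tb$curves
  expect_equal(nrow(curves), 2 * 2 * 2)
  expect_true(all(c("mean_mcc", "n_subjects") %in% names(curves)))
  expect_equal(unique(curves$n_subjects), 2)
})

test_that("the command-line dispatcher generates a dataset from a config", {
  cli <- system.file("cli", "eegemo.R", package = "eegemo")
  skip_if(cli == "", "CLI script not installed")
  out <- file.path(tempdir(), "eegemo-cli-out")
  on.exit(unlink(out, recursive = TRUE))
  cfg_file <- file.path(tempdir(), "eegemo-cli.yml")
  yaml::write_yaml(list(n_subjects = 1, n_songs_per_subject = 1,
                        song_duration = 4, block_duration = c(2, 3),
                        master_seed = 5), cfg_file)
  res <- system2("Rscript", c(cli, "generate", "--config", cfg_file,
                              "--out", out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  mf <- read.csv(file.path(out, "manifest.csv"))
  expect_equal(nrow(mf), 1)
})

test_that("the wide report layout mirrors architecture-by-condition cells", {
  res <- data.frame(dimension = "valence",
                    architecture = rep(c("3Conv", "Average"), each = 2),
                    window_length = rep(c(1, 2), 2),
                    mean_accuracy = c(60, 70, 55, 65),
                    mean_mcc = c(0.2, 0.4, 0.1, 0.3),
                    pooled_accuracy = c(60, 70, 55, 65),
                    pooled_mcc = c(0.2, 0.4, 0.1, 0.3))
  w <- format_results_wide(res, "valence")
  expect_equal(w$architecture, c("3Conv", "Average"))
  expect_equal(w[["1"]], c("60.00 (0.2000)", "55.00 (0.1000)"))
  expect_equal(w[["2"]], c("70.00 (0.4000)", "65.00 (0.3000)"))
})
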