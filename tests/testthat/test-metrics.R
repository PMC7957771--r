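cc <- function(tp, tn, fp, fn)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")

test_that("accuracy and MCC match their closed forms on worked examples", {
  expect_equal(accuracy(cc(5, 5, 0, 0)), 100)
  expect_equal(accuracy(cc(3, 4, 2, 1)), 70)
  expect_equal(accuracy(cc(0, 0, 5, 5)), 0)
  expect_equal(mcc(cc(5, 5, 0, 0)), 1)
  expect_equal(mcc(cc(3, 4, 2, 1)), 10 / sqrt(600))  # 0.40825
  expect_equal(mcc(cc(0, 4, 0, 6)), 0)  # one-class predictor -> chance level
  expect_error(accuracy(cc(0, 0, 0, 0)), "empty")
  expect_error(mcc(cc(0, 0, 0, 0)), "empty")
})

test_that("metrics agree with direct formula evaluation on random tables", {
  set.seed(1)
  for (i in 1:200) {
    k <- cc(rpois(1, 5), rpois(1, 5), rpois(1, 5), rpois(1, 5))
    if (eegemo:::counts_total(k) == 0) next
    expect_equal(accuracy(k), 100 * (k$TP + k$TN) / (k$TP + k$TN + k$FP + k$FN))
    den <- (k$TP + k$FP) * (k$TP + k$FN) * (k$TN + k$FP) * (k$TN + k$FN)
    want <- if (den == 0) 0 else (k$TP * k$TN - k$FP * k$FN) / sqrt(den)
    expect_equal(mcc(k), want)
    expect_gte(mcc(k), -1)
    expect_lte(mcc(k), 1)
  }
})

test_that("confusion counts classify each prediction once", {
  truth <- c(1, 1, 0, 0, 1)
  pred <- c(1, 0, 0, 1, 1)
  k <- confusion_counts(truth, pred, positive = 1)
  expect_equal(unlist(k[c("TP", "TN", "FP", "FN")]),
               c(TP = 2, TN = 1, FP = 1, FN = 1))
  expect_equal(eegemo:::counts_total(k), 5)
})

test_that("exact Wilcoxon signed-rank matches enumeration and the reference", {
  # five all-positive differences: two-sided exact p = 2/2^5
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r$p_value, 0.0625)
  expect_equal(r$statistic, 15)
  expect_true(r$exact)

  # identical vectors
  r0 <- wilcoxon_signed_rank(1:4, 1:4)
  expect_equal(r0$p_value, 1)
  expect_match(r0$note, "zero")

  # symmetric in the argument order
  set.seed(3)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)

  # cross-check against the independent implementation on tie-free data
  set.seed(9)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Kruskal-Wallis matches hand ranks and the reference", {
  # {1,2,3} vs {4,5,6}: ranks 1..6, H = 3.857 (no ties)
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  # rank-based: invariant under monotone transforms
  g <- list(rnorm(6)^2 + 1, rnorm(5)^2 + 2, rnorm(7)^2)
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, log))$statistic)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
  set.seed(4)
  for (i in 1:50) {
    g <- lapply(seq_len(sample(2:4, 1)), function(j) rnorm(sample(4:9, 1)))
    ours <- kruskal_wallis(g)
    x <- unlist(g); grp <- factor(rep(seq_along(g), lengths(g)))
    ref <- kruskal.test(x, grp)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("BH step-up rejections and q-values follow the definition", {
  r <- fdr_correct(c(0.01, 0.02, 0.03, 0.04), q_level = 0.05)
  expect_true(all(r$reject))  # thresholds 0.0125, 0.025, 0.0375, 0.05
  r1 <- fdr_correct(rep(1, 5))
  expect_false(any(r1$reject))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")

  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    r <- fdr_correct(p, q_level = 0.05)
    # step-up definition computed directly
    o <- order(p)
    k <- max(c(0, which(p[o] <= seq_along(p) / length(p) * 0.05)))
    manual <- logical(length(p))
    if (k > 0) manual[o[seq_len(k)]] <- TRUE
    expect_identical(r$reject, manual)
    expect_equal(r$q_values, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(diff(r$q_values[o]) > -1e-12))  # monotone in sorted p
  }
})

test_that("a stated family size m enters the thresholds", {
  # p = 0.02 alone passes at m = 1 but not at m = 36
  expect_true(fdr_correct(0.02, 0.05, m = 1)$reject)
  expect_false(fdr_correct(0.02, 0.05, m = 36)$reject)
})
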