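test_that("score scaling maps to [0, 1] affinely and preserves order", {
  expect_equal(scale_scores(c(0.2, 0.6, 1.0)), c(0, 0.5, 1))
  expect_equal(scale_scores(c(0, 0.3, 1)), c(0, 0.3, 1))
  expect_warning(z <- scale_scores(rep(2, 5)), "constant")
  expect_equal(z, rep(0, 5))
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(1000)
    expect_equal(order(scale_scores(x)), order(x))
  }
})

test_that("confusion counts match a brute-force tally and boundary cases", {
  set.seed(32)
  es <- evaluation_set(runif(500), rbinom(500, 1, 0.3), hours = 1)
  n_pos <- sum(es$labels == 1)
  c0 <- confusion_at_threshold(es, 0)
  expect_equal(unname(c0["FN"]), 0)
  expect_equal(unname(c0["TP"]), n_pos)
  expect_equal(unname(c0["TN"]), 0)
  chigh <- confusion_at_threshold(es, max(es$scores) + 1e-9)
  expect_equal(unname(chigh["TP"] + chigh["FP"]), 0)
  for (t in runif(10)) {
    cm <- confusion_at_threshold(es, t)
    expect_equal(sum(cm), 500)
    # per-item oracle
    expect_equal(unname(cm["TP"]), sum(es$scores >= t & es$labels == 1))
    expect_equal(unname(cm["FP"]), sum(es$scores >= t & es$labels == 0))
  }
})

test_that("prior calibration satisfies its algebraic identities and the worked case", {
  # hand evaluation: r = 0.8, f = 0.1, pi = 0.5 -> 8/9
  cal <- calibrate_counts(TP = 80, FN = 20, FP = 30, TN = 270, target_prior = 0.5)
  expect_equal(cal$precision_cal, 8 / 9)
  expect_equal(cal$recall, 0.8)
  # calibration at the empirical prior reproduces raw precision
  TP <- 40; FN <- 10; FP <- 25; TN <- 125
  pi_emp <- (TP + FN) / (TP + FN + FP + TN)
  cal2 <- calibrate_counts(TP, FP, FN, TN, target_prior = pi_emp)
  expect_equal(cal2$precision_cal, TP / (TP + FP))
  # no false positives -> calibrated precision 1
  expect_equal(calibrate_counts(10, 0, 5, 100, 0.3)$precision_cal, 1)
  # monotone increasing in the target prior for fixed (r, f)
  ps <- sapply(seq(0.05, 0.95, 0.1),
               function(p) calibrate_counts(80, 30, 20, 270, p)$precision_cal)
  expect_true(all(diff(ps) > 0))
  # degenerate margins yield NA markers, not errors
  expect_true(is.na(calibrate_counts(0, 5, 0, 95, 0.5)$precision_cal))
})

test_that("AUC-PR and peak F1 equal brute-force threshold sweeps on random sets", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(20:80, 1)
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # force some ties
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    es <- evaluation_set(scores, labels, hours = 1)
    cv <- pr_curve(es)
    expect_equal(auc_pr(cv), brute_auc_pr(scores, labels), tolerance = 1e-12)
    expect_equal(peak_f1(cv)$f1, brute_peak_f1(scores, labels), tolerance = 1e-12)
  }
})

test_that("perfect separation yields AUC-PR and peak F1 of 1; random scores approach the prior", {
  es <- evaluation_set(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), hours = 1)
  cv <- pr_curve(es)
  expect_equal(auc_pr(cv), 1)
  expect_equal(peak_f1(cv)$f1, 1)
  set.seed(34)
  for (prior in c(0.2, 0.5)) {
    scores <- runif(10000)
    labels <- rbinom(10000, 1, prior)
    a <- auc_pr(pr_curve(evaluation_set(scores, labels, hours = 1)))
    expect_lt(abs(a - prior), 0.05)
  }
  # single-class set is an undefined-metric marker
  expect_null(pr_curve(evaluation_set(runif(10), rep(1, 10), hours = 1)))
})

test_that("AUC-PR is invariant under strictly monotone score transforms", {
  set.seed(35)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.4)
  a1 <- auc_pr(pr_curve(evaluation_set(scores, labels, hours = 1)))
  a2 <- auc_pr(pr_curve(evaluation_set(qlogis(scores / 1.001 + 1e-4), labels, hours = 1)))
  a3 <- auc_pr(pr_curve(evaluation_set(scores^3, labels, hours = 1)))
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("calibrated PR curves keep recall and reweight precision", {
  set.seed(36)
  scores <- runif(400)
  labels <- rbinom(400, 1, 0.3)
  es <- evaluation_set(scores, labels, hours = 1)
  raw <- pr_curve(es)
  cal <- pr_curve(es, target_prior = 0.3)
  expect_equal(cal$recall, raw$recall)
  emp <- mean(labels)
  cal_emp <- pr_curve(es, target_prior = emp)
  expect_equal(cal_emp$precision, raw$precision, tolerance = 1e-12)
})

test_that("false positives per hour divides FP counts by audio hours", {
  es <- evaluation_set(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 0, 1), hours = 2)
  expect_equal(fp_per_hour(es, 0.5), 0.5)     # one FP over 2 h
  expect_equal(fp_per_hour(es, 0.95), 0)
  expect_lte(fp_per_hour(es, 1.0), fp_per_hour(es, 0.5))
})

test_that("recall by INI bins notes by their preceding interval", {
  ann <- note_annotations(c(10, 27, 48.5, 65.4), c(11, 28, 49.5, 66.4))
  dets <- data.frame(segment_start_s = 0:96,
                     score = rep(0, 97))
  # detect only the note at 27 (INI 17) and the note at 65.4 (INI 16.9)
  dets$score[dets$segment_start_s %in% c(25, 63)] <- 1
  rb <- recall_by_ini(dets, ann, threshold = 0.5, ini_bins = c(15, 20, 25, 30))
  expect_equal(rb$n_notes, c(2L, 1L, 0L))  # INIs 17, 16.9 | 21.5 | none
  expect_equal(rb$n_detected, c(2L, 0L, 0L))
  expect_equal(rb$recall[1:2], c(1, 0))
  expect_true(is.na(rb$recall[3]))      # empty bin marker
  # all detected / none detected boundary behavior
  dets$score[] <- 1
  expect_equal(recall_by_ini(dets, ann, 0.5, c(15, 25))$recall, 1)
  dets$score[] <- 0
  expect_equal(recall_by_ini(dets, ann, 0.5, c(15, 25))$recall, 0)
})

test_that("fold aggregation takes pointwise medians on a common recall grid", {
  es <- evaluation_set(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0), hours = 1)
  cv <- pr_curve(es)
  agg_same <- aggregate_folds(list(cv, cv, cv))
  single <- aggregate_folds(list(cv))
  expect_equal(agg_same$precision, single$precision)
  # constant-precision curves -> pointwise median
  mk <- function(p) {
    out <- data.frame(threshold = c(0.9, 0.5, 0.1), precision = p,
                      recall = c(0.2, 0.6, 1))
    class(out) <- c("pr_curve", "data.frame")
    out
  }
  agg <- aggregate_folds(list(mk(0.2), mk(0.5), mk(0.9)))
  expect_true(all(agg$precision == 0.5))
  # bounded between pointwise min and max of the inputs
  set.seed(37)
  curves <- lapply(1:3, function(i) {
    es <- evaluation_set(runif(100), rbinom(100, 1, 0.4), hours = 1)
    pr_curve(es)
  })
  agg <- aggregate_folds(curves)
  grid_p <- vapply(curves, function(cv)
    stats::approx(cv$recall, cv$precision, xout = agg$recall,
                  method = "constant", f = 1, rule = 2,
                  ties = list("ordered", min))$y,
    numeric(nrow(agg)))
  expect_true(all(agg$precision >= apply(grid_p, 1, min) - 1e-12))
  expect_true(all(agg$precision <= apply(grid_p, 1, max) + 1e-12))
})

test_that("PARTIAL segments are excluded from evaluation sets by default", {
  scores <- c(0.9, 0.5, 0.1)
  labels <- c("POSITIVE", "PARTIAL", "NEGATIVE")
  es <- evaluation_set(scores, labels, hours = 1)
  expect_equal(length(es$scores), 2)
  es_neg <- evaluation_set(scores, labels, hours = 1, partial_as = "negative")
  expect_equal(length(es_neg$scores), 3)
  expect_equal(es_neg$labels, c(1L, 0L, 0L))
})
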