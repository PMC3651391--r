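# Confusion metrics, ROC/AUC, cut-off selection, rank-sum test, jackknife.

test_that("confusion metrics evaluate the five ratios exactly", {
  m <- confusion_metrics(tp = 14, fp = 1, tn = 18, fn = 1)
  expect_equal(m$ppv, 14 / 15, tolerance = 1e-15)
  expect_equal(m$npv, 18 / 19, tolerance = 1e-15)
  expect_equal(m$sensitivity, 14 / 15, tolerance = 1e-15)
  expect_equal(m$specificity, 18 / 19, tolerance = 1e-15)
  expect_equal(m$accuracy, 32 / 34, tolerance = 1e-15)
  expect_identical(unname(m$fractions["accuracy"]), "32/34")

  all_right <- confusion_metrics(tp = 5, fp = 0, tn = 4, fn = 0)
  defined <- unlist(all_right[c("ppv", "npv", "sensitivity", "specificity",
                                "accuracy")])
  expect_true(all(defined == 1))

  w <- capture_warnings(z <- confusion_metrics(tp = 0, fp = 0, tn = 5,
                                               fn = 0))
  expect_match(w, "undefined", all = TRUE)
  expect_length(w, 2L)  # both PPV and sensitivity have empty denominators
  expect_true(is.na(z$ppv))
  expect_true(is.na(z$sensitivity))
  expect_identical(z$accuracy, 1)
  expect_error(confusion_metrics(tp = -1, fp = 0, tn = 1, fn = 0),
               "codp_invalid_argument")
})

test_that("metrics satisfy the prevalence-weighted accuracy identity", {
  set.seed(8)
  for (i in 1:20) {
    cnt <- as.list(rmultinom(1, 50, c(0.3, 0.2, 0.3, 0.2))[, 1] + 1)
    names(cnt) <- c("tp", "fp", "tn", "fn")
    m <- suppressWarnings(do.call(confusion_metrics, cnt))
    P <- cnt$tp + cnt$fn
    N <- cnt$fp + cnt$tn
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("binarization applies each tool's decision convention", {
  expect_true(binarize_scores(0.03, "sift"))
  expect_true(binarize_scores(0.05, "sift"))   # boundary damaging
  expect_false(binarize_scores(0.06, "sift"))
  expect_true(binarize_scores(0.446, "pph2"))  # boundary damaging
  expect_false(binarize_scores(0.445, "pph2"))
  expect_false(binarize_scores(0.56, "codp"))  # strict > for pathogenic
  expect_true(binarize_scores(0.561, "codp"))
  expect_false(binarize_scores(1.0, "mapp"))   # strict > for pathogenic
  expect_true(binarize_scores(1.01, "mapp"))
  expect_true(binarize_scores(0.2, "codp", threshold = 0.1))
})

test_that("roc_auc equals the brute-force concordant-pair count and the
          rank-sum identity", {
  expect_identical(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_identical(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(2:5, 1)
    n0 <- 8 - n1
    scores <- round(runif(8), 2)  # duplicates likely -> exercises ties
    labels <- sample(c(rep(1, n1), rep(0, n0)))
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
    u <- wilcoxon_rank_sum(scores[labels == 1],
                           scores[labels == 0])$statistic
    expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-12)
    # the ROC polygon starts at (0,0) and ends at (1,1)
    expect_identical(c(r$roc$fpr[1], r$roc$tpr[1]), c(0, 0))
    expect_identical(c(max(r$roc$fpr), max(r$roc$tpr)), c(1, 1))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "codp_single_class")
  # independent reference implementation agrees
  set.seed(19)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  if (length(unique(labels)) == 2) {
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                                direction = "<",
                                                quiet = TRUE)))
    expect_equal(roc_auc(scores, labels)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("optimal_cutoff matches an exhaustive threshold sweep", {
  expect_identical(optimal_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)),
                   0.5)
  set.seed(23)
  for (i in 1:30) {
    scores <- round(runif(6), 2)
    labels <- sample(c(1, 1, 1, 0, 0, 0))
    if (length(unique(scores)) < 2) next
    expect_identical(optimal_cutoff(scores, labels),
                     brute_cutoff(scores, labels))
  }
  expect_warning(deg <- optimal_cutoff(rep(0.5, 4), c(0, 0, 1, 1)),
                 "codp_degenerate")
  expect_true(is.na(deg))
})

test_that("exact Wilcoxon p-values equal the complete-enumeration oracle", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(w$mode, "exact")
  expect_identical(w$statistic, 0)
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)  # 2 * 1/choose(6,3)

  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    z <- sample(1000, n1 + n2)  # distinct -> tie-free
    x <- z[seq_len(n1)]
    y <- z[-seq_len(n1)]
    w <- wilcoxon_rank_sum(x, y)
    expect_identical(w$mode, "exact")
    expect_equal(w$p_value, enum_wilcoxon_p(x, y), tolerance = 1e-12)
    # invariance under strictly monotone transforms of the pooled scores
    w2 <- wilcoxon_rank_sum(exp(x / 100), exp(y / 100))
    expect_equal(w2$p_value, w$p_value, tolerance = 1e-12)
  }
})

test_that("tied or large samples fall back to the corrected normal
          approximation", {
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$mode, "approx")
  expect_identical(same$p_value, 1)  # U at its null mean
  set.seed(37)
  x <- rnorm(18)
  y <- rnorm(18, 1)
  w <- wilcoxon_rank_sum(x, y)
  expect_identical(w$mode, "approx")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
  forced <- wilcoxon_rank_sum(x, y, mode = "exact")
  expect_identical(forced$mode, "exact")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "codp_invalid_argument")
})

test_that("leave-one-out jackknife is accurate on separable synthetic data
          and near prevalence on shuffled labels", {
  # a well-separated generating model: doubling the logit coefficients
  # pushes the class-membership probabilities towards 0/1
  sharp <- codp_model(intercept = 2 * codp_model()$intercept,
                      coefficients = 2 * codp_model()$coefficients)
  d <- simulate_variants(sharp, n = 200, seed = 13)
  jk <- jackknife_loo(d, d$label)
  expect_identical(nrow(jk$predictions), 200L)
  expect_gt(jk$accuracy, 0.9)
  expect_named(jk$accuracy_by_class, c("pathogenic", "non_pathogenic"))

  set.seed(99)
  y_shuf <- sample(d$label)
  jk0 <- jackknife_loo(d, y_shuf)
  prev <- max(mean(y_shuf), 1 - mean(y_shuf))
  expect_lt(abs(jk0$accuracy - prev), 0.15)
})

test_that("a minimal jackknife produces one held-out prediction per item", {
  d <- data.frame(x1 = c(0.1, 0.3, 0.2, 0.9, 0.8, 1.0, 0.85, 0.15),
                  label = c(0, 0, 0, 1, 1, 1, 1, 0))
  jk <- jackknife_loo(d, d$label, ridge = 1e-2)
  expect_identical(nrow(jk$predictions), 8L)
  expect_false(any(is.na(jk$predictions$q[!jk$predictions$failed])))
  expect_error(jackknife_loo(d[1:5, ], d$label[1:5]), "3 items per class")
})
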