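# Performance evaluation: confusion metrics, ROC/AUC, cut-off selection,
# Wilcoxon rank-sum comparison and the leave-one-out jackknife.

#' Confusion-matrix metrics
#'
#' Exact rational evaluation of PPV = TP/(TP+FP), NPV = TN/(FN+TN),
#' sensitivity = TP/(TP+FN), specificity = TN/(FP+TN) and
#' accuracy = (TP+TN)/(TP+TN+FP+FN). A metric with a zero denominator is
#' reported as `NA` with a warning, never as 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts (total >= 1). `tp` may
#'   also be a named vector/list carrying all four counts.
#' @return A `codp_metrics` list: the counts plus `ppv`, `npv`,
#'   `sensitivity`, `specificity`, `accuracy`, and `fractions` (the exact
#'   fraction strings, e.g. `"14/15"`).
#' @examples
#' confusion_metrics(tp = 14, fp = 1, tn = 18, fn = 1)
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 4L) {
    cnt <- as.list(tp)
    tp <- cnt$tp; fp <- cnt$fp; tn <- cnt$tn; fn <- cnt$fn
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) < 1) {
    stop("codp_invalid_argument: counts must be non-negative integers with ",
         "a positive total", call. = FALSE)
  }
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("codp_metrics: ", what, " undefined (zero denominator)",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  frac <- function(num, den) if (den == 0) NA_character_ else
    paste0(num, "/", den)
  out <- list(
    counts = counts,
    ppv = ratio(tp, tp + fp, "PPV"),
    npv = ratio(tn, fn + tn, "NPV"),
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, fp + tn, "specificity"),
    accuracy = (tp + tn) / sum(counts),
    fractions = c(ppv = frac(tp, tp + fp), npv = frac(tn, fn + tn),
                  sensitivity = frac(tp, tp + fn),
                  specificity = frac(tn, fp + tn),
                  accuracy = frac(tp + tn, sum(counts)))
  )
  class(out) <- "codp_metrics"
  out
}

#' @export
print.codp_metrics <- function(x, digits = 3, ...) {
  cat("confusion counts: TP", x$counts["tp"], "FP", x$counts["fp"],
      "TN", x$counts["tn"], "FN", x$counts["fn"], "\n")
  for (m in c("ppv", "npv", "sensitivity", "specificity", "accuracy")) {
    cat(sprintf("  %-12s %s (%s)\n", m,
                ifelse(is.na(x[[m]]), "NA", format(round(x[[m]], digits))),
                ifelse(is.na(x$fractions[m]), "-", x$fractions[m])))
  }
  invisible(x)
}

#' Binarize tool scores into pathogenic calls
#'
#' Applies each tool's published decision convention: SIFT calls pathogenic
#' when the score is at or below 0.05 (low = damaging); PolyPhen-2 when at
#' or above 0.446; the CoDP joint score when strictly above 0.56; the
#' normalized MAPP score when strictly above 1.0.
#'
#' @param scores Numeric score vector.
#' @param tool One of `"sift"`, `"pph2"`, `"codp"`, `"mapp"`.
#' @param threshold Override of the tool's default threshold.
#' @return Logical vector, TRUE = pathogenic call.
#' @examples
#' binarize_scores(c(0.03, 0.2), "sift")
#' binarize_scores(1.0, "mapp")   # boundary is benign: strict > required
#' @export
binarize_scores <- function(scores, tool = c("codp", "mapp", "sift", "pph2"),
                            threshold = NULL) {
  tool <- match.arg(tool)
  def <- c(codp = 0.56, mapp = 1.0, sift = 0.05, pph2 = 0.446)
  t <- if (is.null(threshold)) def[[tool]] else threshold
  switch(tool,
         sift = scores <= t,
         pph2 = scores >= t,
         codp = scores > t,
         mapp = scores > t)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) identity with midranks for ties, which
#' equals the trapezoidal area under the ROC curve over all distinct
#' thresholds.
#'
#' @param scores Numeric scores (higher = more pathogenic).
#' @param labels Binary labels (1/TRUE = pathogenic); both classes required.
#' @return List with `auc` and `roc` (data frame of `threshold`, `fpr`,
#'   `tpr`, one row per distinct threshold plus the two endpoints).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(scores) != length(y) || any(is.na(scores)) || any(is.na(y))) {
    stop("codp_invalid_argument: scores/labels must be complete and equal ",
         "length", call. = FALSE)
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("codp_single_class: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[y == 0] >= t),
                      numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(scores[y == 1] >= t),
                      numeric(1)))
  )
  list(auc = auc, roc = roc)
}

#' Optimal score cut-off
#'
#' Selects the decision threshold over the midpoints between adjacent
#' distinct scores (calls are "score > threshold"). The default rule
#' maximizes Youden's J = sensitivity + specificity - 1; the alternative
#' minimizes the distance to the ROC corner (0, 1). Ties break toward the
#' smaller threshold.
#'
#' @inheritParams roc_auc
#' @param rule `"youden"` (default) or `"closest"`.
#' @return The selected threshold (`NA` with a warning when all scores are
#'   identical).
#' @export
optimal_cutoff <- function(scores, labels, rule = c("youden", "closest")) {
  rule <- match.arg(rule)
  y <- as.integer(as.logical(labels))
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop("codp_single_class: both classes must be present", call. = FALSE)
  }
  s <- sort(unique(scores))
  if (length(s) < 2) {
    warning("codp_degenerate: all scores identical; no cut-off exists",
            call. = FALSE)
    return(NA_real_)
  }
  cand <- (s[-1] + s[-length(s)]) / 2
  crit <- vapply(cand, function(t) {
    sens <- mean(scores[y == 1] > t)
    spec <- mean(scores[y == 0] <= t)
    switch(rule,
           youden = sens + spec - 1,
           closest = -sqrt((1 - sens)^2 + (1 - spec)^2))
  }, numeric(1))
  cand[which.max(crit)]  # which.max takes the first (smallest) on ties
}

#' Wilcoxon rank-sum comparison of two score distributions
#'
#' Two-sided rank-sum test with the Mann-Whitney U statistic (midranks for
#' ties). The exact p-value (complete enumeration of rank assignments;
#' doubled one-sided tail capped at 1) is used when the pooled sample is at
#' most 20 with no ties; otherwise the normal approximation with tie and
#' continuity correction. Either mode can be forced.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List with `statistic` (U for the first sample), `p_value` and
#'   `mode` (the mode actually used).
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)    # exact two-sided p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1 || any(is.na(c(x, y)))) {
    stop("codp_invalid_argument: both samples must be non-empty and ",
         "complete", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  n <- length(x) + length(y)
  use_exact <- switch(mode,
                      auto = !ties && n <= 20,
                      exact = TRUE,
                      approx = FALSE)
  if (use_exact && ties && mode == "exact") {
    # exact enumeration is defined on distinct ranks only
    use_exact <- FALSE
    warning("codp_wilcoxon: ties present; falling back to the normal ",
            "approximation", call. = FALSE)
  }
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)
  )
  list(statistic = u, p_value = unname(ht$p.value),
       mode = if (use_exact) "exact" else "approx")
}

#' Leave-one-out jackknife of the CoDP fit
#'
#' For each labeled variant, refits the logistic model on the remaining
#' variants and predicts the held-out one with the pathogenicity cut-off.
#' The component scores are treated as fixed inputs: only the regression
#' fit is left out. Refits that fail (for example through complete
#' separation of the reduced data) flag the item, which is excluded from
#' the summary with a warning.
#'
#' @inheritParams codp_fit
#' @param t_low Pathogenicity cut-off on the held-out joint score
#'   (default 0.56).
#' @param ridge Ridge penalty passed to each refit (default 0).
#' @return List with `predictions` (per-variant data frame: `q`, `predicted`,
#'   `label`, `correct`, `failed`), `accuracy`, `accuracy_by_class` (named:
#'   pathogenic / non_pathogenic), and `n_failed`.
#' @examples
#' d <- simulate_variants(n = 60, seed = 7)
#' jackknife_loo(d, d$label)$accuracy
#' @export
jackknife_loo <- function(features, labels = NULL, t_low = 0.56, ridge = 0,
                          feature_names = NULL) {
  features <- as.data.frame(features)
  if (is.null(labels)) labels <- features$label
  y <- as.integer(labels)
  if (sum(y == 1) < 3 || sum(y == 0) < 3) {
    stop("codp_invalid_argument: need at least 3 items per class",
         call. = FALSE)
  }
  n <- length(y)
  q <- rep(NA_real_, n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      codp_fit(features[-i, , drop = FALSE], y[-i], ridge = ridge,
               feature_names = feature_names),
      error = function(e) NULL
    )
    if (is.null(fit_i)) {
      failed[i] <- TRUE
    } else {
      q[i] <- joint_score(features[i, , drop = FALSE], fit_i)
    }
  }
  if (any(failed)) {
    warning("codp_jackknife: ", sum(failed), " refit(s) failed and were ",
            "excluded from the summary", call. = FALSE)
  }
  predicted <- q > t_low
  correct <- predicted == (y == 1)
  ok <- !failed
  acc_class <- c(
    pathogenic = mean(correct[ok & y == 1]),
    non_pathogenic = mean(correct[ok & y == 0])
  )
  list(
    predictions = data.frame(q = q, predicted = predicted, label = y,
                             correct = correct, failed = failed),
    accuracy = mean(correct[ok]),
    accuracy_by_class = acc_class,
    n_failed = sum(failed)
  )
}
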