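# Pair-preserving repeated k-fold cross-validation, classification metrics,
# ROC/AUC by threshold sweep, the corrected resampled t-test over sorted
# runs, Benjamini-Hochberg adjustment, and the label-shuffle null
# experiment.

#' Build a pair-preserving repeated k-fold plan
#'
#' Cases are dealt randomly into folds (sizes differing by at most one) with
#' an independent shuffle per repeat; every control inherits its matched
#' case's fold, so a case and its controls are never split. On each
#' iteration one fold tests, the next fold (cyclically) validates, and the
#' remaining folds train.
#'
#' @param persons Person table with `person_id`, `label`, `matched_case_id`.
#' @param n_repeats,n_folds Plan dimensions (default 10 x 10).
#' @param seed Optional seed; plans are deterministic per seed.
#' @return Object of class `fold_plan` with an `assignment` data frame
#'   (`repeat_id`, `case_id`, `fold`).
#' @export
make_folds <- function(persons, n_repeats = 10L, n_folds = 10L,
                       seed = NULL) {
  stopifnot(n_repeats >= 1, n_folds >= 3)
  # groups are anchored by matched_case_id so the plan also works after a
  # label shuffle moved the "case" label onto a former control
  cases_per_group <- tapply(persons$label == "case",
                            persons$matched_case_id, sum)
  if (any(cases_per_group != 1)) {
    stop(sum(cases_per_group == 0),
         " control(s) have no matched case in the table", call. = FALSE)
  }
  case_ids <- names(cases_per_group)
  if (length(case_ids) < n_folds) {
    stop("fewer cases than folds", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  assignment <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    shuffled <- sample(case_ids)
    data.frame(repeat_id = r, case_id = shuffled,
               fold = rep_len(seq_len(n_folds), length(shuffled)),
               stringsAsFactors = FALSE)
  }))
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 assignment = assignment),
            class = "fold_plan")
}

# Fold index per person for one repeat (controls follow their case).
person_folds <- function(plan, persons, repeat_id) {
  a <- plan$assignment[plan$assignment$repeat_id == repeat_id, ]
  a$fold[match(persons$matched_case_id, a$case_id)]
}

#' Classification metrics at a decision threshold
#'
#' Sensitivity is the percentage of cases scored above the threshold,
#' specificity the percentage of controls at or below it, and the error rate
#' is the balanced error `100 - (sensitivity + specificity) / 2`, in
#' percent.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (1 = case) or `"case"`/`"control"`.
#' @param threshold Decision threshold (default 0.5; case iff `r > 0.5`).
#' @return Named vector `error`, `sensitivity`, `specificity` (percent).
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  is_case <- as_case_indicator(labels)
  if (all(is_case) || !any(is_case)) {
    stop("both classes must be present to compute sensitivity/specificity",
         call. = FALSE)
  }
  pred_case <- scores > threshold
  sens <- 100 * mean(pred_case[is_case])
  spec <- 100 * mean(!pred_case[!is_case])
  c(error = balanced_error(sens, spec), sensitivity = sens,
    specificity = spec)
}

#' Balanced error rate from sensitivity and specificity
#'
#' @param sensitivity,specificity In percent.
#' @return `100 - (sensitivity + specificity) / 2`, in percent.
#' @export
#' @examples
#' balanced_error(57.28, 84.94)  # 28.89
balanced_error <- function(sensitivity, specificity) {
  100 - (sensitivity + specificity) / 2
}

as_case_indicator <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "case"
  } else {
    labels == 1
  }
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over all distinct scores, yielding the
#' (false positive rate, true positive rate) curve from (0, 0) to (1, 1),
#' and integrates it by the trapezoid rule. The resulting AUC equals the
#' probability that a random case outscores a random control, with ties
#' counting one half.
#'
#' @inheritParams confusion_metrics
#' @return Object of class `roc_curve`: list with `points` (data frame
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  is_case <- as_case_indicator(labels)
  if (all(is_case) || !any(is_case)) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  cs <- cumsum(is_case[ord])
  cc <- cumsum(!is_case[ord])
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct score
  tpr <- c(0, cs[last] / sum(is_case))
  fpr <- c(0, cc[last] / sum(!is_case))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Shuffle case labels within matched groups
#'
#' The negative-control experiment: within every matched group, the `"case"`
#' label is reassigned uniformly at random to one of the group's controls
#' and the original case becomes a control. Group membership, features and
#' index dates are untouched, so any residual classification performance
#' reflects idiosyncratic structure, not the case-control signal.
#'
#' @param persons Person table with complete, equal-sized matched groups.
#' @param seed Optional seed.
#' @return `persons` with the `label` column reassigned.
#' @export
shuffle_labels <- function(persons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- split(seq_len(nrow(persons)), persons$matched_case_id)
  sizes <- lengths(groups)
  if (length(unique(sizes)) != 1) {
    stop("incomplete matched group(s): sizes ",
         paste(sort(unique(sizes)), collapse = ", "), call. = FALSE)
  }
  labels <- persons$label
  for (g in groups) {
    ctrl_rows <- g[labels[g] == "control"]
    if (length(ctrl_rows) == 0 || sum(labels[g] == "case") != 1) {
      stop("each matched group needs exactly one case and >= 1 control",
           call. = FALSE)
    }
    new_case <- if (length(ctrl_rows) == 1) ctrl_rows
                else sample(ctrl_rows, 1)
    labels[g] <- "control"
    labels[new_case] <- "case"
  }
  persons$label <- labels
  persons
}

#' Run repeated cross-validation for one architecture
#'
#' For every (repeat, fold) iteration a fresh network is trained on the
#' eight training folds (age standardized with training-fold statistics),
#' early-stopped on the validation fold, and evaluated on the test fold
#' only. Iterations whose training diverges (non-finite cost) are flagged,
#' excluded and counted.
#'
#' @param x Raw design matrix from [build_design_matrix()].
#' @param y 0/1 labels.
#' @param persons Person table aligned with the rows of `x`.
#' @param plan A [make_folds()] plan.
#' @param arch Architecture tag.
#' @param cfg A [training_config()].
#' @param seed Master seed; per-iteration init/batching seeds derive from it.
#' @return Data frame of class `cv_results`, one row per iteration:
#'   `repeat_id`, `fold`, `error`, `sensitivity`, `specificity`, `auc`.
#' @export
run_cv <- function(x, y, persons, plan, arch = "nn0",
                   cfg = training_config(), seed = 1L) {
  stopifnot(inherits(plan, "fold_plan"), nrow(x) == length(y),
            nrow(x) == nrow(persons))
  set.seed(seed)
  n_iter <- plan$n_repeats * plan$n_folds
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  rows <- vector("list", n_iter)
  n_diverged <- 0L
  i <- 0L
  for (r in seq_len(plan$n_repeats)) {
    folds <- person_folds(plan, persons, r)
    for (f in seq_len(plan$n_folds)) {
      i <- i + 1L
      val_f <- f %% plan$n_folds + 1L
      test_ix <- which(folds == f)
      val_ix <- which(folds == val_f)
      train_ix <- which(folds != f & folds != val_f)
      set.seed(iter_seeds[i])
      net <- init_network(arch, input_dim = ncol(x))
      mu <- mean(x[train_ix, 1])
      sd_ <- stats::sd(x[train_ix, 1])
      if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
      xs <- x
      xs[, 1] <- (xs[, 1] - mu) / sd_
      fit <- tryCatch(
        nn_train(net, xs[train_ix, , drop = FALSE], y[train_ix],
                 persons$matched_case_id[train_ix],
                 xs[val_ix, , drop = FALSE], y[val_ix], cfg),
        error = function(e) {
          if (grepl("diverged", conditionMessage(e))) NULL else stop(e)
        })
      if (is.null(fit)) {
        n_diverged <- n_diverged + 1L
        next
      }
      scores <- nn_predict(fit$net, xs[test_ix, , drop = FALSE],
                           standardize = FALSE)
      m <- confusion_metrics(scores, y[test_ix])
      rows[[i]] <- data.frame(repeat_id = r, fold = f,
                              error = m[["error"]],
                              sensitivity = m[["sensitivity"]],
                              specificity = m[["specificity"]],
                              auc = roc_auc(scores, y[test_ix])$auc)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  if (n_diverged > 0) {
    warning(n_diverged, " iteration(s) diverged and were excluded")
  }
  structure(out, class = c("cv_results", "data.frame"),
            arch = arch, n_diverged = n_diverged, seed = seed)
}

#' Summarize cross-validation results
#'
#' Mean and standard deviation over iterations for each metric, mirroring
#' the usual mean (SD) presentation of repeated-CV performance tables.
#'
#' @param results A `cv_results` data frame from [run_cv()].
#' @return Data frame with one row per metric.
#' @export
summarize_cv <- function(results) {
  metrics <- c("error", "sensitivity", "specificity", "auc")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(results[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(results[[m]]), numeric(1)),
    row.names = NULL
  )
}

#' Corrected resampled t-test over sorted runs
#'
#' Compares two systems evaluated under the same repeated k-fold plan.
#' Within each repeat, each system's per-fold values are sorted ascending
#' and differenced by rank; averaging over repeats yields one difference per
#' fold rank. The t statistic inflates the naive variance by the
#' train/test-overlap factor: `t = mean(d) / sqrt(var(d) * (1/k +
#' test_train_ratio))` with `k` fold ranks and `k - 1` degrees of freedom.
#'
#' @param results_a,results_b `cv_results` from the same [make_folds()]
#'   plan, or plain data frames with `repeat_id`, `fold` and the metric.
#' @param metric Column to compare (default `"error"`).
#' @param test_train_ratio Size ratio of test to training data (default 1/8:
#'   one test fold against eight training folds).
#' @return List with `t`, `p` (two-sided), `df` and the rank-difference
#'   vector `d`.
#' @export
corrected_resampled_ttest <- function(results_a, results_b,
                                      metric = "error",
                                      test_train_ratio = 1 / 8) {
  va <- results_a[[metric]]
  vb <- results_b[[metric]]
  stopifnot(length(va) == length(vb))
  sa <- tapply(va, results_a$repeat_id, sort)
  sb <- tapply(vb, results_b$repeat_id, sort)
  k <- length(sa[[1]])
  d <- rowMeans(mapply(function(a, b) a - b, sa, sb))
  vd <- stats::var(d)
  if (vd == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = k - 1L, d = d))
    warning("zero variance with nonzero mean difference; p reported as 0")
    return(list(t = sign(mean(d)) * Inf, p = 0, df = k - 1L, d = d))
  }
  t_stat <- mean(d) / sqrt(vd * (1 / k + test_train_ratio))
  p <- 2 * stats::pt(-abs(t_stat), df = k - 1)
  list(t = t_stat, p = p, df = k - 1L, d = d)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of p-values to q-values, returned in input order and
#' capped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Pairwise architecture comparison
#'
#' Runs the corrected resampled t-test on every pair of result sets and
#' adjusts the p-values with [bh_adjust()].
#'
#' @param results_list Named list of `cv_results`, all from one fold plan.
#' @param metric Metric column to compare.
#' @param test_train_ratio See [corrected_resampled_ttest()].
#' @return Data frame with one row per pair: `a`, `b`, `t`, `p`, `q`.
#' @export
compare_architectures <- function(results_list, metric = "error",
                                  test_train_ratio = 1 / 8) {
  tags <- names(results_list)
  stopifnot(length(tags) >= 2)
  pairs <- utils::combn(tags, 2)
  out <- data.frame(a = pairs[1, ], b = pairs[2, ], t = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    tt <- corrected_resampled_ttest(results_list[[pairs[1, i]]],
                                    results_list[[pairs[2, i]]],
                                    metric, test_train_ratio)
    out$t[i] <- tt$t
    out$p[i] <- tt$p
  }
  out$q <- bh_adjust(out$p)
  out
}
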