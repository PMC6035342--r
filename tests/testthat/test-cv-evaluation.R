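# Cross-validation plans, metrics, ROC/AUC, corrected t-test, BH, shuffle.

test_that("fold plans balance cases and never split matched groups", {
  coh <- small_cohort(n_cases = 20, seed = 41)
  plan <- make_folds(coh$persons, n_repeats = 3, n_folds = 5, seed = 1)
  for (r in 1:3) {
    a <- plan$assignment[plan$assignment$repeat_id == r, ]
    expect_equal(sort(a$case_id),
                 sort(coh$persons$person_id[coh$persons$label == "case"]))
    expect_true(all(table(a$fold) == 4))
    # every control lands in its case's fold: group check is exhaustive
    folds <- a$fold[match(coh$persons$matched_case_id, a$case_id)]
    split_groups <- tapply(folds, coh$persons$matched_case_id,
                           function(f) length(unique(f)))
    expect_true(all(split_groups == 1))
  }
  expect_identical(make_folds(coh$persons, 2, 5, seed = 7),
                   make_folds(coh$persons, 2, 5, seed = 7))

  # uneven case counts differ by at most one per fold
  coh2 <- small_cohort(n_cases = 21, seed = 42)
  plan2 <- make_folds(coh2$persons, 1, 5, seed = 1)
  sizes <- table(plan2$assignment$fold)
  expect_lte(diff(range(sizes)), 1)

  bad <- coh$persons
  bad$matched_case_id[bad$label == "control"][1] <- "nobody"
  expect_error(make_folds(bad, 2, 5), "no matched case")
})

test_that("confusion metrics implement the balanced error", {
  # identity on printed-style sensitivity/specificity values
  expect_equal(balanced_error(57.28, 84.94), 28.89)
  expect_equal(balanced_error(100, 100), 0)

  scores <- c(0.9, 0.8, 0.2, 0.1, 0.6, 0.4)
  labels <- c(1, 1, 0, 0, 0, 1)
  m <- confusion_metrics(scores, labels)
  expect_equal(unname(m["sensitivity"]), 100 * 2 / 3)
  expect_equal(unname(m["specificity"]), 100 * 2 / 3)
  expect_equal(unname(m["error"]),
               100 - (m[["sensitivity"]] + m[["specificity"]]) / 2)
  expect_error(confusion_metrics(scores, rep(1, 6)), "both classes")

  # scores independent of labels give ~50% balanced error
  set.seed(8)
  s <- runif(20000)
  y <- rep(c(1, 0), c(1000, 19000))
  expect_equal(unname(confusion_metrics(s, y)["error"]), 50,
               tolerance = 0.05)
})

test_that("AUC equals the case-control pair-count oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # label inversion flips the area
  set.seed(12)
  s <- round(runif(30), 1)  # coarse scores force ties
  y <- rbinom(30, 1, 0.4)
  while (length(unique(y)) < 2) y <- rbinom(30, 1, 0.4)
  expect_equal(roc_auc(s, y)$auc, pairwise_auc(s, y))
  expect_equal(roc_auc(s, 1 - y)$auc, 1 - roc_auc(s, y)$auc)
  for (rep in 1:20) {
    s <- sample(seq(0, 1, 0.05), 25, replace = TRUE)
    y <- c(1, 0, rbinom(23, 1, 0.5))
    expect_equal(roc_auc(s, y)$auc, pairwise_auc(s, y))
  }
  # curve runs from (0,0) to (1,1), nondecreasing
  curve <- roc_auc(s, y)$points
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
})

test_that("corrected resampled t-test follows the sorted-runs formula", {
  fake <- function(vals) {
    data.frame(repeat_id = rep(1:2, each = 5), fold = rep(1:5, 2),
               error = vals)
  }
  a <- fake(c(30, 28, 31, 29, 27, 30.5, 28.5, 29.5, 27.5, 31.5))
  expect_equal(corrected_resampled_ttest(a, a),
               list(t = 0, p = 1, df = 4L,
                    d = setNames(rep(0, 5), NULL)),
               ignore_attr = TRUE)
  b <- fake(c(32, 29, 33, 30, 28, 33.5, 29.5, 31.5, 28.5, 34))
  got <- corrected_resampled_ttest(a, b, test_train_ratio = 1 / 8)
  # independent arithmetic: sort within repeat, rank-difference, average
  d <- (sort(a$error[1:5]) - sort(b$error[1:5]) +
          sort(a$error[6:10]) - sort(b$error[6:10])) / 2
  t_direct <- mean(d) / sqrt(var(d) * (1 / 5 + 1 / 8))
  expect_equal(got$t, t_direct)
  expect_equal(got$p, 2 * pt(-abs(t_direct), df = 4))
  # rescaling both systems leaves the statistic unchanged (d scales by c)
  expect_equal(corrected_resampled_ttest(fake(3 * a$error),
                                         fake(3 * b$error))$t,
               got$t, tolerance = 1e-12)
  # degenerate: constant nonzero difference
  c2 <- fake(a$error + 1)
  expect_warning(z <- corrected_resampled_ttest(a, c2), "zero variance")
  expect_equal(z$p, 0)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(bh_adjust(p), stepup_bh(p))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(4)
  for (rep in 1:10) {
    p <- runif(sample(3:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, stepup_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("label shuffling keeps one case per matched group", {
  coh <- small_cohort(n_cases = 15, seed = 51)
  sh <- shuffle_labels(coh$persons, seed = 2)
  per_group <- tapply(sh$label == "case", sh$matched_case_id, sum)
  expect_true(all(per_group == 1))
  # original cases always lose their label
  orig_cases <- coh$persons$person_id[coh$persons$label == "case"]
  expect_true(all(sh$label[sh$person_id %in% orig_cases] == "control"))
  expect_identical(shuffle_labels(coh$persons, seed = 2), sh)

  expect_error(shuffle_labels(coh$persons[-2, ], seed = 1), "incomplete")
})

test_that("the shuffled position is uniform among a group's controls", {
  persons <- data.frame(
    person_id = paste0("p", 1:(21 * 10000)),
    label = rep(c("case", rep("control", 20)), 10000),
    matched_case_id = rep(paste0("g", 1:10000), each = 21)
  )
  sh <- shuffle_labels(persons, seed = 3)
  pos <- apply(matrix(sh$label == "case", nrow = 21), 2, which)
  expect_true(all(pos >= 2))  # the original case never keeps the label
  counts <- table(factor(pos, levels = 2:21))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("cross-validation is deterministic and recovers planted signal", {
  coh <- small_cohort(n_cases = 20, seed = 61)
  d <- build_design_matrix(coh$persons, coh$events)
  plan <- make_folds(coh$persons, 1, 4, seed = 5)
  r1 <- run_cv(d$x, d$y, coh$persons, plan, "nn0", fast_cfg(), seed = 6)
  r2 <- run_cv(d$x, d$y, coh$persons, plan, "nn0", fast_cfg(), seed = 6)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 4)
  # balanced-error identity holds row-wise
  expect_equal(r1$error, 100 - (r1$sensitivity + r1$specificity) / 2)
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
  # planted case-control differences are learnable
  expect_gt(mean(r1$auc), 0.8)
})
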