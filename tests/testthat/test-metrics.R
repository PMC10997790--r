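test_that("accuracy within k categories counts banded agreement", {
  pred <- c(1, 3, 8, 5); obs <- c(2, 3, 6, 5)
  expect_equal(accuracy_within(pred, obs, 0), 0.5)
  expect_equal(accuracy_within(pred, obs, 1), 0.75)   # only |8-6| = 2 misses
  expect_equal(accuracy_within(pred, obs, 2), 1.0)
  expect_equal(accuracy_within(sample(1:8, 50, TRUE), sample(1:8, 50, TRUE), 7), 1.0)
  expect_error(accuracy_within(integer(0), integer(0)), "empty")
})

test_that("discrepancy statistics carry the optimism sign convention", {
  expect_equal(discrepancy_stats(c(8, 8), c(1, 1))$md, 7)      # optimistic
  expect_equal(discrepancy_stats(c(1, 1), c(8, 8))$md, -7)     # pessimistic
  d <- discrepancy_stats(c(4, 7, 2, 5), c(4, 7, 2, 5))
  expect_equal(d$md, 0); expect_equal(d$sdd, 0)
  # hand-computed: sd(1,3,5,7) = sqrt(20/3)
  d2 <- discrepancy_stats(c(4, 4, 4, 4), c(1, 3, 5, 7))
  expect_equal(d2$md, 0)
  expect_equal(d2$sdd, -sqrt(20 / 3), tolerance = 1e-12)
  expect_true(is.na(discrepancy_stats(3, 5)$sdd))
})

test_that("category proportion discrepancies hit their analytic extremes", {
  disjoint <- category_proportion_discrepancy(rep(8L, 10), rep(1L, 10))
  expect_equal(disjoint$tcpd, 2)
  expect_equal(disjoint$mcpd, 1)
  obs <- sample(1:8, 40, TRUE)
  matched <- category_proportion_discrepancy(sample(obs), obs)
  expect_equal(matched$tcpd, 0)
  expect_equal(matched$mcpd, 0)
  ex <- category_proportion_discrepancy(c(1, 1, 2, 2), c(1, 1, 1, 2))
  expect_equal(unname(ex$pcp[1:2]), c(0.5, 0.5))
  expect_equal(unname(ex$ocp[1:2]), c(0.75, 0.25))
  expect_equal(ex$tcpd, 0.5)
  expect_equal(ex$mcpd, 0.25)
})

test_that("one-vs-rest macro statistics follow the exclusion rule", {
  perfect <- one_vs_rest_stats(1:8, 1:8)
  expect_equal(perfect$aba, 1); expect_equal(perfect$precision_macro, 1)
  expect_equal(perfect$recall_macro, 1); expect_equal(perfect$specificity_macro, 1)

  # hand confusion counts: class 1 sens .5/spec 1, class 2 sens 1/spec .5
  ovr <- one_vs_rest_stats(c(1, 2, 2), c(1, 1, 2))
  expect_equal(ovr$aba, 0.75)
  expect_equal(ovr$recall_macro, 0.75)
  expect_equal(ovr$precision_macro, 0.75)

  # category observed but never predicted: recall 0, precision excluded
  ovr2 <- one_vs_rest_stats(c(1, 1, 1), c(1, 1, 3))
  per3 <- ovr2$per_category[ovr2$per_category$category == 3, ]
  expect_equal(per3$sensitivity, 0)
  expect_true(is.na(per3$precision))
  expect_gt(ovr2$n_excluded, 0)
  expect_equal(ovr2$precision_macro, 2 / 3)   # only class 1 contributes
})

test_that("dichotomized AUROC uses the documented splits and tie rule", {
  # perfectly separating mortality scores
  probs <- matrix(0, 4, 8); probs[, 1] <- c(0.9, 0.8, 0.1, 0.2)
  probs[, 8] <- 1 - probs[, 1]
  expect_equal(dichotomized_auroc(probs, c(1, 1, 7, 8), "mortality"), 1.0)
  # all-tied scores give 0.5
  probs2 <- matrix(1 / 8, 6, 8)
  expect_equal(dichotomized_auroc(probs2, c(1, 1, 1, 8, 8, 8), "mortality"), 0.5)
  # hand pair count: positives at 0.8 and 0.4 -> 3 of 4 concordant pairs
  probs3 <- matrix(0, 4, 8); probs3[, 1] <- c(0.8, 0.6, 0.4, 0.2)
  probs3[, 8] <- 1 - probs3[, 1]
  expect_equal(dichotomized_auroc(probs3, c(1, 5, 1, 5), "mortality"), 0.75)
  # unfavorable split scores with p1+p2+p3+p4
  probs4 <- matrix(0.25, 3, 8) * cbind(1, 1, 1, 1, 0, 0, 0, 0)[rep(1, 3), ]
  probs4[1, ] <- c(0, 0, 0, 0, .25, .25, .25, .25)
  expect_equal(dichotomized_auroc(probs4, c(5, 3, 4), "unfavorable"), 1.0)
  expect_warning(out <- dichotomized_auroc(probs2, rep(8, 6), "mortality"),
                 "one class")
  expect_true(is.na(out))
})

test_that("confusion matrix orientation and identities hold", {
  m <- confusion_matrix(1:8, 1:8)
  expect_equal(unname(diag(m)), rep(1L, 8))
  expect_equal(sum(m), 8)
  # rows are observed: one observed-3 patient predicted as 5
  m2 <- confusion_matrix(pred = 5L, obs = 3L)
  expect_equal(unname(m2[3, 5]), 1L)
  expect_equal(sum(confusion_matrix(integer(0), integer(0))), 0)
  # trace / n = accuracy on fuzzed inputs
  for (i in 1:20) {
    pred <- sample(1:8, 30, TRUE); obs <- sample(1:8, 30, TRUE)
    expect_equal(sum(diag(confusion_matrix(pred, obs))) / 30,
                 accuracy_within(pred, obs, 0))
  }
})

test_that("error distribution is observed minus predicted over -7..7", {
  ed <- error_distribution(c(8L), c(1L))
  expect_equal(unname(ed["-7"]), 1L)
  expect_equal(sum(ed), 1L)
  obs <- sample(1:8, 50, TRUE)
  ed2 <- error_distribution(obs, obs)
  expect_equal(unname(ed2["0"]), 50L)
  expect_equal(sum(error_distribution(sample(1:8, 33, TRUE), sample(1:8, 33, TRUE))),
               33L)
})

test_that("calibration curves bin by predicted probability", {
  # constant probability equal to the base rate: one merged bin at (c, ~c)
  n <- 400; c0 <- 0.3
  probs <- matrix((1 - c0) / 7, n, 8); probs[, 4] <- c0
  obs <- ifelse(seq_len(n) <= n * c0, 4L, 1L)
  expect_warning(cc <- calibration_curve(probs, obs, category = 4, n_bins = 5),
                 "fewer distinct")
  expect_equal(nrow(cc), 1)
  expect_equal(cc$mean_predicted, c0)
  expect_equal(cc$observed_freq, c0)
  expect_equal(cc$count, n)
  # generic: bin counts sum to n
  set.seed(3)
  probs2 <- t(apply(matrix(rexp(50 * 8), 50), 1, function(r) r / sum(r)))
  obs2 <- sample(1:8, 50, TRUE)
  cc2 <- calibration_curve(probs2, obs2, category = 2, n_bins = 5)
  expect_equal(sum(cc2$count), 50)
  expect_true(all(cc2$observed_freq >= 0 & cc2$observed_freq <= 1))
})

test_that("full_report assembles every statistic coherently", {
  obs <- rep(1:8, times = c(5, 1, 6, 2, 3, 3, 5, 7))
  probs <- matrix(0, length(obs), 8)
  probs[cbind(seq_along(obs), obs)] <- 1
  perfect <- full_report(prediction_set(obs, obs, probs, "perfect"))
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$aw1, 1)
  expect_equal(perfect$aw2, 1); expect_equal(perfect$md, 0)
  expect_equal(perfect$sdd, 0); expect_equal(perfect$tcpd, 0)
  expect_equal(perfect$mcpd, 0)
  expect_equal(perfect$auroc_mortality, 1)
  expect_equal(sum(perfect$confusion), length(obs))
  row <- report_row(perfect)
  expect_equal(row$accuracy, 1)
  expect_identical(names(row)[1:2], c("model", "n"))
})
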