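# Multi-category evaluation suite for 8-level GOSE predictions: accuracy
# within k categories, one-vs-rest macro statistics, discrepancy and
# category-proportion balance measures, dichotomized AUROCs, confusion
# matrix, error distribution and calibration curves.

check_pred_obs <- function(pred, obs, allow_empty = FALSE) {
  stopifnot(length(pred) == length(obs))
  if (!allow_empty && length(pred) == 0L) stop("empty input")
  stopifnot(all(pred %in% GOSE_LEVELS), all(obs %in% GOSE_LEVELS))
  invisible(TRUE)
}

#' Accuracy within k categories
#'
#' Fraction of patients whose predicted GOSE lies within `k` categories of
#' the observed GOSE; `k = 0` is plain accuracy, `k = 1` is AW1 and
#' `k = 2` is AW2.
#'
#' @param pred,obs integer GOSE vectors of equal nonzero length.
#' @param k non-negative integer tolerance.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy_within <- function(pred, obs, k = 0L) {
  check_pred_obs(pred, obs)
  stopifnot(k >= 0)
  mean(abs(pred - obs) <= k)
}

#' Mean and standard-deviation discrepancy
#'
#' `md = mean(pred) - mean(obs)`: positive values flag an optimistic model
#' (overestimated outcome), negative a pessimistic one. `sdd = sd(pred) -
#' sd(obs)` (sample sd, n-1): negative values mean the predictions are
#' less variable than the observations. `sdd` is `NA` for n < 2.
#'
#' @param pred,obs integer GOSE vectors of equal nonzero length.
#' @return List with `md` and `sdd` (GOSE units).
#' @export
discrepancy_stats <- function(pred, obs) {
  check_pred_obs(pred, obs)
  list(md = mean(pred) - mean(obs),
       sdd = if (length(pred) >= 2L) sd(pred) - sd(obs) else NA_real_)
}

#' Category-proportion discrepancies
#'
#' Predicted (PCP) and observed (OCP) category proportions over all 8 GOSE
#' levels (zero for absent levels), their total absolute difference
#' `tcpd = sum_j |pcp_j - ocp_j|` (0 = perfectly balanced, 2 = disjoint
#' supports) and maximum absolute difference `mcpd` (largest single-level
#' bias, in `[0, 1]`).
#'
#' @param pred,obs integer GOSE vectors of equal nonzero length.
#' @return List with `pcp`, `ocp` (length-8 fractions), `tcpd`, `mcpd`.
#' @export
category_proportion_discrepancy <- function(pred, obs) {
  check_pred_obs(pred, obs)
  pcp <- tabulate(pred, nbins = 8L) / length(pred)
  ocp <- tabulate(obs, nbins = 8L) / length(obs)
  list(pcp = setNames(pcp, GOSE_LEVELS), ocp = setNames(ocp, GOSE_LEVELS),
       tcpd = sum(abs(pcp - ocp)), mcpd = max(abs(pcp - ocp)))
}

#' One-vs-rest macro statistics
#'
#' For each GOSE category present in `obs` or `pred`, computes one-vs-rest
#' sensitivity (recall), specificity and precision, then macro-averages:
#' average balanced accuracy `aba = mean_j (sensitivity_j +
#' specificity_j) / 2`, and macro precision / recall / specificity.
#' Per-category terms with a zero denominator (category never observed, or
#' never predicted for precision) are excluded from the affected averages;
#' the number of exclusions is reported.
#'
#' @param pred,obs integer GOSE vectors of equal nonzero length.
#' @return List with `aba`, `precision_macro`, `recall_macro`,
#'   `specificity_macro`, a `per_category` data.frame, and `n_excluded`.
#' @export
one_vs_rest_stats <- function(pred, obs) {
  check_pred_obs(pred, obs)
  n <- length(obs)
  cats <- sort(union(unique(obs), unique(pred)))
  per <- lapply(cats, function(j) {
    tp <- sum(pred == j & obs == j)
    fp <- sum(pred == j & obs != j)
    fn <- sum(pred != j & obs == j)
    tn <- n - tp - fp - fn
    data.frame(category = j,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
  per <- do.call(rbind, per)
  per$balanced_accuracy <- (per$sensitivity + per$specificity) / 2
  macro <- function(v) mean(v[!is.na(v)])
  list(aba = macro(per$balanced_accuracy),
       precision_macro = macro(per$precision),
       recall_macro = macro(per$sensitivity),
       specificity_macro = macro(per$specificity),
       per_category = per,
       n_excluded = sum(is.na(per[, c("sensitivity", "specificity", "precision")])))
}

# Mann-Whitney rank AUROC with 0.5 credit for ties.
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC of the classic dichotomized outcomes
#'
#' Scores each patient with the model's probability of the positive class
#' of the classic TBI dichotomy: mortality (`GOSE 1` vs survival `2-8`,
#' score `p1`) or unfavorable outcome (`GOSE 1-4` vs favorable `5-8`,
#' score `p1+p2+p3+p4`), and computes the AUROC by the rank
#' (Mann-Whitney) formulation with ties counted 0.5.
#'
#' @param probabilities `n x 8` matrix of category probabilities.
#' @param obs observed GOSE vector.
#' @param split `"mortality"` or `"unfavorable"`.
#' @return AUROC fraction, or `NA` with a warning when only one class is
#'   present after dichotomization.
#' @export
dichotomized_auroc <- function(probabilities, obs, split = c("mortality", "unfavorable")) {
  split <- match.arg(split)
  probabilities <- as.matrix(probabilities)
  stopifnot(nrow(probabilities) == length(obs), ncol(probabilities) == 8L)
  if (split == "mortality") {
    scores <- probabilities[, 1]
    positive <- obs == 1L
  } else {
    scores <- rowSums(probabilities[, 1:4, drop = FALSE])
    positive <- obs <= 4L
  }
  auc <- rank_auc(scores, positive)
  if (is.na(auc)) {
    warning("dichotomized_auroc: only one class present after the '",
            split, "' split; AUROC undefined")
  }
  auc
}

#' 8 x 8 confusion matrix
#'
#' Counts with rows = observed GOSE and columns = predicted GOSE (the
#' orientation of the study's confusion heat maps). `sum(diag(.)) / n`
#' equals plain accuracy.
#'
#' @param pred,obs integer GOSE vectors of equal length (may be empty).
#' @return An `8 x 8` integer matrix, dimnames `observed` x `predicted`.
#' @export
confusion_matrix <- function(pred, obs) {
  check_pred_obs(pred, obs, allow_empty = TRUE)
  m <- matrix(0L, 8L, 8L,
              dimnames = list(observed = GOSE_LEVELS, predicted = GOSE_LEVELS))
  if (length(obs)) {
    tab <- table(factor(obs, levels = GOSE_LEVELS),
                 factor(pred, levels = GOSE_LEVELS))
    m[] <- as.integer(tab)
  }
  m
}

#' Prediction error distribution
#'
#' Histogram of `obs - pred` over the signed range -7..+7. Negative values
#' mean the model overestimated prognosis (predicted better than
#' observed), positive that it underestimated.
#'
#' @param pred,obs integer GOSE vectors of equal length.
#' @return Named integer vector of counts over `-7..7`.
#' @export
error_distribution <- function(pred, obs) {
  check_pred_obs(pred, obs, allow_empty = TRUE)
  d <- factor(obs - pred, levels = -7:7)
  setNames(as.integer(table(d)), -7:7)
}

#' Calibration curve for one GOSE category
#'
#' Bins patients by the predicted probability of the category (quantile
#' bins) and compares, per bin, the mean predicted probability against the
#' observed frequency of that category, with a binomial standard error.
#' When there are fewer distinct probabilities than requested bins,
#' adjacent bins are merged with a warning.
#'
#' @param probabilities `n x 8` probability matrix.
#' @param obs observed GOSE vector.
#' @param category GOSE level 1-8.
#' @param n_bins number of quantile bins (>= 2).
#' @return A `gose_calibration` data.frame with columns `mean_predicted`,
#'   `observed_freq`, `se`, `count`.
#' @export
calibration_curve <- function(probabilities, obs, category, n_bins = 10L) {
  probabilities <- as.matrix(probabilities)
  stopifnot(n_bins >= 2L, category %in% GOSE_LEVELS,
            nrow(probabilities) == length(obs))
  p <- probabilities[, category]
  breaks <- unique(quantile(p, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(breaks) < n_bins + 1L) {
    warning("calibration_curve: fewer distinct probabilities than bins; ",
            length(breaks) - 1L, " bin(s) used")
  }
  if (length(breaks) == 1L) breaks <- c(breaks, breaks + 1e-12)
  bin <- cut(p, breaks = breaks, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- which(bin == b)
    f <- mean(obs[i] == category)
    data.frame(mean_predicted = mean(p[i]), observed_freq = f,
               se = sqrt(f * (1 - f) / length(i)), count = length(i))
  }))
  attr(out, "category") <- category
  class(out) <- c("gose_calibration", "data.frame")
  out
}

#' Full evaluation report for a prediction set
#'
#' Computes every summary of the evaluation suite from one
#' [prediction_set()]: accuracy, AW1, AW2, ABA, macro precision / recall /
#' specificity, MD, SDD, PCP/OCP with TCPD and MCPD, the dichotomized
#' AUROCs, and the 8 x 8 confusion matrix.
#'
#' @param prediction_set a [prediction_set()].
#' @return A `gose_report` list; see [report_row()] for the flat
#'   table-style row.
#' @export
full_report <- function(prediction_set) {
  ps <- prediction_set
  stopifnot(inherits(ps, "gose_prediction_set"))
  if (length(ps$observed) == 0L) stop("empty prediction set")
  pred <- ps$predicted; obs <- ps$observed
  ovr <- one_vs_rest_stats(pred, obs)
  disc <- discrepancy_stats(pred, obs)
  cpd <- category_proportion_discrepancy(pred, obs)
  auroc_m <- tryCatch(dichotomized_auroc(ps$probabilities, obs, "mortality"),
                      warning = function(w) NA_real_)
  auroc_u <- tryCatch(dichotomized_auroc(ps$probabilities, obs, "unfavorable"),
                      warning = function(w) NA_real_)
  structure(list(
    model_tag = ps$model_tag,
    n = length(obs),
    accuracy = accuracy_within(pred, obs, 0L),
    aw1 = accuracy_within(pred, obs, 1L),
    aw2 = accuracy_within(pred, obs, 2L),
    aba = ovr$aba,
    precision_macro = ovr$precision_macro,
    recall_macro = ovr$recall_macro,
    specificity_macro = ovr$specificity_macro,
    md = disc$md,
    sdd = disc$sdd,
    pcp = cpd$pcp,
    ocp = cpd$ocp,
    tcpd = cpd$tcpd,
    mcpd = cpd$mcpd,
    auroc_mortality = auroc_m,
    auroc_unfavorable = auroc_u,
    confusion = confusion_matrix(pred, obs),
    error_distribution = error_distribution(pred, obs),
    n_excluded_categories = ovr$n_excluded
  ), class = "gose_report")
}

#' Flatten a report into a one-row data.frame
#'
#' Column layout mirrors the study's model-performance summary table:
#' accuracy, AW1, AW2, ABA, precision, recall, specificity, MD, SDD, TCPD,
#' MCPD, AUROC-U, AUROC-M.
#'
#' @param report a `gose_report`.
#' @return One-row data.frame.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "gose_report"))
  data.frame(model = report$model_tag, n = report$n,
             accuracy = report$accuracy, aw1 = report$aw1, aw2 = report$aw2,
             aba = report$aba, precision = report$precision_macro,
             recall = report$recall_macro,
             specificity = report$specificity_macro,
             md = report$md, sdd = report$sdd,
             tcpd = report$tcpd, mcpd = report$mcpd,
             auroc_unfavorable = report$auroc_unfavorable,
             auroc_mortality = report$auroc_mortality,
             stringsAsFactors = FALSE)
}

#' @export
print.gose_report <- function(x, ...) {
  cat(sprintf("<gose_report> %s (n=%d)\n", x$model_tag, x$n))
  row <- report_row(x)
  print(cbind(row[, -(1:2)]), row.names = FALSE, digits = 3)
  invisible(x)
}
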