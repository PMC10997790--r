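make_imbalanced <- function() {
  counts <- c(`1` = 50, `3` = 30, `8` = 100)
  df <- data.frame(
    patient_id = sprintf("P%03d", seq_len(sum(counts))),
    age = runif(sum(counts), 20, 90),
    gcs_motor = sample(1:6, sum(counts), TRUE),
    pupils = sample(c("both", "one", "none"), sum(counts), TRUE),
    marshall = sample(c("diffuse_I", "diffuse_II", "evacuated_mass"),
                      sum(counts), TRUE),
    gose = rep(c(1L, 3L, 8L), times = counts)
  )
  cohort(df)
}

test_that("balanced undersampling follows the min-count rule", {
  set.seed(1)
  co <- make_imbalanced()
  sub <- balanced_undersample(co, seed = 5)
  expect_equal(nrow(sub), 90)                     # 30 per class
  expect_true(all(table(sub$gose) == 30))
  # target larger than every class returns the cohort whole
  whole <- balanced_undersample(co, target_per_class = 500, seed = 5)
  expect_equal(nrow(whole), nrow(co))
  # determinism
  expect_identical(balanced_undersample(co, seed = 7)$patient_id,
                   balanced_undersample(co, seed = 7)$patient_id)
  expect_error(balanced_undersample(co[0, , drop = FALSE]), "empty|gose_cohort")
})

test_that("m = 1 with a full-cohort target degenerates to a single POLR", {
  co <- simulate_cohort(profile_config("uppsala", n = 400, seed = 9))
  d <- encode_design(co)
  ens <- fit_ensemble(co, m = 1, target_per_class = nrow(co), seed = 2)
  single <- polr_fit(d, co$gose)
  expect_equal(ensemble_predict(ens, d), polr_predict(single, d),
               tolerance = 1e-9)
  # every member's subsample is per-class balanced (or the whole class)
  counts <- table(co$gose)
  plan_counts <- table(co$gose[co$patient_id %in% ens$subsample_plan[[1]]])
  expect_equal(as.integer(plan_counts), as.integer(pmin(counts, nrow(co))))
})

test_that("median aggregation matches a hand-computed example and renormalizes", {
  # three intercept-only members with known category-8 probabilities
  v <- function(p8, p1) c(p1, 0.01, 0.01, 0.01, 0.01, 0.01, 1 - p1 - p8 - 0.05, p8)
  members <- list(manual_polr(v(0.2, 0.3)), manual_polr(v(0.5, 0.1)),
                  manual_polr(v(0.9, 0.02)))
  ens <- structure(list(members = members, m = 3L,
                        subsample_plan = list(), aggregation = "median",
                        retries = integer(3), encoding = NULL, seed = 1L),
                   class = "gose_ensemble")
  X <- empty_design(2)
  out <- ensemble_predict(ens, X)
  raw_median <- apply(sapply(list(v(0.2, 0.3), v(0.5, 0.1), v(0.9, 0.02)),
                             identity), 1, median)
  expect_equal(unname(out[1, ]), raw_median / sum(raw_median), tolerance = 1e-12)
  expect_equal(unname(out[1, 8] * sum(raw_median)), 0.5)  # pre-normalization median
  expect_equal(rowSums(out), c(1, 1), tolerance = 1e-12)
  # identical members collapse to the member prediction exactly
  ens2 <- ens; ens2$members <- members[c(1, 1, 1)]
  expect_equal(unname(ensemble_predict(ens2, X)[1, ]), v(0.2, 0.3),
               tolerance = 1e-12)
  # monotone: raising one member's category probability cannot lower the median
  ens3 <- ens; ens3$members[[1]] <- manual_polr(v(0.6, 0.1))
  expect_gte(ensemble_predict(ens3, X)[1, 8] , out[1, 8])
})

test_that("ensemble spreads predictions over more GOSE categories than one POLR", {
  co <- simulate_cohort(profile_config("uppsala", n = 866, seed = 33))
  d <- encode_design(co)
  ens <- fit_ensemble(co, m = 50, seed = 4)
  single <- polr_fit(d, co$gose)
  support_ens <- unique(goseprog:::argmax_low(ensemble_predict(ens, d)))
  support_single <- unique(goseprog:::argmax_low(polr_predict(single, d)))
  expect_gt(length(support_ens), length(support_single))
  expect_true(all(ens$retries <= 5))
  # plan balanced for every member
  for (ids in ens$subsample_plan[1:5]) {
    cls <- table(co$gose[co$patient_id %in% ids])
    expect_true(max(cls) == min(cls))
  }
})

test_that("ensembles serialize to a member directory and back", {
  co <- simulate_cohort(profile_config("uppsala", n = 600, seed = 44))
  d <- encode_design(co)
  ens <- fit_ensemble(co, m = 3, seed = 6)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  back <- read_ensemble(dir)
  expect_equal(ensemble_predict(back, d), ensemble_predict(ens, d),
               tolerance = 1e-12)
})
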