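# Uppsala register fractions the generator must reproduce.
UPPSALA_GOSE <- c(126, 10, 158, 65, 88, 87, 131, 201) / 866

test_that("simulation is deterministic given the config seed", {
  cfg <- profile_config("uppsala", n = 300, seed = 11)
  expect_identical(as.data.frame(simulate_cohort(cfg)),
                   as.data.frame(simulate_cohort(cfg)))
  cfg2 <- profile_config("uppsala", n = 300, seed = 12)
  expect_false(identical(simulate_cohort(cfg)$gose, simulate_cohort(cfg2)$gose))
})

test_that("config validation rejects malformed inputs", {
  cfg <- profile_config("uppsala", n = 10, seed = 1)
  expect_error(generator_config("uppsala", 10, cfg$covariate_marginals,
                                cfg$age_distribution, 0.3,
                                cfg$beta_true, rev(cfg$zeta_true)),
               "increasing")
  bad <- cfg$covariate_marginals
  bad$pupils <- c(both = 0.5, one = 0.2, none = 0.2)
  expect_error(generator_config("uppsala", 10, bad, cfg$age_distribution,
                                0.3, cfg$beta_true, cfg$zeta_true),
               "summing to 1")
  expect_error(profile_config("oslo", 10), "should be one of")
})

test_that("null-effect configs reproduce the implied GOSE marginal", {
  cfg <- profile_config("uppsala", n = 100000, seed = 21)
  cfg$beta_true[] <- 0
  cfg$zeta_true <- qlogis(cumsum(UPPSALA_GOSE)[1:7])
  co <- simulate_cohort(cfg)
  emp <- tabulate(co$gose, 8) / nrow(co)
  expect_lt(max(abs(emp - UPPSALA_GOSE)), 0.01)
})

test_that("profile marginals match the documented cohort fractions", {
  cfg <- profile_config("uppsala", n = 100000, seed = 31)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$gcs_motor == 6) - 0.46), 0.01)
  expect_lt(abs(mean(co$pupils == "both") - 0.86), 0.01)
  expect_lt(abs(mean(co$marshall == "diffuse_II") - 0.45), 0.01)
  # outcome marginal after zeta calibration
  expect_lt(max(abs(tabulate(co$gose, 8) / nrow(co) - UPPSALA_GOSE)), 0.015)
  # external-profile anchors are configured exactly
  expect_equal(unname(profile_config("protect", 10)$covariate_marginals$gcs_motor["6"]),
               0.03)
  expect_equal(unname(profile_config("leuven", 10)$covariate_marginals$gcs_motor["6"]),
               0.76)
})

test_that("harmful covariate levels push simulated GOSE down", {
  cfg <- profile_config("uppsala", n = 20000, seed = 41)
  co <- simulate_cohort(cfg)
  expect_lt(mean(co$gose[co$pupils == "none"]), mean(co$gose[co$pupils == "both"]))
  expect_lt(mean(co$gose[co$gcs_motor <= 2]), mean(co$gose[co$gcs_motor == 6]))
})

test_that("severity coupling induces positive covariate dependence", {
  cfg <- profile_config("uppsala", n = 10000, seed = 51, severity_coupling = 0.3)
  co <- simulate_cohort(cfg)
  sev_gcs <- -co$gcs_motor                       # higher = more severe
  sev_pup <- match(co$pupils, c("both", "one", "none"))
  expect_gt(cor(sev_gcs, sev_pup, method = "spearman"), 0)
  # and independence at coupling zero
  cfg0 <- profile_config("uppsala", n = 10000, seed = 51, severity_coupling = 0)
  co0 <- simulate_cohort(cfg0)
  sev_pup0 <- match(co0$pupils, c("both", "one", "none"))
  expect_lt(abs(cor(-co0$gcs_motor, sev_pup0, method = "spearman")), 0.03)
})

test_that("generated outcomes obey the proportional-odds property", {
  # isolate one covariate so marginal group-wise cumulative logits are exact
  cfg <- profile_config("uppsala", n = 150000, seed = 61, severity_coupling = 0)
  cfg$beta_true[] <- 0
  cfg$beta_true["pupils_none"] <- -1.5
  co <- simulate_cohort(cfg)
  cum_logit <- function(y) {
    p <- cumsum(tabulate(y, 8) / length(y))[1:7]
    qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
  }
  gap <- cum_logit(co$gose[co$pupils == "none"]) -
    cum_logit(co$gose[co$pupils == "both"])
  # constant shift equal to the pupils_none coefficient, across all splits
  expect_lt(max(abs(gap - 1.5)), 0.15)
})

test_that("bayes_accuracy behaves as an oracle ceiling", {
  cfg <- profile_config("uppsala", n = 10, seed = 71)
  # degenerate: all mass on the first category
  cfg_deg <- cfg
  cfg_deg$beta_true[] <- 0
  cfg_deg$zeta_true <- seq(30, 36)
  expect_equal(bayes_accuracy(cfg_deg, n_eval = 500), 1.0)
  # null effects: Bayes accuracy is the max implied category probability
  cfg0 <- cfg
  cfg0$beta_true[] <- 0
  cfg0$zeta_true <- qlogis(cumsum(UPPSALA_GOSE)[1:7])
  expect_equal(bayes_accuracy(cfg0, n_eval = 2000), max(UPPSALA_GOSE),
               tolerance = 1e-8)
  # dominates a fitted model on fresh draws (within MC error)
  train <- simulate_cohort(profile_config("uppsala", n = 2000, seed = 72))
  fit <- polr_fit(encode_design(train), train$gose)
  fresh <- simulate_cohort(profile_config("uppsala", n = 20000, seed = 73))
  acc_fit <- mean(goseprog:::argmax_low(polr_predict(fit, encode_design(fresh))) ==
                    fresh$gose)
  expect_gte(bayes_accuracy(profile_config("uppsala", n = 10, seed = 73),
                            n_eval = 20000) + 0.01, acc_fit)
})
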