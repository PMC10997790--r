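test_that("negative log-likelihood matches hand values and the brute-force oracle", {
  # single observation, beta = 0, zeta_1 = 0: contribution -log(0.5)
  X1 <- matrix(0, 1, 1)
  expect_equal(polr_negloglik(0, 0, X1, 1L), -log(0.5))

  # two-level outcome reduces to binary logistic regression with intercept -zeta_1
  set.seed(5)
  Xb <- matrix(rnorm(60), 30, 2)
  yb <- rbinom(30, 1, 0.5) + 1L
  beta <- c(0.4, -0.7); zeta1 <- 0.3
  eta <- drop(Xb %*% beta)
  binary_nll <- -sum(log(ifelse(yb == 2L, plogis(eta - zeta1), 1 - plogis(eta - zeta1))))
  expect_equal(polr_negloglik(beta, zeta1, Xb, yb), binary_nll, tolerance = 1e-12)

  # random small instances against the independent oracle
  for (rep in 1:10) {
    set.seed(rep)
    n <- sample(5:30, 1); p <- sample(1:4, 1); J <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n)
    y <- sample.int(J, n, replace = TRUE)
    b <- rnorm(p); z <- sort(rnorm(J - 1))
    expect_equal(polr_negloglik(b, z, X, y), oracle_negloglik(b, z, X, y),
                 tolerance = 1e-10)
  }
  expect_error(polr_negloglik(c(0, 0), c(1, 0, -1), matrix(0, 2, 2), c(1L, 2L)),
               "increasing")
})

test_that("intercept-only fits recover logits of cumulative proportions", {
  y <- rep(c(1L, 3L, 5L, 8L), each = 25)
  fit <- polr_fit(empty_design(100), y)
  expect_equal(unname(fit$zeta), qlogis(c(0.25, 0.5, 0.75)), tolerance = 1e-6)
  expect_true(fit$converged)
  # predicted probabilities equal empirical frequencies, mapped to 8 levels
  probs <- polr_predict(fit, empty_design(3))
  expect_equal(unname(probs[1, ]), c(.25, 0, .25, 0, .25, 0, 0, .25),
               tolerance = 1e-6)
  expect_equal(probs[1, ], probs[3, ])
})

test_that("fit matches the MASS reference implementation", {
  skip_if_not_installed("MASS")
  co <- simulate_cohort(profile_config("uppsala", n = 1000, seed = 7))
  d <- encode_design(co)
  fit <- polr_fit(d, co$gose)
  df <- data.frame(y = factor(co$gose, ordered = TRUE), d$matrix)
  ref <- MASS::polr(y ~ ., data = df, method = "logistic")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$zeta), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("parameters are recovered from simulated data", {
  set.seed(9)
  n <- 5000
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  beta_true <- c(0.8, -0.5); zeta_true <- c(-1, 0, 1)
  cum <- sapply(zeta_true, function(z) plogis(z - drop(X %*% beta_true)))
  y <- as.integer(rowSums(runif(n) > cum) + 1L)
  fit <- polr_fit(X, y)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta - beta_true)), 0.15)
  expect_lt(max(abs(fit$zeta - zeta_true)), 0.15)
  expect_true(all(diff(fit$zeta) > 0))
  # optimality: fitted likelihood beats the generative truth on this sample
  expect_lte(polr_negloglik(fit$beta, fit$zeta, X, y),
             polr_negloglik(beta_true, zeta_true, X, y))
})

test_that("fit is equivariant to affine rescaling of a covariate", {
  co <- simulate_cohort(profile_config("uppsala", n = 800, seed = 13))
  d <- encode_design(co)
  fit1 <- polr_fit(d, co$gose)
  X2 <- d$matrix
  X2[, "age"] <- X2[, "age"] / 10
  fit2 <- polr_fit(X2, co$gose)
  expect_equal(unname(fit2$beta["age"]), unname(fit1$beta["age"] * 10),
               tolerance = 1e-5)
  expect_equal(fit2$zeta, fit1$zeta, tolerance = 1e-5)
})

test_that("rank deficiency errors by name unless dropping is requested", {
  co <- simulate_cohort(profile_config("uppsala", n = 200, seed = 17))
  X <- encode_design(co)$matrix
  X <- cbind(X, age_copy = X[, "age"])
  expect_error(polr_fit(X, co$gose), "age_copy")
  fit <- polr_fit(X, co$gose, control = polr_control(drop_collinear = TRUE))
  expect_identical(fit$dropped, "age_copy")
  expect_equal(unname(fit$beta["age_copy"]), 0)
})

test_that("prediction handles level gaps, mismatches and extreme scores", {
  # training labels missing interior levels: zero mass there at prediction
  y <- rep(c(1L, 3L, 8L), times = c(30, 40, 30))
  set.seed(2)
  X <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "x"))
  fit <- polr_fit(X, y)
  probs <- polr_predict(fit, X)
  expect_true(all(probs[, c(2, 4:7)] == 0))
  expect_equal(rowSums(probs), rep(1, 100), tolerance = 1e-12)
  # cumulative sums monotone in the category index
  cums <- t(apply(probs, 1, cumsum))
  expect_true(all(diff(t(cums)) >= -1e-12))
  # extreme linear predictor concentrates mass on the top observed category
  manual <- fit
  manual$beta <- c(x = 1)
  manual$zeta <- setNames(c(0, 1), names(fit$zeta))
  Xbig <- matrix(50, 1, 1, dimnames = list(NULL, "x"))
  expect_gt(polr_predict(manual, Xbig)[1, 8], 0.99)
  # column mismatch is an encoding error
  expect_error(polr_predict(fit, matrix(0, 1, 1, dimnames = list(NULL, "z"))),
               "encoding mismatch")
})

test_that("POLR model JSON serialization round-trips predictions", {
  co <- simulate_cohort(profile_config("uppsala", n = 300, seed = 19))
  d <- encode_design(co)
  fit <- polr_fit(d, co$gose)
  path <- withr::local_tempfile(fileext = ".json")
  write_polr(fit, path)
  back <- read_polr(path)
  expect_equal(polr_predict(back, d), polr_predict(fit, d), tolerance = 1e-12)
})
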