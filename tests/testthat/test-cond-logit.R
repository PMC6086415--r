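test_that("log-likelihood at beta = 0 is -S log(set size)", {
  d <- data.frame(set_id = rep(1:12, each = 11),
                  case = rep(c(1, rep(0, 10)), 12),
                  x = rnorm(132))
  ll0 <- cond_logit_loglik(0, cbind(d$x), d$case, d$set_id)
  expect_equal(ll0, 12 * log(1 / 11))
})

test_that("likelihood matches direct enumeration on random datasets", {
  set.seed(101)
  for (i in 1:20) {
    d <- random_cc_dataset(n_sets = 6)
    x <- as.matrix(d[, c("x1", "x2", "x3")])
    beta <- rnorm(3, sd = 0.5)
    expect_equal(cond_logit_loglik(beta, x, d$case, d$set_id),
                 oracle_cond_loglik(beta, x, d$case, d$set_id))
  }
})

test_that("likelihood is invariant to within-set row reordering", {
  set.seed(11)
  d <- random_cc_dataset(n_sets = 10)
  x <- as.matrix(d[, c("x1", "x2", "x3")])
  beta <- c(0.3, -0.2, 0.1)
  ll1 <- cond_logit_loglik(beta, x, d$case, d$set_id)
  o <- sample(nrow(d))
  ll2 <- cond_logit_loglik(beta, x[o, ], d$case[o], d$set_id[o])
  expect_equal(ll1, ll2)
})

test_that("set-constant covariates contribute nothing to the likelihood", {
  set.seed(12)
  d <- random_cc_dataset(n_sets = 8, k = 2)
  d$const <- ave(rnorm(nrow(d)), d$set_id)  # constant within each set
  x2 <- as.matrix(d[, c("x1", "x2", "const")])
  for (g in c(-2, 0, 1.5)) {
    expect_equal(cond_logit_loglik(c(0.4, -0.3, g), x2, d$case, d$set_id),
                 cond_logit_loglik(c(0.4, -0.3, 0), x2, d$case, d$set_id))
  }
  expect_warning(fit <- cond_logit(case ~ x1 + x2 + const, d),
                 "no within-set variation")
  expect_false("const" %in% names(coef(fit)))
})

test_that("matched-pair closed form log(a/b) is recovered", {
  # a pairs exposed-case-only, b pairs exposed-control-only, plus
  # concordant pairs that carry no information
  a <- 12; b <- 5
  d <- rbind(
    data.frame(set_id = seq_len(a), case = 1, x = 1),
    data.frame(set_id = seq_len(a), case = 0, x = 0),
    data.frame(set_id = a + seq_len(b), case = 1, x = 0),
    data.frame(set_id = a + seq_len(b), case = 0, x = 1),
    data.frame(set_id = a + b + 1:3, case = 1, x = 1),
    data.frame(set_id = a + b + 1:3, case = 0, x = 1))
  fit <- cond_logit(case ~ x, d)
  expect_equal(unname(coef(fit)), log(a / b), tolerance = 1e-8)
})

test_that("fit agrees with a generic optimizer and with survival::clogit", {
  set.seed(202)
  for (i in 1:10) {
    d <- random_cc_dataset(n_sets = 10)
    x <- as.matrix(d[, c("x1", "x2", "x3")])
    fit <- cond_logit(case ~ x1 + x2 + x3, d)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$gradient)), 1e-6)
    expect_lt(max(abs(unname(coef(fit)) -
                        oracle_cond_fit(x, d$case, d$set_id))), 1e-6)
  }
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  d <- random_cc_dataset(n_sets = 40)
  fit <- cond_logit(case ~ x1 + x2 + x3, d)
  sf <- survival::clogit(case ~ x1 + x2 + x3 + strata(set_id), data = d)
  expect_equal(unname(coef(fit)), unname(coef(sf)), tolerance = 1e-6)
  expect_equal(unname(diag(vcov(fit))), unname(diag(vcov(sf))),
               tolerance = 1e-5)
  expect_equal(fit$loglik, unname(sf$loglik[2]), tolerance = 1e-8)
})

test_that("null data recover beta near zero; known OR is recovered", {
  d <- simulate_ncc_study(n_persons = 6000, n_days = 60,
                          baseline_odds = 0.002, or_exposure = 1,
                          or_profile = 1, seed = 31)
  fit <- cond_logit(case ~ exposed + profile, d)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit)) < 3 * se))
  d2 <- simulate_ncc_study(n_persons = 6000, n_days = 60,
                           baseline_odds = 0.002, or_exposure = 2,
                           or_profile = 1, seed = 32)
  fit2 <- cond_logit(case ~ exposed + profile, d2)
  ci <- confint(fit2)["exposed", ]
  expect_true(ci[1] < log(2) && log(2) < ci[2])
})

test_that("separation is detected and flagged, never silent", {
  d <- data.frame(set_id = rep(1:8, each = 2),
                  case = rep(c(1, 0), 8),
                  x = rep(c(1, 0), 8))  # exposure perfectly predicts case
  expect_warning(fit <- cond_logit(case ~ x, d), "separation")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("Wald tests: single-term identity and joint additivity", {
  set.seed(44)
  d <- random_cc_dataset(n_sets = 60)
  fit <- cond_logit(case ~ x1 + x2 + x3, d)
  w <- wald_test(fit, "x1")
  expect_equal(w$statistic,
               unname((coef(fit)["x1"] / sqrt(vcov(fit)["x1", "x1"]))^2))
  expect_equal(w$df, 1)
  # joint test on independent terms equals the sum of single statistics
  forged <- structure(list(coefficients = c(a = 0.5, b = -0.3),
                           vcov = diag(c(0.04, 0.09))), class = "cond_logit")
  dimnames(forged$vcov) <- list(c("a", "b"), c("a", "b"))
  wj <- wald_test(forged, c("a", "b"))
  expect_equal(wj$statistic, 0.5^2 / 0.04 + 0.3^2 / 0.09)
  expect_equal(wj$df, 2)
  # zero coefficient gives statistic 0, p = 1
  forged$coefficients[["a"]] <- 0
  w0 <- wald_test(forged, "a")
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
})

test_that("AIC identities hold", {
  set.seed(55)
  d <- random_cc_dataset(n_sets = 50)
  f1 <- cond_logit(case ~ x1, d)
  f2 <- cond_logit(case ~ x1 + x2, d)
  expect_equal(aic(f1), 2 * 1 - 2 * f1$loglik)
  expect_equal(aic(f2) - aic(f1),
               2 * (f2$n_par - f1$n_par) - 2 * (f2$loglik - f1$loglik))
  expect_equal(AIC(f1), aic(f1))  # logLik method consistency
  # a null-effect column costs about 2 AIC on null data at moderate n
  d$noise <- rnorm(nrow(d))
  f3 <- cond_logit(case ~ x1 + x2 + noise, d)
  expect_lt(abs(aic(f3) - aic(f2)), 4)
})

test_that("predict returns within-set softmax probabilities", {
  set.seed(66)
  d <- random_cc_dataset(n_sets = 30)
  fit <- cond_logit(case ~ x1 + x2, d)
  pr <- predict(fit, d, type = "prob")
  expect_equal(as.vector(tapply(pr, d$set_id, sum)), rep(1, 30))
  lp <- predict(fit, d, type = "lp")
  expect_equal(lp, as.numeric(as.matrix(d[, c("x1", "x2")]) %*% coef(fit)))
})
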