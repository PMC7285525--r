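test_that("group-mean worked example: both routes give OR 2.04", {
  y <- c(rep(0.04, 12), rep(0.02, 12))
  X <- cbind(`(Intercept)` = 1, group = rep(c(1, 0), each = 12))
  fit <- fit_fracreg(y, X)
  or_fit <- odds_ratio(fit, "group")
  or_closed <- (0.04 * (1 - 0.02)) / (0.02 * (1 - 0.04))
  expect_equal(or_fit$or, or_closed, tolerance = 1e-8)
  expect_equal(round(or_fit$or, 2), 2.04)
  # saturated group model reproduces the group means exactly
  expect_equal(unique(round(fit$fitted, 10)), c(0.04, 0.02))
})

test_that("intercept-only fit on y = 0.5 gives beta0 = 0", {
  y <- rep(0.5, 20)
  X <- matrix(1, 20, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_fracreg(y, X)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-10)
  o <- odds_ratio(fit, "(Intercept)")
  expect_equal(o$or, 1, tolerance = 1e-8)
  # constant y makes the robust SE degenerate at 0, so the interval
  # collapses onto the point estimate
  expect_true(o$ci[1] <= 1 && o$ci[2] >= 1)
})

test_that("IRLS matches brute-force quasi-likelihood maximisation", {
  set.seed(30)
  n <- 20
  x <- rnorm(n)
  y <- pmin(pmax(plogis(-1 + 0.8 * x) + rnorm(n, 0, 0.05), 0), 1)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_fracreg(y, X)
  grid <- gridfit_fracreg2(y, X)
  expect_equal(unname(coef(fit)), grid, tolerance = 1e-4)
})

test_that("quasi-score equations vanish at the optimum", {
  set.seed(31)
  n <- 150
  X <- cbind(`(Intercept)` = 1, g = rbinom(n, 1, 0.5), z = rnorm(n))
  y <- pmin(pmax(plogis(-2 + 0.5 * X[, 2] + 0.3 * X[, 3]) *
                   (1 + rnorm(n, 0, 0.2)), 0), 1)
  fit <- fit_fracreg(y, X)
  expect_lt(max(abs(crossprod(X, y - fit$fitted))), 1e-6)
  expect_true(fit$converged)
  # covariance is symmetric PSD with finite quasi-log-likelihood
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_true(is.finite(fit$loglik))
})

test_that("estimates agree with quasibinomial GLM and HC1 sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(32)
  n <- 120
  g <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  y <- pmin(pmax(plogis(-2.5 + 0.6 * g + 0.2 * z) * 2 * rbeta(n, 6, 6),
                 0), 1)
  fit <- fit_fracreg(y, cbind(`(Intercept)` = 1, g = g, z = z))
  gl <- suppressWarnings(glm(y ~ g + z, family = quasibinomial()))
  expect_equal(unname(coef(fit)), unname(coef(gl)), tolerance = 1e-8)
  V <- sandwich::vcovHC(gl, type = "HC1")
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-5)
})

test_that("group OR is invariant to affine covariate rescaling", {
  set.seed(33)
  n <- 200
  g <- rbinom(n, 1, 0.5)
  age <- runif(n, 50, 85)
  y <- pmin(pmax(plogis(-3 + 0.7 * g + 0.01 * age) *
                   (1 + rnorm(n, 0, 0.1)), 0), 1)
  f1 <- fit_fracreg(y, cbind(`(Intercept)` = 1, g = g, age = age))
  f2 <- fit_fracreg(y, cbind(`(Intercept)` = 1, g = g,
                             age = (age - 65) / 10))
  expect_equal(coef(f1)[["g"]], coef(f2)[["g"]], tolerance = 1e-6)
  expect_equal(coef(f1)[["age"]], coef(f2)[["age"]] / 10,
               tolerance = 1e-6)
  expect_equal(odds_ratio(f1, "g")$or, odds_ratio(f2, "g")$or,
               tolerance = 1e-6)
})

test_that("responses outside [0,1] and unknown terms are rejected", {
  X <- cbind(`(Intercept)` = rep(1, 5))
  expect_error(fit_fracreg(c(0.1, 0.2, 1.3, 0, 0.5), X), "\\[0, 1\\]")
  fit <- fit_fracreg(rep(0.3, 5), X)
  expect_error(odds_ratio(fit, "group"), "no term")
})
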