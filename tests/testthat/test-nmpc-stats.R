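test_that("skew-minimising log transform straightens log-normal data", {
  set.seed(60)
  x <- matrix(exp(rnorm(400, 1, 0.8)), ncol = 2,
              dimnames = list(NULL, c("met_a", "met_b")))
  tr <- transform_nmpc(x)
  for (met in colnames(x)) {
    v <- tr$values[, met]
    v <- v[!is.na(v)]
    sk <- mean((v - mean(v))^3) / sd(v)^3
    expect_lt(abs(sk), 0.25)
  }
  expect_identical(tr$retained, c("met_a", "met_b"))
  # transform parameters invert back to the raw values where unmasked
  back <- exp(tr$values[, "met_a"]) - tr$shift[["met_a"]]
  ok <- !is.na(back)
  expect_equal(back[ok], x[ok, "met_a"], tolerance = 1e-9)
})

test_that("sparse and constant metabolites are filtered out", {
  set.seed(61)
  x <- cbind(kept = exp(rnorm(100)),
             sparse = c(rep(0, 60), exp(rnorm(40))),
             zero = rep(0, 100))
  expect_message(tr <- transform_nmpc(x), "dropped")
  expect_identical(tr$retained, "kept")
  expect_identical(unname(tr$dropped["sparse"]), "<=50% nonzero")
  expect_identical(unname(tr$dropped["zero"]), "all zero")
})

test_that("LMM reduces to OLS when batches carry no signal", {
  set.seed(62)
  n <- 200
  g <- rbinom(n, 1, 0.5)
  X <- cbind(`(Intercept)` = 1, g = g)
  y <- 1 + 0.5 * g + rnorm(n)
  batch <- rep(c("b1", "b2", "b3", "b4"), each = n / 4)
  fit <- fit_lmm(y, X, batch)
  ols <- lm(y ~ g)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-4)
  expect_lt(fit$batch_variance, 0.05)
  # single batch falls back to OLS with a warning
  expect_warning(f1 <- fit_lmm(y, X, rep("b1", n)), "single batch")
  expect_identical(f1$method, "ols")
  expect_equal(unname(f1$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("a planted group effect is recovered with batch structure", {
  set.seed(63)
  n <- 300
  g <- rbinom(n, 1, 0.5)
  batch <- sample(paste0("b", 1:5), n, TRUE)
  beff <- stats::setNames(rnorm(5, 0, 0.6), paste0("b", 1:5))
  y <- 2 + 0.5 * g + beff[batch] + rnorm(n, 0, 0.8)
  fit <- fit_lmm(y, cbind(`(Intercept)` = 1, g = g), batch)
  expect_identical(fit$method, "lmm")
  expect_gt(fit$batch_variance, 0.02)
  ci <- fit$coefficients[["g"]] + c(-2, 2) * fit$se[["g"]]
  expect_gt(0.5, ci[1])
  expect_lt(0.5, ci[2])
})

test_that("Hausman statistic is zero for identical fits", {
  fit <- list(coefficients = c(`(Intercept)` = 1, g = 0.4, z = -0.2),
              vcov = diag(c(0.1, 0.05, 0.02)))
  dimnames(fit$vcov) <- list(names(fit$coefficients),
                             names(fit$coefficients))
  h <- hausman_test(fit, fit)
  expect_equal(h$statistic, 0, tolerance = 1e-12)
  # invariant to covariate ordering
  fe <- list(coefficients = c(`(Intercept)` = 1, g = 0.5, z = -0.1),
             vcov = diag(c(0.1, 0.08, 0.05)))
  dimnames(fe$vcov) <- list(names(fe$coefficients),
                            names(fe$coefficients))
  re <- list(coefficients = c(z = -0.2, g = 0.4, `(Intercept)` = 1),
             vcov = diag(c(0.02, 0.05, 0.09)))
  dimnames(re$vcov) <- list(names(re$coefficients),
                            names(re$coefficients))
  h1 <- hausman_test(fe, re, terms = c("g", "z"))
  h2 <- hausman_test(fe, re, terms = c("z", "g"))
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-12)
})

test_that("Hausman agrees with the FE-vs-RE comparison on real fits", {
  set.seed(64)
  n <- 240
  g <- rbinom(n, 1, 0.5)
  batch <- sample(paste0("b", 1:4), n, TRUE)
  y <- 1 + 0.3 * g + rnorm(n)
  re <- fit_lmm(y, cbind(`(Intercept)` = 1, g = g), batch, reml = FALSE)
  Xfe <- cbind(`(Intercept)` = 1, g = g,
               stats::model.matrix(~ batch)[, -1, drop = FALSE])
  ols <- lm(y ~ 0 + Xfe)
  fe <- list(coefficients = stats::setNames(coef(ols), colnames(Xfe)),
             vcov = {
               V <- vcov(ols)
               dimnames(V) <- list(colnames(Xfe), colnames(Xfe))
               V
             })
  h <- hausman_test(fe, re, terms = "g")
  expect_gte(h$statistic, 0)
  expect_gte(h$p, 0.001) # RE assumption holds in this simulation
})

test_that("variance contributions implement r and the strong flag", {
  set.seed(65)
  n <- 80
  ab <- cbind(gA = runif(n), gB = runif(n), gC = rep(0.3, n))
  nm <- cbind(m1 = 2 * ab[, "gA"], m2 = rnorm(n))
  vc <- variance_contribution(ab, nm)
  exact <- vc[vc$genus == "gA" & vc$metabolite == "m1", ]
  expect_equal(exact$r, 1, tolerance = 1e-12)
  expect_true(exact$strong)
  expect_equal(vc$r2, vc$r^2)
  # zero-variance columns give NA, not zero
  expect_true(all(is.na(vc$r[vc$genus == "gC"])))
  # flag keys on r > 0.5, not a re-rounded r2
  vc2 <- variance_contribution(
    cbind(g = c(1, 2, 3, 4, 5)),
    cbind(m = c(1.1, 2.4, 2.9, 3.6, 5.5)))
  expect_identical(vc2$strong, vc2$r > 0.5)
})

test_that("independent columns have mean r^2 near 1/(n-1)", {
  set.seed(66)
  n <- 40
  ab <- matrix(rnorm(n * 15), n, 15,
               dimnames = list(NULL, paste0("g", 1:15)))
  nm <- matrix(rnorm(n * 15), n, 15,
               dimnames = list(NULL, paste0("m", 1:15)))
  vc <- variance_contribution(ab, nm)
  expect_lt(abs(mean(vc$r2) - 1 / (n - 1)), 0.012)
})
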