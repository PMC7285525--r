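#' Transform NMPCs for association analysis
#'
#' Per metabolite, a shifted log transform `log(x + c)` is applied with
#' the shift `c` selected from a declared grid (the smallest positive
#' value times 0.5 and 1, and a log-spaced grid from 1e-6 to 1) so that
#' the absolute sample skewness of the transformed values is minimal. The
#' very differently skewed raw NMPC distributions motivate a per-
#' metabolite choice. After transforming, only metabolites with more than
#' 50% nonzero raw values are retained, and the 4-SD outlier rule is
#' applied per metabolite.
#'
#' @param nmpc samples x metabolites matrix of raw NMPCs (>= 0);
#'   infeasible samples as `NA` rows.
#' @param min_nonzero minimum fraction of nonzero raw values (default
#'   0.5, strict).
#' @param sd_k outlier masking threshold in SDs (default 4).
#' @return list with `values` (transformed matrix, masked entries `NA`),
#'   `shift` (named numeric of chosen `c`), `retained` (metabolite ids),
#'   `dropped` (named character of reasons).
#' @export
transform_nmpc <- function(nmpc, min_nonzero = 0.5, sd_k = 4) {
  stopifnot(is.matrix(nmpc))
  if (any(nmpc < 0, na.rm = TRUE)) stop("NMPCs must be non-negative")
  skew <- function(x) {
    x <- x[!is.na(x)]
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) return(0)
    mean((x - m)^3) / s^3
  }
  dropped <- character(0)
  shift <- numeric(0)
  keep <- character(0)
  out <- NULL
  for (met in colnames(nmpc)) {
    x <- nmpc[, met]
    obs <- x[!is.na(x)]
    if (!length(obs) || all(obs == 0)) {
      dropped[met] <- "all zero"
      next
    }
    if (mean(obs > 0) <= min_nonzero) {
      dropped[met] <- "<=50% nonzero"
      next
    }
    # distributions dominated by one repeated value (e.g. pure diet
    # passthrough capacities) are unsuitable for regression analysis
    modal <- max(table(signif(obs, 10))) / length(obs)
    if (modal > 0.5) {
      dropped[met] <- ">50% identical values"
      next
    }
    minpos <- min(obs[obs > 0])
    grid <- unique(c(minpos * c(0.5, 1), 10^seq(-6, 0, length.out = 13)))
    sk <- vapply(grid, function(cc) abs(skew(log(obs + cc))), numeric(1))
    cc <- grid[which.min(sk)]
    shift[met] <- cc
    keep <- c(keep, met)
    out <- cbind(out, log(x + cc))
  }
  if (length(dropped)) {
    message("dropped metabolites: ",
            paste(names(dropped), dropped, sep = " (", collapse = "), "),
            ")")
  }
  if (is.null(out)) stop("no metabolite passes the nonzero filter")
  colnames(out) <- keep
  rownames(out) <- rownames(nmpc)
  out <- mask_outliers(out, k = sd_k)
  list(values = out, shift = shift, retained = keep, dropped = dropped)
}

#' Linear mixed model with batch random intercept
#'
#' Association model for transformed NMPCs: fixed effects for the
#' predictor of interest and the standard covariates, with the sequencing
#' batch as a random intercept (REML by default). A single batch falls
#' back to ordinary least squares with a warning. The random-effect
#' treatment of batch has more power than fixed batch effects but relies
#' on stronger assumptions, which [hausman_test()] probes.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix including the intercept.
#' @param batch batch identifiers.
#' @param reml fit by REML (default) or ML.
#' @return object of class `lmm_fit`: `coefficients`, `se`, `vcov`,
#'   `batch_variance`, `residual_variance`, `loglik`, `method`
#'   ("lmm" or "ols").
#' @export
fit_lmm <- function(y, X, batch, reml = TRUE) {
  X <- as.matrix(X)
  ok <- stats::complete.cases(y, X, batch)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  batch <- droplevels(as.factor(batch[ok]))
  if (nlevels(batch) < 2L) {
    warning("single batch: falling back to ordinary least squares")
    fit <- stats::lm.fit(X, y)
    res <- fit$residuals
    df <- length(y) - ncol(X)
    s2 <- sum(res^2) / df
    V <- s2 * solve(crossprod(X))
    return(structure(list(coefficients = fit$coefficients,
                          se = sqrt(diag(V)), vcov = V,
                          batch_variance = 0, residual_variance = s2,
                          loglik = as.numeric(stats::logLik(
                            stats::lm(y ~ X - 1))),
                          method = "ols", n = length(y)),
                     class = "lmm_fit"))
  }
  keep <- colnames(X) != "(Intercept)"
  # standardise predictors for the optimiser, then map estimates back
  ctr <- colMeans(X[, keep, drop = FALSE])
  scl <- apply(X[, keep, drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr), 2, scl, "/")
  dat <- data.frame(.y = y, Z, .batch = batch, check.names = FALSE)
  fml <- stats::reformulate(
    c(sprintf("`%s`", colnames(Z)), "(1 | .batch)"),
    response = ".y")
  fit <- lme4::lmer(fml, data = dat, REML = reml)
  vc <- as.data.frame(lme4::VarCorr(fit))
  fez <- lme4::fixef(fit)
  Vz <- as.matrix(stats::vcov(fit))
  # back-transform: beta_j = beta'_j / s_j; intercept absorbs the centring
  k <- length(fez) - 1L
  A <- diag(c(1, 1 / scl))
  A[1, 1 + seq_len(k)] <- -ctr / scl
  fe <- stats::setNames(as.vector(A %*% fez),
                        c("(Intercept)", colnames(Z)))
  V <- A %*% Vz %*% t(A)
  dimnames(V) <- list(names(fe), names(fe))
  structure(list(coefficients = fe, se = sqrt(diag(V)), vcov = V,
                 batch_variance = vc$vcov[vc$grp == ".batch"],
                 residual_variance = vc$vcov[vc$grp == "Residual"],
                 loglik = as.numeric(stats::logLik(fit)),
                 method = "lmm", n = length(y)),
            class = "lmm_fit")
}

#' Hausman specification test
#'
#' Compares the random-effects estimator of the common fixed-effect
#' coefficients against the fixed-effects (batch-dummy) estimator:
#' `H = d' (V_FE - V_RE)^- d` with `d` the coefficient difference, a
#' chi-squared reference on the rank of the variance difference. Under
#' the random-effects assumption both estimators are consistent and `H`
#' is small; a Moore-Penrose pseudo-inverse is used when the variance
#' difference is singular (noted in the result).
#'
#' @param fe_fit,re_fit fits exposing `coefficients` and `vcov` (e.g.
#'   [fit_lmm()] results, or any list with those elements).
#' @param terms coefficients to compare; default: all shared terms
#'   except the intercept.
#' @return list with `statistic`, `df`, `p` and `pseudo_inverse` flag.
#' @export
hausman_test <- function(fe_fit, re_fit, terms = NULL) {
  if (is.null(terms)) {
    terms <- setdiff(intersect(names(fe_fit$coefficients),
                               names(re_fit$coefficients)),
                     "(Intercept)")
  }
  stopifnot(length(terms) >= 1L)
  d <- fe_fit$coefficients[terms] - re_fit$coefficients[terms]
  dV <- fe_fit$vcov[terms, terms, drop = FALSE] -
    re_fit$vcov[terms, terms, drop = FALSE]
  ev <- eigen((dV + t(dV)) / 2, symmetric = TRUE)
  pos <- ev$values > max(ev$values, 0) * 1e-8
  pseudo <- sum(pos) < length(terms) || any(ev$values < -1e-8)
  inv <- ev$vectors[, pos, drop = FALSE] %*%
    diag(1 / ev$values[pos], sum(pos)) %*%
    t(ev$vectors[, pos, drop = FALSE])
  H <- max(0, as.numeric(t(d) %*% inv %*% d))
  df <- sum(pos)
  list(statistic = H, df = df,
       p = stats::pchisq(H, df, lower.tail = FALSE),
       pseudo_inverse = pseudo)
}

#' Genus-to-metabolite variance contribution
#'
#' Pairwise Pearson correlation between genus abundances and (analysis-
#' ready) NMPC values; the squared correlation is the variance
#' contribution, and correlations above 0.5 (25% of variance) are flagged
#' as strong.
#'
#' @param abundance samples x genera matrix.
#' @param nmpc samples x metabolites matrix aligned on rows.
#' @param strong_r threshold on `r` for the strong flag (default 0.5).
#' @return data.frame with `genus`, `metabolite`, `r`, `r2`, `strong`;
#'   zero-variance columns yield `NA`, not 0.
#' @export
variance_contribution <- function(abundance, nmpc, strong_r = 0.5) {
  stopifnot(nrow(abundance) == nrow(nmpc))
  out <- expand.grid(genus = colnames(abundance),
                     metabolite = colnames(nmpc),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- mapply(function(g, m) {
    x <- abundance[, g]
    y <- nmpc[, m]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok])
  }, out$genus, out$metabolite)
  out$r2 <- out$r^2
  out$strong <- !is.na(out$r) & out$r > strong_r
  out
}
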