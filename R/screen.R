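#' Build a fractional-regression design matrix
#'
#' Standard design used across taxon screens: intercept, the predictor of
#' interest, and the adjustment set of technical covariates (batch as
#' fixed-effect indicators, total and unclassified read counts entered
#' linearly), age as a restricted cubic spline (3 knots at the 5th, 50th
#' and 95th percentiles), sex and BMI. Rows with missing values in any
#' modelled variable are dropped (complete-case analysis; missing values
#' are not imputed) and counted.
#'
#' @param metadata data.frame with the modelled columns.
#' @param predictor column name of the predictor of interest; a factor or
#'   logical becomes indicator column(s), a numeric enters linearly.
#' @param interaction optional character vector of covariates whose
#'   interaction with the predictor forms the tested block (e.g.
#'   `c("age", "sex", "bmi")`); all interaction terms enter
#'   simultaneously.
#' @param adjust adjustment variables; defaults to the standard set.
#' @param extra_adjust additional columns entered linearly (e.g. disease
#'   duration for within-case analyses).
#' @param age_spline model age via a restricted cubic spline (default) or
#'   linearly.
#' @return list with `X` (design matrix over complete cases), `rows`
#'   (logical complete-case index into `metadata`), `test_terms` (the
#'   column names of the tested block) and `n_dropped`.
#' @export
fracreg_design <- function(metadata, predictor = "group",
                           interaction = NULL,
                           adjust = c("age", "sex", "bmi", "batch",
                                      "total_reads", "unclassified_reads"),
                           extra_adjust = character(),
                           age_spline = TRUE) {
  adjust <- setdiff(adjust, predictor)
  used <- unique(c(predictor, interaction, adjust, extra_adjust))
  miss <- setdiff(used, names(metadata))
  if (length(miss)) {
    stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  }
  rows <- stats::complete.cases(metadata[, used, drop = FALSE])
  md <- metadata[rows, , drop = FALSE]
  expand <- function(v) {
    x <- md[[v]]
    if (is.logical(x)) x <- factor(x, c(FALSE, TRUE))
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      lev <- levels(droplevels(x))
      if (length(lev) < 2L) {
        stop("variable '", v, "' is constant on the complete cases")
      }
      cols <- vapply(lev[-1L], function(l) as.numeric(x == l),
                     numeric(nrow(md)))
      colnames(cols) <- paste0(v, lev[-1L])
      cols
    } else if (v == "age" && age_spline) {
      b <- rcs_basis(x)
      colnames(b) <- c("age", "age'")[seq_len(ncol(b))]
      b
    } else if (v %in% c("total_reads", "unclassified_reads")) {
      m <- matrix(x / 1e4, ncol = 1, dimnames = list(NULL, v))
      m
    } else {
      matrix(x, ncol = 1, dimnames = list(NULL, v))
    }
  }
  pred_cols <- expand(predictor)
  X <- cbind(`(Intercept)` = 1, pred_cols)
  for (v in c(adjust, extra_adjust)) X <- cbind(X, expand(v))
  test_terms <- colnames(pred_cols)
  if (!is.null(interaction)) {
    if (ncol(pred_cols) != 1L) {
      stop("interaction blocks require a single-column predictor")
    }
    icols <- NULL
    for (v in interaction) {
      vc <- expand(v)
      pc <- vc * pred_cols[, 1L]
      colnames(pc) <- paste0(colnames(pred_cols), ":", colnames(vc))
      icols <- cbind(icols, pc)
    }
    # main effects of interacted variables must already be present
    add <- setdiff(unlist(lapply(interaction, function(v) {
      colnames(expand(v))
    })), colnames(X))
    for (v in interaction) {
      vc <- expand(v)
      keep <- intersect(colnames(vc), add)
      if (length(keep)) X <- cbind(X, vc[, keep, drop = FALSE])
    }
    X <- cbind(X, icols)
    test_terms <- colnames(icols)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; check collinear covariates")
  }
  list(X = X, rows = rows, test_terms = test_terms,
       n_dropped = sum(!rows))
}

#' Screen taxa with fractional regressions
#'
#' Runs one fractional logit regression per taxon, with the taxon's
#' relative abundance as the response and the configured predictor of
#' interest (study group, constipation, a severity score, or an
#' interaction block tested jointly by a Wald test), adjusted for the
#' standard covariate set. P-values are collected over all tested taxa
#' and adjusted by the Benjamini-Hochberg procedure at FDR `q`.
#'
#' @param rel relative abundance matrix (after prevalence filtering and
#'   outlier masking; masked entries are `NA` and drop their sample from
#'   that taxon's regression only).
#' @param metadata data.frame aligned with `rownames(rel)` via
#'   `sample_id`.
#' @param predictor,interaction,extra_adjust,age_spline see
#'   [fracreg_design()].
#' @param q target false discovery rate (default 0.05).
#' @param subset optional logical/index vector of samples to analyse
#'   (e.g. cases only for within-disease phenotypes).
#' @return data.frame of class `screen_result`: per taxon the log-odds
#'   estimate, odds ratio with 95% CI (single-term predictors), robust
#'   SE, p, BH-adjusted q-value, significance flag at `q`, sample count
#'   and convergence flag. Attribute `n_tests` records the family size;
#'   skipped zero-variance taxa are excluded from it.
#' @export
screen_taxa <- function(rel, metadata, predictor = "group",
                        interaction = NULL, extra_adjust = character(),
                        age_spline = TRUE, q = 0.05, subset = NULL) {
  stopifnot(!is.null(rownames(rel)), "sample_id" %in% names(metadata))
  metadata <- metadata[match(rownames(rel), metadata$sample_id), ,
                       drop = FALSE]
  if (!is.null(subset)) {
    rel <- rel[subset, , drop = FALSE]
    metadata <- metadata[subset, , drop = FALSE]
  }
  dz <- fracreg_design(metadata, predictor = predictor,
                       interaction = interaction,
                       extra_adjust = extra_adjust,
                       age_spline = age_spline)
  single <- length(dz$test_terms) == 1L && is.null(interaction)
  res <- lapply(colnames(rel), function(tx) {
    y <- rel[dz$rows, tx]
    ok <- !is.na(y)
    if (sum(ok) < ncol(dz$X) + 2L || stats::var(y[ok]) == 0) {
      message("skipping zero-variance or underpowered taxon: ", tx)
      return(NULL)
    }
    fit <- fit_fracreg(y[ok], dz$X[ok, , drop = FALSE])
    if (single) {
      orr <- odds_ratio(fit, dz$test_terms)
      data.frame(taxon = tx, estimate = orr$log_or, or = orr$or,
                 ci_lo = orr$ci[1], ci_hi = orr$ci[2], se = orr$se,
                 p = orr$p, n = sum(ok), converged = fit$converged,
                 stringsAsFactors = FALSE)
    } else {
      w <- wald_block_test(fit, dz$test_terms)
      data.frame(taxon = tx, estimate = NA_real_, or = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, se = NA_real_,
                 p = w$p, n = sum(ok), converged = fit$converged,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable taxa")
  fdr <- bh_fdr(out$p, q)
  out$q_value <- fdr$adjusted
  out$significant <- fdr$reject
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  attr(out, "n_dropped_samples") <- dz$n_dropped
  class(out) <- c("screen_result", "data.frame")
  out
}
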