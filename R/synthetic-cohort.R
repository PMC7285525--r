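#' Specify a simulated case-control cohort
#'
#' Parameters for a Dirichlet-multinomial cohort generator with planted,
#' recoverable effects. Group effects are planted on mean relative
#' abundances through the logit transform, so a fractional logit regression
#' of a taxon's relative abundance on the group indicator recovers exactly
#' the planted odds ratio in expectation. Age effects are planted as a
#' quadratic on the logit scale, exercising the spline machinery; batch
#' effects are additive logit shifts drawn once per batch and taxon.
#'
#' Distributional defaults (read depth, dispersion, concentration,
#' unclassified rate) are declared package choices: the emulated study
#' design reports no such quantities.
#'
#' @param n_cases,n_controls group sizes (their sum must be at least 4).
#' @param taxon_effects named numeric vector of target odds ratios (case
#'   vs control on mean relative abundance); `NULL` plants ORs 1.5, 2.04
#'   and 3 on the first three species of the universe.
#' @param covariate_effects list with optional elements `age` (named list
#'   of `c(linear, quadratic)` logit coefficients per decade of age,
#'   centred at 65), `sex` and `bmi` (named numeric); `NULL` plants small
#'   defaults on the next taxa of the universe.
#' @param n_batches number of sequencing batches (default 2).
#' @param read_depth `c(mean, dispersion)` of the negative-binomial total
#'   read count (default 30000 reads, size 10).
#' @param concentration Dirichlet concentration (default 300; larger means
#'   less compositional overdispersion).
#' @param unclassified_rate expected fraction of reads without taxonomic
#'   assignment (default 0.08).
#' @param batch_sd SD of per-batch logit shifts (default 0.1).
#' @param age_means,age_sd mean age in cases/controls and common SD;
#'   ages are truncated at 50.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 150L, n_controls = 160L,
                        taxon_effects = NULL, covariate_effects = NULL,
                        n_batches = 2L, read_depth = c(30000, 10),
                        concentration = 300, unclassified_rate = 0.08,
                        batch_sd = 0.1, age_means = c(69.3, 63.3),
                        age_sd = 8.5, seed = 1L) {
  if (n_cases + n_controls < 4L) {
    stop("degenerate cohort: need at least 4 individuals in total")
  }
  if (!is.null(taxon_effects) && any(taxon_effects <= 0)) {
    stop("target odds ratios must be positive")
  }
  stopifnot(n_batches >= 1L, read_depth[1] >= 1, concentration > 0,
            unclassified_rate >= 0, unclassified_rate < 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 taxon_effects = taxon_effects,
                 covariate_effects = covariate_effects,
                 n_batches = as.integer(n_batches),
                 read_depth = read_depth,
                 concentration = concentration,
                 unclassified_rate = unclassified_rate,
                 batch_sd = batch_sd, age_means = age_means,
                 age_sd = age_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a simulated cohort
#'
#' Draws per-sample taxon counts and metadata. For each sample, classified
#' reads are allocated by a Dirichlet-multinomial whose mean vector is
#' built on the logit scale: baseline log-odds per taxon, plus the planted
#' group log-odds ratio, covariate terms and batch shifts. The last
#' species of the universe acts as the compositional absorber so that the
#' expected relative abundance of every other taxon equals its inverse
#' logit exactly. Total read counts are negative binomial; a binomial
#' share of reads is left unclassified. Row sums of counts (classified
#' plus unclassified) equal the sampled read depth exactly, and identical
#' seeds give byte-identical tables.
#'
#' @param spec a [cohort_spec()].
#' @param universe a [universe_spec()] providing the taxon labels.
#' @return list with `counts` (integer matrix, samples x taxa, last column
#'   `unclassified`) and `metadata` (data.frame with sample id, group,
#'   age, sex, BMI, batch, total/unclassified reads, constipation and
#'   disease-severity columns).
#' @export
generate_cohort <- function(spec, universe) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(universe, "universe_spec"))
  taxa <- universe$species_names
  if (length(taxa) < 2L) stop("universe must contain at least 2 species")
  filler <- taxa[length(taxa)]
  eff <- spec$taxon_effects
  if (is.null(eff)) {
    k <- min(3L, length(taxa) - 1L)
    eff <- stats::setNames(c(1.5, 2.04, 3)[seq_len(k)], taxa[seq_len(k)])
  }
  if (!all(names(eff) %in% taxa)) {
    stop("taxon_effects references taxa outside the universe: ",
         paste(setdiff(names(eff), taxa), collapse = ", "))
  }
  if (filler %in% names(eff)) {
    stop("no effect can be planted on the absorber taxon '", filler, "'")
  }
  cov_eff <- spec$covariate_effects
  if (is.null(cov_eff)) {
    free <- setdiff(taxa, c(names(eff), filler))
    cov_eff <- list(
      age = if (length(free) >= 1L) {
        stats::setNames(list(c(0.15, -0.10)), free[1L])
      },
      sex = if (length(free) >= 2L) stats::setNames(0.3, free[2L]),
      bmi = if (length(free) >= 3L) stats::setNames(0.02, free[3L]))
  }
  rng <- .local_rng(spec$seed)
  n <- spec$n_cases + spec$n_controls
  group <- rep(c("PD", "Control"), c(spec$n_cases, spec$n_controls))
  is_case <- group == "PD"
  age <- pmax(50, rng$norm(n, ifelse(is_case, spec$age_means[1],
                                     spec$age_means[2]), spec$age_sd))
  sex <- ifelse(rng$unif(n) < 0.33, "F", "M")
  bmi <- pmax(16, rng$norm(n, 27.5, 4.6))
  batch <- paste0("B", 1L + (rng$int(spec$n_batches, n, replace = TRUE) - 1L))
  constipation <- rng$unif(n) < ifelse(is_case, 0.37, 0.06)
  hoehn_yahr <- ifelse(is_case, pmin(5, pmax(1, round(rng$norm(n, 2.2, 0.6)))),
                       NA_real_)
  updrs3 <- ifelse(is_case, pmax(0, round(rng$norm(n, 34.6, 16.1))),
                   NA_real_)
  disease_duration <- ifelse(is_case, round(abs(rng$norm(n, 5.9, 5.7)), 1),
                             NA_real_)
  # taxon baselines: non-filler taxa get small mean fractions summing to a
  # third of the classified mass; drawn once from the cohort seed
  nt <- length(taxa) - 1L
  base <- exp(rng$norm(nt, log(0.01), 0.8))
  base <- pmin(base, 0.04)
  base <- base / sum(base) * 0.35
  names(base) <- setdiff(taxa, filler)
  # per-batch, per-taxon logit shifts
  bshift <- matrix(rng$norm(spec$n_batches * nt, 0, spec$batch_sd),
                   spec$n_batches, nt,
                   dimnames = list(paste0("B", seq_len(spec$n_batches)),
                                   names(base)))
  depth <- pmax(2000, rng$nbinom(n, mu = spec$read_depth[1],
                                 size = spec$read_depth[2]))
  unclassified <- rng$binom(n, depth, spec$unclassified_rate)
  classified <- depth - unclassified
  counts <- matrix(0L, n, length(taxa) + 1L,
                   dimnames = list(sprintf("S%04d", seq_len(n)),
                                   c(taxa, "unclassified")))
  asc <- (age - 65) / 10
  for (j in seq_len(n)) {
    eta <- stats::qlogis(base)
    if (is_case[j]) {
      eta[names(eff)] <- eta[names(eff)] + log(eff)
    }
    for (tx in names(cov_eff$age)) {
      a <- cov_eff$age[[tx]]
      eta[tx] <- eta[tx] + a[1] * asc[j] + a[2] * asc[j]^2
    }
    for (tx in names(cov_eff$sex)) {
      if (sex[j] == "F") eta[tx] <- eta[tx] + cov_eff$sex[[tx]]
    }
    for (tx in names(cov_eff$bmi)) {
      eta[tx] <- eta[tx] + cov_eff$bmi[[tx]] * (bmi[j] - 27.5)
    }
    eta <- eta + bshift[batch[j], ]
    p <- stats::plogis(eta)
    pf <- 1 - sum(p)
    if (pf <= 0.05) {
      stop("planted effects push the absorber taxon below 5% of the ",
           "composition; reduce baselines or effects")
    }
    mean_vec <- c(p, stats::setNames(pf, filler))
    # mean_vec is already in taxa order (absorber last)
    g <- rng$gamma(length(mean_vec), shape = spec$concentration * mean_vec,
                   rate = 1)
    w <- g / sum(g)
    counts[j, seq_along(taxa)] <-
      as.integer(rng$multinom(1, classified[j], w))
  }
  counts[, "unclassified"] <- as.integer(unclassified)
  metadata <- data.frame(
    sample_id = rownames(counts), group = group, age = age, sex = sex,
    bmi = bmi, batch = batch, total_reads = as.integer(depth),
    unclassified_reads = as.integer(unclassified),
    constipation = constipation, hoehn_yahr = hoehn_yahr,
    updrs3 = updrs3, disease_duration = disease_duration,
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}

#' Write a cohort to TSV files
#'
#' @param cohort output of [generate_cohort()].
#' @param dir destination directory.
#' @return invisible character vector of the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fc <- file.path(dir, "counts.tsv")
  fm <- file.path(dir, "metadata.tsv")
  cts <- data.frame(sample_id = rownames(cohort$counts), cohort$counts,
                    check.names = FALSE)
  utils::write.table(cts, fc, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$metadata, fm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fc, fm))
}
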