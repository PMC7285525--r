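#' Run the full two-tier analysis pipeline
#'
#' Orchestrates an end-to-end run: (1) input or simulation of a count
#' table, metadata, strain reconstructions and a diet; (2) relative
#' abundances, prevalence filtering, outlier masking, alpha/beta
#' diversity with permutation tests; (3) fractional-regression screening
#' of the group effect with FDR control; (4) pan-species merging,
#' personalised community models and NMPC computation; (5) NMPC
#' transformation, mixed-model screening and genus variance attribution.
#' Every dropped sample, taxon or metabolite is logged with a reason to a
#' line-delimited JSON log, and a re-run with the same configuration and
#' seed reproduces all tables bit-identically.
#'
#' @param config configuration list, or path to a YAML file with the
#'   same structure. Recognised fields: `seed` (mandatory), `out_dir`,
#'   `simulate` (parameters for [universe_spec()] and [cohort_spec()]),
#'   or `inputs` (paths: `counts`, `metadata`, `models_dir`, `diet`),
#'   `stages` (logical toggles `diversity`, `screen`, `modelling`,
#'   `nmpc_stats`), and `settings` (`fdr_q`, `n_perm`,
#'   `presence_threshold`, `biomass_bounds`, `min_prevalence`).
#' @return invisible list with the in-memory results of each executed
#'   stage; tables are also written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir %||% "gutflux_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- utils::modifyList(
    list(diversity = TRUE, screen = TRUE, modelling = TRUE,
         nmpc_stats = TRUE), config$stages %||% list())
  st <- utils::modifyList(
    list(fdr_q = 0.05, n_perm = 999, presence_threshold = 1e-4,
         biomass_bounds = c(0.4, 1), min_prevalence = 0.5),
    config$settings %||% list())
  logfile <- file.path(out_dir, "log.jsonl")
  unlink(logfile)
  logit <- function(stage, event, ...) {
    rec <- c(list(stage = stage, event = event), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logfile, append = TRUE)
  }
  results <- list()

  # --- inputs -------------------------------------------------------
  if (!is.null(config$inputs)) {
    prof <- load_count_table(config$inputs$counts)
    metadata <- utils::read.delim(config$inputs$metadata,
                                  stringsAsFactors = FALSE)
    files <- list.files(config$inputs$models_dir, pattern = "\\.(json|xml)$",
                        full.names = TRUE)
    files <- files[!duplicated(sub("\\.(json|xml)$", "", files))]
    strains <- lapply(files, read_model)
    species <- sub("__.*$", "", vapply(strains, `[[`, character(1), "id"))
    recons <- split(strains, species)
    diet <- utils::read.delim(config$inputs$diet, stringsAsFactors = FALSE)
  } else {
    sim <- config$simulate %||% list()
    uargs <- sim[intersect(names(sim),
                           names(formals(universe_spec)))]
    uargs$seed <- seed
    u <- do.call(universe_spec, uargs)
    cargs <- sim[intersect(names(sim), names(formals(cohort_spec)))]
    cargs$seed <- seed + 1L
    cs <- do.call(cohort_spec, cargs)
    recons <- generate_toy_reconstructions(u)
    diet <- generate_diet(u)
    cohort <- generate_cohort(cs, u)
    prof <- taxonomic_profile(cohort$counts)
    metadata <- cohort$metadata
    write_cohort(cohort, out_dir)
    utils::write.table(diet, file.path(out_dir, "diet.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    logit("simulate", "generated", n_samples = nrow(prof$counts),
          n_taxa = ncol(prof$counts))
  }

  # --- abundances ---------------------------------------------------
  rel_all <- to_relative(prof)
  rel <- prevalence_filter(rel_all, st$min_prevalence)
  logit("abundance", "prevalence_filter",
        dropped_taxa = setdiff(colnames(rel_all), colnames(rel)))
  rel <- mask_outliers(rel)
  logit("abundance", "outlier_mask", n_masked = sum(attr(rel, "mask")))
  utils::write.table(
    data.frame(sample_id = rownames(rel), rel, check.names = FALSE),
    file.path(out_dir, "relative_abundance.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  results$relative_abundance <- rel

  if (isTRUE(stages$diversity)) {
    alpha <- alpha_diversity(rel_all)
    utils::write.table(alpha, file.path(out_dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bc <- bray_curtis(rel_all)
    grp <- metadata$group[match(rownames(rel_all), metadata$sample_id)]
    results$anosim <- anosim(bc, grp, n_perm = st$n_perm, seed = seed)
    results$permanova <- permanova(bc, grp, n_perm = st$n_perm,
                                   seed = seed)
    results$alpha <- alpha
    logit("diversity", "anosim", R = results$anosim$statistic,
          p = results$anosim$p.value)
  }

  if (isTRUE(stages$screen)) {
    scr <- screen_taxa(rel, metadata, predictor = "group", q = st$fdr_q)
    utils::write.table(scr, file.path(out_dir, "screen_group.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$screen <- scr
    logit("screen", "group", n_tests = attr(scr, "n_tests"),
          n_significant = sum(scr$significant))
  }

  if (isTRUE(stages$modelling)) {
    pans <- lapply(recons, build_pan_species)
    names(pans) <- names(recons)
    nt <- nmpc_table(pans, rel_all, diet,
                     presence_threshold = st$presence_threshold,
                     biomass_bounds = st$biomass_bounds)
    utils::write.table(
      data.frame(sample_id = rownames(nt$nmpc), nt$nmpc,
                 check.names = FALSE),
      file.path(out_dir, "nmpc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    results$nmpc <- nt
    logit("modelling", "nmpc",
          infeasible_samples = names(nt$feasible)[!nt$feasible],
          mean_species = mean(nt$model_size$species),
          mean_reactions = mean(nt$model_size$reactions))
  }

  if (isTRUE(stages$nmpc_stats) && isTRUE(stages$modelling)) {
    tr <- transform_nmpc(results$nmpc$nmpc)
    logit("nmpc_stats", "transform", retained = tr$retained,
          dropped = as.list(tr$dropped))
    md <- metadata[match(rownames(tr$values), metadata$sample_id), ]
    dz <- fracreg_design(md, predictor = "group")
    scr <- do.call(rbind, lapply(colnames(tr$values), function(met) {
      y <- tr$values[dz$rows, met]
      fit <- fit_lmm(y, dz$X, md$batch[dz$rows])
      b <- fit$coefficients[["groupPD"]]
      se <- fit$se[["groupPD"]]
      data.frame(metabolite = met, estimate = b, se = se,
                 p = 2 * stats::pnorm(-abs(b / se)),
                 stringsAsFactors = FALSE)
    }))
    fdr <- bh_fdr(scr$p, st$fdr_q)
    scr$q_value <- fdr$adjusted
    scr$significant <- fdr$reject
    utils::write.table(scr, file.path(out_dir, "nmpc_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$nmpc_screen <- scr
    vc <- variance_contribution(
      rel_all[rownames(tr$values), , drop = FALSE], tr$values)
    utils::write.table(vc, file.path(out_dir, "variance_contribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$variance_contribution <- vc
    logit("nmpc_stats", "screen", n_tests = nrow(scr),
          n_significant = sum(scr$significant))
  }

  logit("pipeline", "done")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
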