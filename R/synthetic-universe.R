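#' Specify a toy reconstruction universe
#'
#' Defines a small universe of species, strains, diet metabolites and
#' species-specific secretion capabilities from which
#' [generate_toy_reconstructions()] builds strain-level metabolic models.
#' It stands in for a strain-resolved reconstruction collection of gut
#' microbes so the community-modelling machinery can be exercised and
#' tested end to end with analytically known secretion capacities.
#'
#' @param n_species number of species (default 8).
#' @param strains_per_species strains per species (default 2).
#' @param diet_metabolites metabolite identifiers available from the diet.
#' @param secretion_map named list (by species) of named numeric vectors
#'   `metabolite -> maximal yield per unit substrate`; `NULL` assigns each
#'   species one or two secretions from a fixed metabolite pool,
#'   deterministically from `seed`.
#' @param species_names optional species labels; defaults to
#'   `Species_1 ... Species_n` style binomials.
#' @param seed integer seed controlling all randomised assignments.
#' @return object of class `universe_spec`.
#' @export
universe_spec <- function(n_species = 8L, strains_per_species = 2L,
                          diet_metabolites = c("glc", "fru", "lcts"),
                          secretion_map = NULL, species_names = NULL,
                          seed = 1L) {
  stopifnot(n_species >= 1L, strains_per_species >= 1L,
            length(diet_metabolites) >= 1L)
  if (is.null(species_names)) {
    species_names <- sprintf("Species_%02d", seq_len(n_species))
  }
  stopifnot(length(species_names) == n_species,
            !anyDuplicated(species_names))
  pool <- c("ac", "but", "ppa", "gaba", "h2s", "lac_L", "succ", "for")
  if (is.null(secretion_map)) {
    rng <- .local_rng(seed)
    secretion_map <- stats::setNames(lapply(seq_len(n_species), function(i) {
      k <- rng$int(2L, 1L) # 1 or 2 secreted metabolites
      mets <- pool[((i - 1L + seq_len(k) - 1L) %% length(pool)) + 1L]
      stats::setNames(round(0.5 + 1.5 * rng$unif(k), 2), mets)
    }), species_names)
  }
  bad <- setdiff(unlist(lapply(secretion_map, names)),
                 c(pool, diet_metabolites))
  if (length(bad)) {
    stop("secretion_map references unknown metabolites: ",
         paste(unique(bad), collapse = ", "))
  }
  if (!all(names(secretion_map) %in% species_names)) {
    stop("secretion_map references unknown species")
  }
  structure(list(n_species = as.integer(n_species),
                 strains_per_species = as.integer(strains_per_species),
                 diet_metabolites = diet_metabolites,
                 secretion_map = secretion_map,
                 species_names = species_names,
                 seed = as.integer(seed)),
            class = "universe_spec")
}

# Small self-contained RNG wrapper so generators are deterministic under
# their own seed without touching the caller's .Random.seed.
.local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    s
  })
  call_with <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, globalenv())
        }
      })
      f(...)
    }
  }
  list(unif = call_with(stats::runif),
       norm = call_with(stats::rnorm),
       int = call_with(function(n, ...) sample.int(n, ...)),
       sample = call_with(sample),
       gamma = call_with(stats::rgamma),
       nbinom = call_with(stats::rnbinom),
       binom = call_with(stats::rbinom),
       multinom = call_with(stats::rmultinom))
}

#' Generate toy strain reconstructions
#'
#' Builds, for every strain of every species in the universe, a small
#' feasible metabolic network: a diet-substrate uptake exchange, a
#' transporter, a unit-yield biomass reaction, and one secretion pathway
#' per secreted metabolite with the specified yield (unit stoichiometry
#' elsewhere). Strains of one species differ in at least one reaction
#' (later strains gain an alternative substrate pathway), so pan-species
#' merging is nontrivial. The maximal secretion of a planted metabolite by
#' a single strain is `yield * (uptake - biomass demand)` by construction,
#' which keeps oracles analytic.
#'
#' @param spec a [universe_spec()].
#' @return named list (by species) of lists of strain `metabolic_model`s.
#' @export
generate_toy_reconstructions <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  nd <- length(spec$diet_metabolites)
  out <- stats::setNames(vector("list", spec$n_species), spec$species_names)
  for (i in seq_len(spec$n_species)) {
    sp <- spec$species_names[i]
    primary <- spec$diet_metabolites[[((i - 1L) %% nd) + 1L]]
    sec <- spec$secretion_map[[sp]]
    if (is.null(sec)) sec <- stats::setNames(numeric(0), character(0))
    strains <- vector("list", spec$strains_per_species)
    for (k in seq_len(spec$strains_per_species)) {
      subs <- primary
      if (k > 1L && nd > 1L) {
        # strain variation: an alternative substrate pathway
        alt <- spec$diet_metabolites[[((i - 1L + k - 1L) %% nd) + 1L]]
        if (alt != primary) subs <- c(primary, alt)
      }
      # biomass coefficient varies slightly by strain so pan-averaging is
      # observable
      bcoef <- 1 + 0.2 * (k - 1L)
      mets <- data.frame(id = c(paste0(subs, "_e"), paste0(subs, "_c"),
                                "biomass_c",
                                if (length(sec)) paste0(names(sec), "_e")),
                         compartment = c(rep("e", length(subs)),
                                         rep("c", length(subs)), "c",
                                         rep("e", length(sec))),
                         stringsAsFactors = FALSE)
      rx <- list()
      st <- list()
      for (s in subs) {
        ex <- paste0("EX_", s, "_e")
        tr <- paste0("T_", s)
        rx[[ex]] <- data.frame(id = ex, lb = -10, ub = 1000, obj = 0)
        st[[ex]] <- data.frame(reaction = ex,
                               metabolite = paste0(s, "_e"), coef = -1)
        rx[[tr]] <- data.frame(id = tr, lb = 0, ub = 1000, obj = 0)
        st[[tr]] <- data.frame(reaction = tr,
                               metabolite = paste0(s, c("_e", "_c")),
                               coef = c(-1, 1))
      }
      if (length(subs) > 1L) {
        # route the alternative substrate into the primary pool so the
        # extra pathway is functional, not a dead end
        cv <- paste0("CONV_", subs[2L], "_", subs[1L])
        rx[[cv]] <- data.frame(id = cv, lb = 0, ub = 1000, obj = 0)
        st[[cv]] <- data.frame(reaction = cv,
                               metabolite = paste0(subs[2:1], "_c"),
                               coef = c(-1, 1))
      }
      rx[["BIOMASS"]] <- data.frame(id = "BIOMASS", lb = 0, ub = 1000,
                                    obj = 1)
      st[["BIOMASS"]] <- data.frame(
        reaction = "BIOMASS",
        metabolite = c(paste0(subs[1L], "_c"), "biomass_c"),
        coef = c(-bcoef, 1))
      rx[["EX_biomass_e"]] <- data.frame(id = "EX_biomass_e", lb = 0,
                                         ub = 1000, obj = 0)
      st[["EX_biomass_e"]] <- data.frame(reaction = "EX_biomass_e",
                                         metabolite = "biomass_c",
                                         coef = -1)
      for (m in names(sec)) {
        sr <- paste0("SEC_", m)
        ex <- paste0("EX_", m, "_e")
        rx[[sr]] <- data.frame(id = sr, lb = 0, ub = 1000, obj = 0)
        st[[sr]] <- data.frame(reaction = sr,
                               metabolite = c(paste0(primary, "_c"),
                                              paste0(m, "_e")),
                               coef = c(-1, sec[[m]]))
        rx[[ex]] <- data.frame(id = ex, lb = 0, ub = 1000, obj = 0)
        st[[ex]] <- data.frame(reaction = ex, metabolite = paste0(m, "_e"),
                               coef = -1)
      }
      strains[[k]] <- metabolic_model(
        sprintf("%s__strain%d", sp, k), mets,
        do.call(rbind, rx), do.call(rbind, st))
    }
    out[[sp]] <- strains
  }
  out
}

#' Generate a diet for a universe
#'
#' One positive, finite uptake bound per diet metabolite. Bounds are drawn
#' deterministically from the universe seed on a moderate scale (5-15
#' mmol/day) so toy communities are growth-limited but feasible.
#'
#' @param spec a [universe_spec()].
#' @return data.frame with columns `metabolite` and `uptake_bound`
#'   (mmol/day).
#' @export
generate_diet <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  rng <- .local_rng(spec$seed + 2L)
  data.frame(metabolite = spec$diet_metabolites,
             uptake_bound = round(5 + 10 * rng$unif(
               length(spec$diet_metabolites)), 2),
             stringsAsFactors = FALSE)
}

#' Write strain reconstructions to a directory
#'
#' Emits every strain model in both SBML L3/FBC and JSON encodings.
#'
#' @param recons output of [generate_toy_reconstructions()].
#' @param dir destination directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_reconstructions <- function(recons, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sp in names(recons)) {
    for (m in recons[[sp]]) {
      fx <- file.path(dir, paste0(m$id, ".xml"))
      fj <- file.path(dir, paste0(m$id, ".json"))
      write_model(m, fx)
      write_model(m, fj)
      files <- c(files, fx, fj)
    }
  }
  invisible(files)
}
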