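#' Assemble a personalised community model
#'
#' Joins pan-species models into one compartmentalised community model for
#' a single sample. Species with relative abundance below the presence
#' threshold (default 1e-4) or without a matching model are removed; the
#' remaining abundances are renormalised to sum to one and written into the
#' community biomass reaction as stoichiometric coefficients. All species
#' reactions and metabolites are id-prefixed with the species label, former
#' species exchange reactions become reversible transporters into a shared
#' lumen compartment, and every lumen metabolite receives a separate diet
#' uptake reaction (`DUt_*`, closed until a diet is applied) and fecal
#' secretion exchange (`EX_*_fe`). The community biomass flux is bounded to
#' the interval `biomass_bounds`, by default \[0.4, 1\] per day,
#' corresponding to a faecal excretion of once every 2.5 days to once a
#' day.
#'
#' Each pan model must contain a biomass reaction (id `biomass_id`) whose
#' single positive-coefficient product is the species biomass metabolite;
#' its exchange, if present, is dropped during assembly.
#'
#' @param pan_models named list of pan-species `metabolic_model`s; names
#'   are the species labels used for matching.
#' @param abundances named numeric vector of relative abundances for one
#'   sample (names are taxon labels; taxa without a model are dropped and
#'   reported).
#' @param presence_threshold minimum relative abundance for a species to
#'   enter the model.
#' @param biomass_bounds length-2 numeric, community biomass flux interval
#'   (1/day).
#' @param diet optional diet specification passed to [apply_diet()].
#' @param biomass_id id of the biomass reaction in each pan model.
#' @return a `metabolic_model` with attributes `species` (named numeric of
#'   renormalised abundances), `dropped` (taxa removed and why) and
#'   `lumen_metabolites`.
#' @export
build_community <- function(pan_models, abundances,
                            presence_threshold = 1e-4,
                            biomass_bounds = c(0.4, 1), diet = NULL,
                            biomass_id = "BIOMASS") {
  stopifnot(is.numeric(abundances), !is.null(names(abundances)),
            all(abundances >= 0), length(biomass_bounds) == 2L)
  unmatched <- setdiff(names(abundances), names(pan_models))
  below <- names(abundances)[abundances < presence_threshold]
  keep <- setdiff(names(abundances)[abundances >= presence_threshold],
                  unmatched)
  if (!length(keep)) {
    stop("no species above the presence threshold with a matching model")
  }
  ab <- abundances[keep]
  ab <- ab / sum(ab)
  mets <- list()
  rxns <- list()
  st <- list()
  lumen <- character(0)
  bio_met <- character(length(keep))
  names(bio_met) <- keep
  for (sp in keep) {
    mod <- pan_models[[sp]]
    pref <- function(x) paste0(sp, "__", x)
    ex <- exchange_reactions(mod)
    sl <- .stoich_list(mod)
    bs <- sl[[biomass_id]]
    if (is.null(bs) || sum(bs > 0) != 1L) {
      stop("pan model for '", sp, "' lacks a biomass reaction '",
           biomass_id, "' with a single biomass product")
    }
    bmet <- names(bs)[bs > 0]
    bio_met[sp] <- pref(bmet)
    mets[[sp]] <- data.frame(id = pref(mod$metabolites$id),
                             compartment = mod$metabolites$compartment,
                             stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mod$reactions))) {
      r <- mod$reactions[i, ]
      co <- sl[[r$id]]
      if (r$id %in% ex) {
        m <- names(co)
        if (m == bmet) next # biomass leaves via the community reaction
        lum <- sub("_e$", "", m)
        lum_id <- paste0(lum, "_lu")
        lumen <- union(lumen, lum_id)
        tid <- paste0("IEX_", lum, "__", sp)
        rxns[[tid]] <- data.frame(id = tid, lb = -1000, ub = 1000, obj = 0)
        st[[tid]] <- data.frame(reaction = tid,
                                metabolite = c(pref(m), lum_id),
                                coef = c(-1, 1), stringsAsFactors = FALSE)
      } else {
        rid <- pref(r$id)
        rxns[[rid]] <- data.frame(id = rid, lb = r$lb, ub = r$ub, obj = 0)
        st[[rid]] <- data.frame(reaction = rid, metabolite = pref(names(co)),
                                coef = unname(co), stringsAsFactors = FALSE)
      }
    }
  }
  met_df <- rbind(do.call(rbind, mets),
                  data.frame(id = lumen, compartment = "lu",
                             stringsAsFactors = FALSE))
  for (lum_id in lumen) {
    base <- sub("_lu$", "", lum_id)
    du <- paste0("DUt_", base)
    fe <- paste0("EX_", base, "_fe")
    rxns[[du]] <- data.frame(id = du, lb = 0, ub = 0, obj = 0)
    st[[du]] <- data.frame(reaction = du, metabolite = lum_id, coef = 1,
                           stringsAsFactors = FALSE)
    rxns[[fe]] <- data.frame(id = fe, lb = 0, ub = 1000, obj = 0)
    st[[fe]] <- data.frame(reaction = fe, metabolite = lum_id, coef = -1,
                           stringsAsFactors = FALSE)
  }
  cb <- "communityBiomass"
  rxns[[cb]] <- data.frame(id = cb, lb = biomass_bounds[1],
                           ub = biomass_bounds[2], obj = 1)
  st[[cb]] <- data.frame(reaction = cb, metabolite = unname(bio_met),
                         coef = -unname(ab), stringsAsFactors = FALSE)
  out <- metabolic_model("community", met_df, do.call(rbind, rxns),
                         do.call(rbind, st))
  attr(out, "species") <- ab
  attr(out, "dropped") <- list(unmatched = unmatched,
                               below_threshold = setdiff(below, unmatched))
  attr(out, "lumen_metabolites") <- sub("_lu$", "", lumen)
  if (!is.null(diet)) out <- apply_diet(out, diet)
  out
}

#' Apply a diet to a model
#'
#' Sets the maximal uptake of each listed diet metabolite and closes all
#' unlisted uptakes (no free lunch). On a community model the diet acts on
#' the `DUt_*` lumen uptake reactions (flux in `[0, uptake]`); on a plain
#' strain or pan model it acts on the exchange-reaction lower bounds
#' (`lb = -uptake`, uptake being a negative exchange flux).
#'
#' @param model a `metabolic_model` (community or single-species).
#' @param diet named numeric vector of maximal uptakes (mmol/day), or a
#'   data.frame with columns `metabolite` and `uptake_bound`.
#' @return the modified model. Unknown diet metabolites are skipped with a
#'   warning; negative uptake values are an error.
#' @export
apply_diet <- function(model, diet) {
  if (is.data.frame(diet)) {
    diet <- stats::setNames(diet$uptake_bound, diet$metabolite)
  }
  stopifnot(is.numeric(diet), !is.null(names(diet)))
  if (any(diet < 0)) {
    stop("negative uptake bound for: ",
         paste(names(diet)[diet < 0], collapse = ", "))
  }
  dut <- grepl("^DUt_", model$reactions$id)
  if (any(dut)) {
    model$reactions$lb[dut] <- 0
    model$reactions$ub[dut] <- 0
    ids <- paste0("DUt_", names(diet))
    hit <- ids %in% model$reactions$id
    if (any(!hit)) {
      warning("diet metabolites not in the lumen, skipped: ",
              paste(names(diet)[!hit], collapse = ", "))
    }
    model$reactions$ub[match(ids[hit], model$reactions$id)] <-
      unname(diet[hit])
  } else {
    ex <- exchange_reactions(model)
    i <- model$reactions$id %in% ex
    model$reactions$lb[i] <- pmax(model$reactions$lb[i], 0)
    ids <- paste0("EX_", names(diet), "_e")
    hit <- ids %in% model$reactions$id
    if (any(!hit)) {
      warning("diet metabolites without exchange reaction, skipped: ",
              paste(names(diet)[!hit], collapse = ", "))
    }
    model$reactions$lb[match(ids[hit], model$reactions$id)] <-
      -unname(diet[hit])
  }
  validate_model(model)
  model
}

#' Net maximal production capacities of a community
#'
#' Computes, for every lumen metabolite of a personalised community model,
#' the net maximal production capacity (NMPC): the maximum of the fecal
#' secretion exchange flux obtained by flux variability analysis under the
#' applied diet constraints and the community biomass interval. An
#' infeasible community (e.g. when diet constraints cannot sustain the
#' required community biomass) is flagged rather than reported as zeros.
#'
#' @param community a community `metabolic_model` from [build_community()].
#' @return named numeric vector of NMPCs (mmol/day) with attributes
#'   `feasible` (logical), `species_count` and `reaction_count`.
#' @export
compute_nmpc <- function(community) {
  fe <- grep("^EX_.*_fe$", community$reactions$id, value = TRUE)
  res <- fva(community, fe)
  mets <- sub("^EX_(.*)_fe$", "\\1", fe)
  nm <- stats::setNames(res$max, mets)
  structure(nm,
            feasible = isTRUE(attr(res, "feasible")),
            species_count = length(attr(community, "species")),
            reaction_count = nrow(community$reactions))
}

#' NMPC table for a cohort
#'
#' Convenience wrapper assembling one personalised community model per
#' sample and collecting NMPCs into a samples x metabolites matrix.
#'
#' @param pan_models named list of pan-species models.
#' @param abundance matrix of relative abundances (samples x taxa) with
#'   dimnames.
#' @param diet diet specification (see [apply_diet()]).
#' @param ... passed to [build_community()].
#' @return list with `nmpc` (matrix, infeasible samples as `NA` rows),
#'   `feasible` (named logical), and `model_size` (data.frame of species
#'   and reaction counts per sample).
#' @export
nmpc_table <- function(pan_models, abundance, diet, ...) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)))
  seen <- character(0)
  rows <- lapply(rownames(abundance), function(s) {
    # identical diet-skip notes repeat across samples; emit each once
    withCallingHandlers({
      cm <- build_community(pan_models, abundance[s, ], diet = diet, ...)
      compute_nmpc(cm)
    }, warning = function(w) {
      msg <- conditionMessage(w)
      if (msg %in% seen) {
        invokeRestart("muffleWarning")
      } else {
        seen <<- c(seen, msg)
      }
    })
  })
  mets <- sort(unique(unlist(lapply(rows, names))))
  nm <- matrix(NA_real_, nrow(abundance), length(mets),
               dimnames = list(rownames(abundance), mets))
  feas <- stats::setNames(vapply(rows, function(r) attr(r, "feasible"),
                                 logical(1)), rownames(abundance))
  for (i in seq_along(rows)) {
    if (feas[i]) {
      # metabolites outside this sample's lumen are not secretable: 0
      nm[i, ] <- 0
      nm[i, names(rows[[i]])] <- as.numeric(rows[[i]])
    }
  }
  size <- data.frame(
    sample = rownames(abundance),
    species = vapply(rows, function(r) attr(r, "species_count"), numeric(1)),
    reactions = vapply(rows, function(r) attr(r, "reaction_count"),
                       numeric(1)))
  list(nmpc = nm, feasible = feas, model_size = size)
}

#' Relative reaction abundances
#'
#' For one sample, the relative abundance of a reaction is the sum of the
#' (renormalised) relative abundances of the included species whose pan
#' model carries that reaction; values lie in \[0, 1\].
#'
#' @param pan_models named list of pan-species models.
#' @param abundances named relative abundance vector for one sample.
#' @param presence_threshold as in [build_community()].
#' @return named numeric vector over the union of pan-model reaction ids.
#' @export
relative_reaction_abundance <- function(pan_models, abundances,
                                        presence_threshold = 1e-4) {
  keep <- intersect(names(abundances)[abundances >= presence_threshold],
                    names(pan_models))
  if (!length(keep)) {
    stop("no species above the presence threshold with a matching model")
  }
  ab <- abundances[keep]
  ab <- ab / sum(ab)
  rxns <- sort(unique(unlist(lapply(pan_models[keep], function(m) {
    m$reactions$id
  }))))
  out <- stats::setNames(numeric(length(rxns)), rxns)
  for (sp in keep) {
    ids <- pan_models[[sp]]$reactions$id
    out[ids] <- out[ids] + ab[[sp]]
  }
  out
}
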