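#' Merge strain reconstructions into a pan-species model
#'
#' Combines the metabolites and reactions of all strain-level
#' reconstructions of one species into a single pan-species model: the
#' reaction set is the union over strains, bounds are merged to the widest
#' interval where strains disagree (capability union), and a pan-biomass
#' reaction is built by averaging the strain biomass reactions. The average
#' for each biomass component is taken over the strains whose biomass
#' reaction contains that component.
#'
#' @param strains list of `metabolic_model`s of one species.
#' @param species_id identifier for the pan model (default: derived from
#'   the first strain).
#' @param biomass_id id of the biomass reaction, common to all strains
#'   (default `"BIOMASS"`).
#' @return a `metabolic_model` with attributes `species_id` and `strains`.
#' @export
build_pan_species <- function(strains, species_id = NULL,
                              biomass_id = "BIOMASS") {
  stopifnot(length(strains) >= 1L)
  lapply(strains, validate_model)
  if (is.null(species_id)) {
    species_id <- sub("__.*$", "", strains[[1L]]$id)
  }
  mets <- unique(do.call(rbind, lapply(strains, `[[`, "metabolites")))
  dup <- mets$id[duplicated(mets$id)]
  if (length(dup)) {
    stop("metabolite ids with conflicting compartments across strains: ",
         paste(unique(dup), collapse = ", "))
  }
  # reaction union; widest bounds; conflicting stoichiometry is an error
  rx <- list()
  st <- list()
  bio <- list()
  for (s in strains) {
    sl <- .stoich_list(s)
    for (i in seq_len(nrow(s$reactions))) {
      r <- s$reactions[i, ]
      co <- sort_by_name(sl[[r$id]])
      if (r$id == biomass_id) {
        bio[[length(bio) + 1L]] <- co
        next
      }
      if (is.null(rx[[r$id]])) {
        rx[[r$id]] <- r
        st[[r$id]] <- co
      } else {
        if (!identical(names(st[[r$id]]), names(co)) ||
            !isTRUE(all.equal(unname(st[[r$id]]), unname(co)))) {
          stop("conflicting stoichiometry for reaction '", r$id,
               "' across strains")
        }
        rx[[r$id]]$lb <- min(rx[[r$id]]$lb, r$lb)
        rx[[r$id]]$ub <- max(rx[[r$id]]$ub, r$ub)
        rx[[r$id]]$obj <- max(rx[[r$id]]$obj, r$obj)
      }
    }
  }
  if (!length(bio)) {
    stop("no strain contains a biomass reaction '", biomass_id, "'")
  }
  # pan-biomass: component-wise mean over strains containing the component
  comp <- unique(unlist(lapply(bio, names)))
  pan_bio <- vapply(comp, function(m) {
    vals <- unlist(lapply(bio, function(b) b[[m]]))
    mean(vals)
  }, numeric(1))
  bio_bounds <- do.call(rbind, lapply(strains, function(s) {
    s$reactions[s$reactions$id == biomass_id, c("lb", "ub")]
  }))
  reactions <- do.call(rbind, rx)
  reactions <- rbind(reactions,
                     data.frame(id = biomass_id, lb = min(bio_bounds$lb),
                                ub = max(bio_bounds$ub), obj = 1))
  stoich <- rbind(
    do.call(rbind, lapply(names(st), function(id) {
      data.frame(reaction = id, metabolite = names(st[[id]]),
                 coef = unname(st[[id]]), stringsAsFactors = FALSE)
    })),
    data.frame(reaction = biomass_id, metabolite = names(pan_bio),
               coef = unname(pan_bio), stringsAsFactors = FALSE))
  rownames(reactions) <- rownames(stoich) <- NULL
  out <- metabolic_model(paste0("pan_", species_id), mets, reactions, stoich)
  attr(out, "species_id") <- species_id
  attr(out, "strains") <- vapply(strains, `[[`, character(1), "id")
  out
}

sort_by_name <- function(x) x[order(names(x))]

#' Match taxon labels against model labels
#'
#' Deterministic name matching between taxonomic assignments and
#' pan-species model names: labels are case-folded, spaces and underscores
#' unified, and bracketed qualifiers stripped, then matched exactly.
#' Unmatched taxa are reported and excluded downstream; a taxon matching
#' two different models is an error, never silently resolved.
#'
#' @param taxa character vector of taxon labels (e.g. classifier output).
#' @param models character vector of model species labels.
#' @return list with `matched` (named character vector taxon -> model
#'   label) and `unmatched` (character vector of taxa without a model).
#' @examples
#' match_species_names("Akkermansia_muciniphila", "Akkermansia muciniphila")
#' @export
match_species_names <- function(taxa, models) {
  stopifnot(length(taxa) > 0L, length(models) > 0L)
  norm <- function(x) {
    x <- gsub("\\[[^]]*\\]|\\([^)]*\\)", "", x) # bracketed qualifiers
    x <- tolower(x)
    x <- gsub("[ _]+", "_", trimws(x))
    gsub("^_|_$", "", x)
  }
  nt <- norm(taxa)
  nm <- norm(models)
  hits <- lapply(nt, function(x) which(nm == x))
  multi <- vapply(hits, length, integer(1)) > 1L
  if (any(multi)) {
    stop("ambiguous species match for: ",
         paste(taxa[multi], collapse = ", "))
  }
  idx <- vapply(hits, function(h) if (length(h)) h else NA_integer_,
                integer(1))
  matched <- stats::setNames(models[idx[!is.na(idx)]], taxa[!is.na(idx)])
  list(matched = matched, unmatched = taxa[is.na(idx)])
}
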