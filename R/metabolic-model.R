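#' Construct a genome-scale metabolic model
#'
#' A `metabolic_model` holds metabolites, reactions with stoichiometry and
#' flux bounds, and a linear objective. Stoichiometry follows the usual
#' constraint-based convention: substrates carry negative coefficients,
#' products positive ones, and the stoichiometric matrix S has one row per
#' metabolite and one column per reaction. Exchange reactions are written as
#' `met <-> nothing` with negative flux meaning uptake and positive flux
#' meaning secretion; reversibility is encoded purely through bounds.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id` and `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub` and `obj`
#'   (objective coefficient).
#' @param stoich data.frame with columns `reaction`, `metabolite`, `coef`
#'   (triplet form of S).
#' @return an object of class `metabolic_model`.
#' @examples
#' m <- metabolic_model(
#'   id = "chain",
#'   metabolites = data.frame(id = c("glc_e", "glc_c"),
#'                            compartment = c("e", "c")),
#'   reactions = data.frame(id = c("EX_glc_e", "GLCt", "BIOMASS"),
#'                          lb = c(-10, 0, 0), ub = c(1000, 1000, 1000),
#'                          obj = c(0, 0, 1)),
#'   stoich = data.frame(
#'     reaction   = c("EX_glc_e", "GLCt", "GLCt", "BIOMASS"),
#'     metabolite = c("glc_e", "glc_e", "glc_c", "glc_c"),
#'     coef       = c(-1, -1, 1, -1))
#' )
#' fba(m)$objective
#' @export
metabolic_model <- function(id, metabolites, reactions, stoich) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  stoich <- as.data.frame(stoich)
  if (is.null(reactions$obj)) reactions$obj <- 0
  m <- structure(
    list(id = as.character(id),
         metabolites = metabolites[, c("id", "compartment")],
         reactions = reactions[, c("id", "lb", "ub", "obj")],
         stoich = stoich[, c("reaction", "metabolite", "coef")]),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks identifier uniqueness, that every stoichiometric entry references a
#' declared metabolite and reaction, and that `lb <= ub` for every reaction.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors list all offending entries.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(model$metabolites$id[duplicated(model$metabolites$id)]),
               collapse = ", "))
  }
  if (anyDuplicated(model$reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(model$reactions$id[duplicated(model$reactions$id)]),
               collapse = ", "))
  }
  bad <- setdiff(model$stoich$metabolite, model$metabolites$id)
  if (length(bad)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(model$stoich$reaction, model$reactions$id)
  if (length(bad)) {
    stop("stoichiometry references unknown reactions: ",
         paste(bad, collapse = ", "))
  }
  flip <- model$reactions$lb > model$reactions$ub
  if (any(flip)) {
    stop("lb > ub for reactions: ",
         paste(model$reactions$id[flip], collapse = ", "))
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return sparse `Matrix` S (metabolites x reactions).
#' @export
stoich_matrix <- function(model) {
  Matrix::sparseMatrix(
    i = match(model$stoich$metabolite, model$metabolites$id),
    j = match(model$stoich$reaction, model$reactions$id),
    x = model$stoich$coef,
    dims = c(nrow(model$metabolites), nrow(model$reactions)),
    dimnames = list(model$metabolites$id, model$reactions$id))
}

#' Identify exchange reactions
#'
#' Exchange reactions are recognised structurally: a single-metabolite
#' stoichiometry (boundary reactions of the form `met <-> nothing`).
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  tab <- table(model$stoich$reaction)
  names(tab)[tab == 1L]
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  exchanges: ", length(exchange_reactions(x)), "\n", sep = "")
  invisible(x)
}

# internal: named stoichiometry list (reaction -> named coef vector)
.stoich_list <- function(model) {
  split(stats::setNames(model$stoich$coef, model$stoich$metabolite),
        factor(model$stoich$reaction, levels = model$reactions$id))
}
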