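#' Flux balance analysis
#'
#' Maximises the linear objective `c'v` subject to steady state `S v = 0`
#' and the flux bounds `lb <= v <= ub`. Under the steady-state assumption no
#' metabolite accumulates, so every internal metabolite's net production is
#' zero. The optimal flux vector need not be unique, but the objective value
#' is, and that is what downstream code relies on.
#'
#' @param model a `metabolic_model` with at least one nonzero objective
#'   coefficient.
#' @param maximize maximise (default) or minimise the objective.
#' @return list of class `flux_result` with `objective`, named `fluxes` and
#'   `status` ("optimal", "infeasible", "unbounded"). On non-optimal status
#'   the objective is `NA` (never a silent zero).
#' @export
fba <- function(model, maximize = TRUE) {
  validate_model(model)
  if (all(model$reactions$obj == 0)) {
    stop("model has no objective: set a nonzero objective coefficient")
  }
  S <- as.matrix(stoich_matrix(model))
  r <- lp_solve(model$reactions$obj, S, rep(0, nrow(S)),
                model$reactions$lb, model$reactions$ub, maximize = maximize)
  fluxes <- if (r$status == "optimal") {
    stats::setNames(r$x, model$reactions$id)
  } else NULL
  structure(list(objective = if (r$status == "optimal") r$objective else
                   NA_real_,
                 fluxes = fluxes, status = r$status),
            class = "flux_result")
}

#' Flux variability analysis
#'
#' For each queried reaction, minimises and maximises its flux under the
#' model's steady-state and bound constraints (including any community
#' biomass interval already encoded in the bounds). No objective is fixed at
#' its optimum first: the community growth requirement enters as an interval
#' constraint on the biomass flux, not as an optimised quantity.
#'
#' @param model a `metabolic_model`.
#' @param reactions character vector of reaction ids to scan (default: all
#'   exchange reactions).
#' @return data.frame with columns `reaction`, `min`, `max`, `status`;
#'   attribute `feasible` is `FALSE` when the whole model is infeasible.
#' @export
fva <- function(model, reactions = exchange_reactions(model)) {
  validate_model(model)
  missing <- setdiff(reactions, model$reactions$id)
  if (length(missing)) {
    stop("unknown reactions: ", paste(missing, collapse = ", "))
  }
  S <- as.matrix(stoich_matrix(model))
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  # single feasibility probe before the per-reaction sweeps
  probe <- lp_solve(rep(0, ncol(S)), S, rep(0, nrow(S)), lb, ub)
  if (probe$status != "optimal") {
    out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                      status = "infeasible", stringsAsFactors = FALSE)
    attr(out, "feasible") <- FALSE
    return(out)
  }
  n <- ncol(S)
  res <- lapply(reactions, function(rx) {
    obj <- numeric(n)
    obj[match(rx, model$reactions$id)] <- 1
    lo <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, maximize = FALSE)
    hi <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
    status <- if (lo$status == "optimal" && hi$status == "optimal") {
      "optimal"
    } else if (lo$status == "unbounded" || hi$status == "unbounded") {
      "unbounded"
    } else "infeasible"
    data.frame(reaction = rx,
               min = if (lo$status == "optimal") lo$objective else
                 if (lo$status == "unbounded") -Inf else NA_real_,
               max = if (hi$status == "optimal") hi$objective else
                 if (hi$status == "unbounded") Inf else NA_real_,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "feasible") <- TRUE
  out
}
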