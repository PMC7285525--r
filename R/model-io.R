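#' Read a metabolic model from disk
#'
#' Two encodings are supported. `"json"` is a compact dialect documented
#' under Details; `"sbml"` is SBML Level 3 Version 1 with the Flux Balance
#' Constraints (fbc) package, bounds carried by fbc flux-bound parameters
#' and the objective by an fbc objective list. The format is guessed from
#' the file extension when not given.
#'
#' @details The JSON dialect is an object with fields `id`, `metabolites`
#' (array of `{id, compartment}`), and `reactions` (array of
#' `{id, stoichiometry, lb, ub, obj}` where `stoichiometry` maps metabolite
#' id to coefficient; substrates negative, products positive).
#'
#' @param path file path.
#' @param format "json", "sbml" or NULL (guess from extension).
#' @return a `metabolic_model`.
#' @seealso [write_model()]
#' @export
read_model <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else "json"
  }
  switch(match.arg(format, c("json", "sbml")),
         json = .read_model_json(path),
         sbml = .read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' @param model a `metabolic_model`.
#' @param path destination file.
#' @param format "json" or "sbml" (guessed from extension when NULL).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  validate_model(model)
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else "json"
  }
  switch(match.arg(format, c("json", "sbml")),
         json = .write_model_json(model, path),
         sbml = .write_model_sbml(model, path))
  invisible(path)
}

.read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(m) {
    data.frame(id = m$id, compartment = m$compartment,
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(x$reactions, function(r) {
    data.frame(id = r$id, lb = as.numeric(r$lb), ub = as.numeric(r$ub),
               obj = if (is.null(r$obj)) 0 else as.numeric(r$obj),
               stringsAsFactors = FALSE)
  }))
  st <- do.call(rbind, lapply(x$reactions, function(r) {
    s <- unlist(r$stoichiometry)
    if (is.null(s)) return(NULL)
    data.frame(reaction = r$id, metabolite = names(s),
               coef = as.numeric(s), stringsAsFactors = FALSE)
  }))
  metabolic_model(x$id, mets, rxns, st)
}

.write_model_json <- function(model, path) {
  sl <- .stoich_list(model)
  out <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      list(id = model$metabolites$id[i],
           compartment = model$metabolites$compartment[i])
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id, stoichiometry = as.list(sl[[r$id]]),
           lb = r$lb, ub = r$ub, obj = r$obj)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# SBML identifiers must be SIds; model ids here are already alphanumeric
# with underscores, so a plain prefix suffices.
.sid <- function(x, prefix) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", x))

.write_model_sbml <- function(model, path) {
  sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
  fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml", xmlns = sbml_ns, `xmlns:fbc` = fbc_ns,
    level = "3", version = "1", `fbc:required` = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = .sid(model$id, "M_"),
                             `fbc:strict` = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = .sid(cmp, "C_"),
                        constant = "true")
  }
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    xml2::xml_add_child(
      sp, "species", id = .sid(model$metabolites$id[i], "S_"),
      name = model$metabolites$id[i],
      compartment = .sid(model$metabolites$compartment[i], "C_"),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  # flux bounds as parameters, deduplicated by value
  vals <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)),
                         sprintf("%.17g", vals))
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(vals)) {
    xml2::xml_add_child(pars, "parameter", id = pid[[k]],
                        value = format(vals[k], digits = 17),
                        constant = "true")
  }
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  sl <- .stoich_list(model)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(
      rl, "reaction", id = .sid(r$id, "R_"), name = r$id,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      `fbc:lowerFluxBound` = pid[[sprintf("%.17g", r$lb)]],
      `fbc:upperFluxBound` = pid[[sprintf("%.17g", r$ub)]])
    s <- sl[[r$id]]
    sub <- s[s < 0]
    prod <- s[s > 0]
    if (length(sub)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(sub)) {
        xml2::xml_add_child(lr, "speciesReference", species = .sid(m, "S_"),
                            stoichiometry = format(-sub[[m]], digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(lp, "speciesReference", species = .sid(m, "S_"),
                            stoichiometry = format(prod[[m]], digits = 17),
                            constant = "true")
      }
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              `fbc:activeObjective` = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", `fbc:id` = "obj",
                            `fbc:type` = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  nz <- which(model$reactions$obj != 0)
  for (i in nz) {
    xml2::xml_add_child(
      fl, "fbc:fluxObjective",
      `fbc:reaction` = .sid(model$reactions$id[i], "R_"),
      `fbc:coefficient` = format(model$reactions$obj[i], digits = 17))
  }
  xml2::write_xml(doc, path)
}

.read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  spn <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip(xml2::xml_attr(spn, "id"), "S_"),
    compartment = strip(xml2::xml_attr(spn, "compartment"), "C_"),
    stringsAsFactors = FALSE)
  prn <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(prn, "value")),
                          xml2::xml_attr(prn, "id"))
  rxn <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rid <- strip(xml2::xml_attr(rxn, "id"), "R_")
  reactions <- data.frame(
    id = rid,
    lb = pval[xml2::xml_attr(rxn, "lowerFluxBound")],
    ub = pval[xml2::xml_attr(rxn, "upperFluxBound")],
    obj = 0, stringsAsFactors = FALSE)
  st <- do.call(rbind, lapply(seq_along(rxn), function(i) {
    re <- xml2::xml_find_all(rxn[[i]], ".//s:listOfReactants/s:speciesReference", ns)
    pr <- xml2::xml_find_all(rxn[[i]], ".//s:listOfProducts/s:speciesReference", ns)
    rbind(
      if (length(re)) data.frame(
        reaction = rid[i],
        metabolite = strip(xml2::xml_attr(re, "species"), "S_"),
        coef = -as.numeric(xml2::xml_attr(re, "stoichiometry")),
        stringsAsFactors = FALSE),
      if (length(pr)) data.frame(
        reaction = rid[i],
        metabolite = strip(xml2::xml_attr(pr, "species"), "S_"),
        coef = as.numeric(xml2::xml_attr(pr, "stoichiometry")),
        stringsAsFactors = FALSE))
  }))
  fo <- xml2::xml_find_all(mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (length(fo)) {
    orx <- strip(xml2::xml_attr(fo, "reaction"), "R_")
    reactions$obj[match(orx, reactions$id)] <-
      as.numeric(xml2::xml_attr(fo, "coefficient"))
  }
  id <- strip(xml2::xml_attr(mdl, "id"), "M_")
  rownames(reactions) <- NULL
  metabolic_model(id, mets, reactions, st)
}
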