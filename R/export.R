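# Model serialisation: a round-trippable JSON document and an SBML Level 3
# export with mass-action kinetic laws.

#' Export / import a compiled model
#'
#' JSON export captures the catalog entry, scheme, parameter set, input
#' mechanism and the resolved AND attenuation factor; importing rebuilds
#' the identical network, so export -> import -> export is byte-stable.
#' SBML export writes a Level 3 Version 2 document with one compartment,
#' all species (initial amounts: conserved pools fully inactive, S at its
#' mean) and mass-action kinetic laws including catalytic modifiers.
#'
#' @param crn an `ffl_crn`.
#' @param format `"json"` or `"sbml"`.
#' @param path optional file path; when `NULL` the document is returned as
#'   a character string.
#' @return The document (invisibly when written to `path`).
#' @examples
#' doc <- export_model(build_model(catalog_entry("c1-OR")), "json")
#' crn2 <- import_model(doc)
#' identical(export_model(crn2, "json"), doc)
#' @export
export_model <- function(crn, format = c("json", "sbml"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(crn, "ffl_crn"))
  doc <- if (format == "json") .export_json(crn) else .export_sbml(crn)
  if (is.null(path)) return(doc)
  writeLines(doc, path)
  invisible(doc)
}

.export_json <- function(crn) {
  e <- crn$entry
  obj <- list(
    model_id = crn$model_id,
    scheme = crn$scheme,
    entry = list(
      model_id = e$model_id, family = e$family, nodes = e$nodes,
      edges = lapply(seq_len(nrow(e$edges)), function(i)
        c(e$edges$from[i], e$edges$to[i], sign_chr(e$edges$sign[i]))),
      gates = as.list(e$gates),
      gate_free = as.list(e$gate_free),
      branch_types = e$branch_types,
      coherence_class = e$coherence_class),
    params = unclass(crn$params)[c("k1", "k2", "k3", "kp", "kpp", "ka",
                                   "total", "s_ref", "p_ref")],
    and_factor = if (is.na(crn$and_factor)) NULL else crn$and_factor,
    input = list(fano = crn$input$fano, mean = crn$input$mean),
    species = crn$species,
    reactions = data.frame(
      name = vapply(crn$reactions, `[[`, character(1), "name"),
      rate_constant = crn$rates,
      stringsAsFactors = FALSE))
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

#' @rdname export_model
#' @param doc a JSON document produced by `export_model()` (string or file
#'   path).
#' @export
import_model <- function(doc) {
  if (length(doc) == 1L && file.exists(doc)) doc <- paste(readLines(doc), collapse = "\n")
  obj <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  e <- obj$entry
  edges <- do.call(rbind, lapply(e$edges, function(tr)
    .edge_df(tr[[1]], tr[[2]], tr[[3]])))
  entry <- .entry(e$model_id, e$family, unlist(e$nodes), edges,
                  unlist(e$gates), unlist(e$gate_free),
                  unlist(e$branch_types), e$coherence_class)
  p <- obj$params
  params <- ffl_params(k1 = p$k1, k2 = p$k2, k3 = p$k3, kp = p$kp,
                       kpp = p$kpp, ka = p$ka, total = p$total,
                       s_ref = p$s_ref, p_ref = p$p_ref,
                       and_factor = obj$and_factor)
  .assemble_crn(entry, obj$scheme, params,
                calibrate_input(obj$input$fano, obj$input$mean),
                and_factor = if (is.null(obj$and_factor)) NA_real_
                             else obj$and_factor)
}

.export_sbml <- function(crn) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model",
                               id = gsub("[^A-Za-z0-9_]", "_", crn$model_id))
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", size = "1",
                      constant = "true")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  init <- .ssa_init_state(crn, crn$input$mean)
  for (i in seq_len(nrow(crn$species)))
    xml2::xml_add_child(ls, "species",
      id = crn$species$name[i], compartment = "cell",
      initialAmount = as.character(init[crn$species$name[i]]),
      hasOnlySubstanceUnits = "true",
      boundaryCondition = "false", constant = "false")
  lp <- xml2::xml_add_child(model, "listOfParameters")
  for (j in seq_along(crn$rates))
    xml2::xml_add_child(lp, "parameter", id = paste0("k_r", j),
                        value = as.character(crn$rates[j]),
                        constant = "true")
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_along(crn$reactions)) {
    rx <- crn$reactions[[j]]
    nd <- xml2::xml_add_child(lr, "reaction",
      id = paste0("r", j), name = rx$name, reversible = "false")
    reac <- which(crn$N[, j] < 0); prod <- which(crn$N[, j] > 0)
    modf <- setdiff(which(crn$E[, j] > 0), reac)
    if (length(reac)) {
      lrc <- xml2::xml_add_child(nd, "listOfReactants")
      for (i in reac)
        xml2::xml_add_child(lrc, "speciesReference",
          species = crn$species$name[i],
          stoichiometry = as.character(-crn$N[i, j]), constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(nd, "listOfProducts")
      for (i in prod)
        xml2::xml_add_child(lpr, "speciesReference",
          species = crn$species$name[i],
          stoichiometry = as.character(crn$N[i, j]), constant = "true")
    }
    if (length(modf)) {
      lmd <- xml2::xml_add_child(nd, "listOfModifiers")
      for (i in modf)
        xml2::xml_add_child(lmd, "modifierSpeciesReference",
                            species = crn$species$name[i])
    }
    kl <- xml2::xml_add_child(nd, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
      xmlns = "http://www.w3.org/1998/Math/MathML")
    factors <- c(paste0("k_r", j),
                 rep(crn$species$name[crn$E[, j] > 0], crn$E[crn$E[, j] > 0, j]))
    if (length(factors) == 1L) {
      xml2::xml_add_child(math, "ci", factors)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (f in factors) xml2::xml_add_child(ap, "ci", f)
    }
  }
  as.character(doc)
}
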