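#' @title SBML import/export of metabolic networks
#' @name sbml
#' @description
#' Minimal SBML Level 3 (with the fbc flux-bounds package) writer and reader
#' for `metabolic_network` objects, built on xml2. Elemental composition is
#' carried in `fbc:chemicalFormula`, flux bounds in per-reaction parameters,
#' and the exchange/measured flags and subsystem in reaction notes, so that a
#' write-read round trip reproduces the stoichiometric matrix bit-identically.
NULL

sbml_ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

num17 <- function(x) sprintf("%.17g", x)

compartment_code <- c(cytosol = "c", mitochondrion = "m", extracellular = "e")

#' Write a network as SBML Level 3 with fbc bounds
#'
#' @param network a `metabolic_network`.
#' @param path output file.
#' @return the network, invisibly.
#' @export
write_network_sbml <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = sbml_ns[["s"]], "xmlns:fbc" = sbml_ns[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = "network",
                               "fbc:strict" = "true")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in unique(network$metabolites$compartment)) {
    code <- compartment_code[[cp]]
    xml2::xml_add_child(lc, "compartment", id = code, name = cp,
                        constant = "true")
  }
  ls_ <- xml2::xml_add_child(model, "listOfSpecies")
  for (k in seq_len(nrow(network$metabolites))) {
    m <- network$metabolites[k, ]
    formula <- paste0(if (m$carbon > 0) paste0("C", m$carbon) else "",
                      if (m$nitrogen > 0) paste0("N", m$nitrogen) else "")
    if (formula == "") formula <- "X"
    xml2::xml_add_child(ls_, "species", id = m$id, name = m$name,
                        compartment = compartment_code[[m$compartment]],
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false",
                        "fbc:chemicalFormula" = formula)
  }
  lp <- xml2::xml_add_child(model, "listOfParameters")
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (k in seq_len(nrow(network$reactions))) {
    r <- network$reactions[k, ]
    lb_id <- paste0(r$id, "_lb"); ub_id <- paste0(r$id, "_ub")
    xml2::xml_add_child(lp, "parameter", id = lb_id,
                        value = num17(r$lower_bound), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = ub_id,
                        value = num17(r$upper_bound), constant = "true")
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false",
                              "fbc:lowerFluxBound" = lb_id,
                              "fbc:upperFluxBound" = ub_id)
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("subsystem: ", r$subsystem))
    xml2::xml_add_child(body, "p", paste0("is_exchange: ", r$is_exchange))
    xml2::xml_add_child(body, "p", paste0("is_measured: ", r$is_measured))
    st <- network$stoichiometry[[r$id]]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lrx <- xml2::xml_add_child(rn, "listOfReactants")
      for (sp in names(reac))
        xml2::xml_add_child(lrx, "speciesReference", species = sp,
                            stoichiometry = num17(-reac[[sp]]),
                            constant = "true")
    }
    if (length(prod)) {
      lpx <- xml2::xml_add_child(rn, "listOfProducts")
      for (sp in names(prod))
        xml2::xml_add_child(lpx, "speciesReference", species = sp,
                            stoichiometry = num17(prod[[sp]]),
                            constant = "true")
    }
  }
  lo <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = network$objective_id,
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(network)
}

#' Read a network from SBML Level 3 with fbc bounds
#'
#' @param path SBML file written by [write_network_sbml()] (or compatible).
#' @return a `metabolic_network`.
#' @export
read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- sbml_ns
  comp_nodes <- xml2::xml_find_all(doc, ".//s:compartment", ns)
  comp_map <- stats::setNames(xml2::xml_attr(comp_nodes, "name"),
                              xml2::xml_attr(comp_nodes, "id"))
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  parse_formula <- function(f) {
    cnt <- function(el) {
      m <- regmatches(f, regexec(paste0(el, "([0-9]+)"), f))[[1]]
      if (length(m) == 2L) as.integer(m[2]) else 0L
    }
    c(carbon = cnt("C"), nitrogen = cnt("N"))
  }
  formulas <- t(vapply(xml2::xml_attr(sp, "chemicalFormula"), parse_formula,
                       integer(2)))
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     name = xml2::xml_attr(sp, "name"),
                     compartment = unname(comp_map[xml2::xml_attr(sp, "compartment")]),
                     carbon = formulas[, "carbon"],
                     nitrogen = formulas[, "nitrogen"],
                     stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rnodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  note_field <- function(rn, key) {
    ps <- xml2::xml_text(xml2::xml_find_all(
      rn, ".//xhtml:p", c(xhtml = "http://www.w3.org/1999/xhtml")))
    hit <- grep(paste0("^", key, ": "), ps, value = TRUE)
    if (length(hit)) sub(paste0("^", key, ": "), "", hit[1]) else NA_character_
  }
  rows <- list(); stoich <- list()
  for (rn in rnodes) {
    id <- xml2::xml_attr(rn, "id")
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(rn, paste0("./s:", tag, "/s:speciesReference"),
                                 ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", 1))
    stoich[[id]] <- st
    rows[[length(rows) + 1L]] <- data.frame(
      id = id,
      equation = format_equation(st),
      reversible = xml2::xml_attr(rn, "reversible") == "true",
      lower_bound = pval[[xml2::xml_attr(rn, "lowerFluxBound")]],
      upper_bound = pval[[xml2::xml_attr(rn, "upperFluxBound")]],
      is_exchange = identical(note_field(rn, "is_exchange"), "TRUE"),
      is_measured = identical(note_field(rn, "is_measured"), "TRUE"),
      subsystem = note_field(rn, "subsystem"),
      stringsAsFactors = FALSE)
  }
  rx <- do.call(rbind, rows)
  obj <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns), "reaction")
  if (is.na(obj)) obj <- rx$id[1]
  build_network(rx, mets, objective = obj)
}
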