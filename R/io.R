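#' Load a metabolic model from file
#'
#' Two dialects are supported: the package's canonical JSON dialect
#' (objects `metabolites[]`, `reactions[]`, `objective{}`) and SBML Level 3
#' with FBC-style flux bounds. Bounds absent from the file default to
#' +/-1000 mmol/gCDW/h; reversibility is encoded purely by bounds.
#'
#' @param path File path.
#' @param format `"json"` or `"sbml"`; guessed from the extension when
#'   missing.
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Save a metabolic model to file
#'
#' The emitted file reloads to a structurally equal model (round trip).
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @param format `"json"` or `"sbml"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

## ---- JSON dialect ---------------------------------------------------------

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- lapply(doc$metabolites, function(m)
    metabolite(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               formula = m$formula, charge = m$charge))
  rxns <- lapply(doc$reactions, function(r) {
    lb <- r$lower_bound %||% -DEFAULT_BOUND
    ub <- r$upper_bound %||% DEFAULT_BOUND
    if (!is.numeric(lb) || !is.numeric(ub))
      stop("reaction ", r$id, ": malformed numeric bound")
    reaction(id = r$id, name = r$name %||% r$id,
             stoichiometry = unlist(r$stoichiometry),
             lower_bound = lb, upper_bound = ub,
             gene_rule = r$gene_rule, subsystem = r$subsystem,
             role = r$role)
  })
  metabolic_model(id = doc$id %||% tools::file_path_sans_ext(basename(path)),
                  metabolites = mets, reactions = rxns,
                  objective = unlist(doc$objective) %||% numeric(0))
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(unname(model$metabolites), function(m)
      drop_null(list(id = m$id, name = m$name, compartment = m$compartment,
                     formula = m$formula, charge = m$charge))),
    reactions = lapply(unname(model$reactions), function(r)
      drop_null(list(id = r$id, name = r$name,
                     stoichiometry = as.list(r$stoichiometry),
                     lower_bound = r$lower_bound,
                     upper_bound = r$upper_bound,
                     gene_rule = r$gene_rule, subsystem = r$subsystem,
                     role = r$role))),
    objective = as.list(model$objective))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

## ---- SBML (Level 3 core + FBC-style bounds) -------------------------------
##
## A deliberately small writer/reader pair: species with chemical formulas,
## reactions with speciesReferences and per-reaction bound parameters in the
## FBC attribute style, one maximize objective. Role/subsystem/gene_rule
## survive the round trip in a package annotation namespace.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
GFX_NS <- "https://gabaflux.example.org/sbml-annotations"

## SBML ids must match SId; our ids (alnum + _) already do
write_model_sbml <- function(model, path) {
  bound_par <- function(i, which) sprintf("%s_%s", which, i)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" xmlns:gfx="%s" ',
                   'level="3" version="1" fbc:required="false">'),
            SBML_NS, FBC_NS, GFX_NS),
    sprintf('  <model id="%s" fbc:strict="true">', xml_escape(model$id)),
    '    <listOfCompartments>')
  comps <- unique(vapply(model$metabolites, `[[`, "", "compartment"))
  lines <- c(lines, sprintf(
    '      <compartment id="%s" constant="true"/>', comps),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (m in model$metabolites) {
    attrs <- sprintf(
      'id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
      m$id, xml_escape(m$name), m$compartment)
    if (!is.null(m$formula))
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    if (!is.null(m$charge))
      attrs <- paste0(attrs, sprintf(' fbc:charge="%d"', as.integer(m$charge)))
    lines <- c(lines, sprintf('      <species %s/>', attrs))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (r in model$reactions)
    lines <- c(lines,
      sprintf('      <parameter id="%s" value="%.17g" constant="true"/>',
              bound_par(r$id, "lb"), r$lower_bound),
      sprintf('      <parameter id="%s" value="%.17g" constant="true"/>',
              bound_par(r$id, "ub"), r$upper_bound))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    rev <- if (r$lower_bound < 0) "true" else "false"
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      r$id, xml_escape(r$name), rev, bound_par(r$id, "lb"),
      bound_par(r$id, "ub")))
    anno <- character(0)
    if (!is.null(r$role)) anno <- c(anno, sprintf('role="%s"', r$role))
    if (!is.null(r$subsystem))
      anno <- c(anno, sprintf('subsystem="%s"', xml_escape(r$subsystem)))
    if (!is.null(r$gene_rule))
      anno <- c(anno, sprintf('geneRule="%s"', xml_escape(r$gene_rule)))
    if (length(anno))
      lines <- c(lines,
                 '        <annotation>',
                 sprintf('          <gfx:meta %s/>', paste(anno, collapse = " ")),
                 '        </annotation>')
    st <- r$stoichiometry
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                names(subs), -unname(subs)),
        '        </listOfReactants>')
    }
    if (length(prods)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                names(prods), unname(prods)),
        '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (length(model$objective)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%.17g"/>',
              names(model$objective), unname(model$objective)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS, gfx = GFX_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("not an SBML level-3 document: ", path)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))
  ## namespaced attribute lookup (fbc:chemicalFormula etc.): try the
  ## prefixed name first, then the bare local name
  nsattr <- function(node, nm, prefix = "fbc") {
    v <- xml2::xml_attr(node, paste0(prefix, ":", nm), ns = ns)
    if (is.na(v)) v <- xml2::xml_attr(node, nm)
    v
  }
  mets <- lapply(xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns),
    function(sp) {
      ch <- nsattr(sp, "charge")
      chf <- nsattr(sp, "chemicalFormula")
      metabolite(id = xml2::xml_attr(sp, "id"),
                 name = xml2::xml_attr(sp, "name",
                                       default = xml2::xml_attr(sp, "id")),
                 compartment = xml2::xml_attr(sp, "compartment", default = "c"),
                 formula = if (is.na(chf)) NULL else chf,
                 charge = if (is.na(ch)) NULL else as.integer(ch))
    })
  rxns <- lapply(
    xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns),
    function(rx) {
      id <- xml2::xml_attr(rx, "id")
      get_side <- function(xpath, sign) {
        refs <- xml2::xml_find_all(rx, xpath, ns)
        stats::setNames(
          sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
          xml2::xml_attr(refs, "species"))
      }
      st <- c(get_side("./s:listOfReactants/s:speciesReference", -1),
              get_side("./s:listOfProducts/s:speciesReference", +1))
      if (anyDuplicated(names(st)))  # same species on both sides
        st <- tapply(st, names(st), sum)
      lbp <- nsattr(rx, "lowerFluxBound")
      ubp <- nsattr(rx, "upperFluxBound")
      lb <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else
        if (identical(xml2::xml_attr(rx, "reversible"), "false")) 0 else
          -DEFAULT_BOUND
      ub <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else
        DEFAULT_BOUND
      meta <- xml2::xml_find_first(rx, "./s:annotation/gfx:meta", ns)
      role <- subsystem <- gene_rule <- NULL
      if (!inherits(meta, "xml_missing")) {
        a <- function(nm) {
          v <- xml2::xml_attr(meta, nm)
          if (is.na(v)) NULL else v
        }
        role <- a("role"); subsystem <- a("subsystem")
        gene_rule <- a("geneRule")
      }
      reaction(id = id,
               name = xml2::xml_attr(rx, "name", default = id),
               stoichiometry = st, lower_bound = lb, upper_bound = ub,
               gene_rule = gene_rule, subsystem = subsystem, role = role)
    })
  fobj <- xml2::xml_find_all(doc, ".//fbc:fluxObjective", ns)
  objective <- stats::setNames(
    as.numeric(xml2::xml_attr(fobj, "coefficient")),
    xml2::xml_attr(fobj, "reaction"))
  metabolic_model(id = xml2::xml_attr(mdl, "id"),
                  metabolites = mets, reactions = rxns,
                  objective = objective)
}
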