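## In-silico strain series: labeled edit scripts emulating the engineered
## GABA (GABA-1..6) and butyrolactam (BLM-1..3) strain lineages.

#' Define one in-silico strain
#'
#' @param label Unique strain label (e.g. `"GABA-4"`).
#' @param edits Ordered list of [model_edit()]s applied to a fresh copy of
#'   the base model.
#' @param product_rxn Product objective for the producer evaluation;
#'   `NULL` uses the `GABA_EXPORT` role.
#' @param pathway Optional pathway installed before the edits:
#'   `"butyrolactam"` applies [add_butyrolactam_pathway()].
#' @return A `strain_spec` object.
#' @export
strain_spec <- function(label, edits = list(), product_rxn = NULL,
                        pathway = NULL) {
  if (!is.null(pathway)) pathway <- match.arg(pathway, "butyrolactam")
  structure(list(label = label, edits = edits, product_rxn = product_rxn,
                 pathway = pathway),
            class = "strain_spec")
}

#' Evaluate a strain series
#'
#' For each strain the edits are applied to a fresh copy of the base
#' model, the maximal growth is computed, and the producer optimization
#' ([production_fba()]) is run at the given biomass fraction. Per-strain
#' failures are recorded in the `status` column; the series continues.
#'
#' @param base_model Base producer model (GAD pathway installed).
#' @param series List of [strain_spec()]s with unique labels.
#' @param constraint A [production_constraint()]; its `product_rxn` is the
#'   default product, overridden per strain by `strain_spec$product_rxn`.
#' @param backend LP backend.
#' @return Data frame: `label`, `growth_max`, `product_flux`, `status`.
#' @export
strain_series <- function(base_model, series,
                          constraint = production_constraint(
                            reaction_by_role(base_model, "GABA_EXPORT")),
                          backend = "simplex") {
  labels <- vapply(series, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("strain labels must be unique")
  out <- data.frame(label = labels,
                    growth_max = rep(NA_real_, length(labels)),
                    product_flux = rep(NA_real_, length(labels)),
                    status = rep("ok", length(labels)),
                    stringsAsFactors = FALSE)
  biomass <- reaction_by_role(base_model, "BIOMASS")
  for (i in seq_along(series)) {
    sp <- series[[i]]
    res <- tryCatch({
      m <- base_model
      if (identical(sp$pathway, "butyrolactam"))
        m <- add_butyrolactam_pathway(m)
      m <- apply_edits(m, sp$edits)
      g <- fba(m, biomass, backend = backend)
      growth <- if (g$status == "optimal") g$objective_value else NA_real_
      product <- sp$product_rxn %||% constraint$product_rxn
      pf <- if (!is.na(growth) && growth > REPORT_TOL) {
        pc <- production_constraint(product, constraint$biomass_fraction)
        st <- production_fba(m, pc, backend = backend)
        if (st$status == "optimal") st$objective_value else NA_real_
      } else if (!is.na(growth)) 0 else NA_real_
      list(growth = growth, product = pf, status = g$status)
    }, error = function(e) list(growth = NA_real_, product = NA_real_,
                                status = conditionMessage(e)))
    out$growth_max[i] <- res$growth
    out$product_flux[i] <- res$product
    out$status[i] <- res$status
  }
  out
}

#' Load a declarative strain-series file
#'
#' Strain-series files are JSON: a `series` array of
#' `{label, product, pathway, edits[]}` objects. Edit entries:
#' \describe{
#'   \item{knockout}{`{"type": "knockout", "rxn": id-or-role}` -> bounds
#'     fixed to (0, 0), reaction retained.}
#'   \item{fix_flux_multiple}{`{"type": "fix_flux_multiple", "rxn":
#'     id-or-role, "factor": k}` -> equality bounds at k-fold the
#'     reference flux (overexpression semantics: the scan's equality
#'     encoding at a multiple of the wild-type canonical flux).}
#'   \item{set_bounds}{`{"type": "set_bounds", "rxn": id-or-role, "lb":,
#'     "ub":}`.}
#' }
#' Role tags are resolved against `model`; reference fluxes against
#' `reference_state` (the wild-type pFBA solution).
#'
#' @param path JSON file; defaults to the packaged GABA-1..6 / BLM-1..3
#'   series.
#' @param model Model used to resolve role tags.
#' @param reference_state Wild-type `flux_state` for
#'   `fix_flux_multiple` references.
#' @return List of [strain_spec()]s.
#' @export
load_strain_series <- function(path = NULL, model, reference_state) {
  path <- path %||% system.file("extdata", "strains_gaba_blm.json",
                                package = "gabaflux", mustWork = TRUE)
  doc <- jsonlite::read_json(path)
  resolve_rxn <- function(x) {
    if (x %in% ROLE_TAGS) reaction_by_role(model, x)
    else if (x %in% reaction_ids(model)) x
    else stop("cannot resolve reaction or role '", x, "'")
  }
  lapply(doc$series, function(s) {
    edits <- lapply(s$edits, function(e) {
      switch(e$type,
        knockout = model_edit("delete_reaction", rxn = resolve_rxn(e$rxn),
                              label = e$label %||%
                                paste0("knockout ", e$rxn)),
        fix_flux_multiple = {
          id <- resolve_rxn(e$rxn)
          ref <- reference_state$fluxes[[id]]
          model_edit("set_bounds", rxn = id, lb = e$factor * ref,
                     ub = e$factor * ref,
                     label = e$label %||%
                       sprintf("%s flux fixed at %gx reference", e$rxn,
                               e$factor))
        },
        set_bounds = model_edit("set_bounds", rxn = resolve_rxn(e$rxn),
                                lb = e$lb, ub = e$ub,
                                label = e$label %||%
                                  paste0("set_bounds ", e$rxn)),
        stop("unknown edit type: ", e$type))
    })
    strain_spec(label = s$label, edits = edits,
                product_rxn = s$product, pathway = s$pathway)
  })
}
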