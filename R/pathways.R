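#' Default species id map for pathway additions
#'
#' Maps the chemical species the heterologous pathways touch to metabolite
#' ids of the host model. The defaults match the packaged core model's JSON
#' dialect (`_c`/`_e` compartment suffixes); supply a modified map when
#' editing a foreign model (e.g. a genome-scale reconstruction with its own
#' id scheme).
#'
#' @param ... Overrides, e.g. `glu = "glu__L_c"`.
#' @return Named list of metabolite ids.
#' @export
species_id_map <- function(...) {
  map <- list(glu = "glu_c", co2 = "co2_c", gaba = "gaba_c",
              gaba_ext = "gaba_e", accoa = "accoa_c", coa = "coa_c",
              ac = "ac_c", ac_ext = "ac_e", btl = "btl_c", btl_ext = "btl_e")
  utils::modifyList(map, list(...))
}

#' Add the heterologous GAD route for GABA synthesis
#'
#' Installs the one-reaction decarboxylation of glutamate to GABA
#' (glutamate -> GABA + CO2, reversible), a cytosol-to-extracellular GABA
#' transport, and a secretion-only GABA exchange. The GAD reaction gains
#' role `GAD` and the exchange gains role `GABA_EXPORT`; no other reaction
#' is touched.
#'
#' @param model Host `metabolic_model`; must contain cytosolic glutamate
#'   and CO2 under the ids in `id_map`.
#' @param id_map A [species_id_map()].
#' @return The extended model.
#' @export
add_gaba_pathway <- function(model, id_map = species_id_map()) {
  for (sp in c("glu", "co2"))
    if (!id_map[[sp]] %in% metabolite_ids(model))
      stop("cannot resolve species '", sp, "' (id ", id_map[[sp]],
           ") in model ", model$id)
  if (!is.null(reaction_by_role(model, "GAD", required = FALSE)))
    stop("model already has a reaction with role GAD")
  gaba <- id_map$gaba; gabae <- id_map$gaba_ext
  if (!gaba %in% metabolite_ids(model))
    model$metabolites[[gaba]] <-
      metabolite(gaba, "4-aminobutyrate", "c", formula = "C4NO2")
  if (!gabae %in% metabolite_ids(model))
    model$metabolites[[gabae]] <-
      metabolite(gabae, "4-aminobutyrate (extracellular)", "e",
                 formula = "C4NO2")
  add <- list(
    reaction("GAD", stats::setNames(c(-1, 1, 1),
                                    c(id_map$glu, gaba, id_map$co2)),
             lower_bound = -DEFAULT_BOUND, upper_bound = DEFAULT_BOUND,
             name = "glutamate decarboxylase", role = "GAD",
             subsystem = "GABA synthesis"),
    reaction("GABAt", stats::setNames(c(-1, 1), c(gaba, gabae)),
             lower_bound = 0, upper_bound = DEFAULT_BOUND,
             name = "GABA efflux", subsystem = "transport"),
    reaction("EX_gaba", stats::setNames(-1, gabae),
             lower_bound = 0, upper_bound = DEFAULT_BOUND,
             name = "GABA exchange", role = "GABA_EXPORT",
             subsystem = "exchange"))
  for (r in add) {
    if (r$id %in% reaction_ids(model))
      stop("reaction id already present: ", r$id)
    model$reactions[[r$id]] <- r
  }
  validate_model(model)
  model
}

#' Add the acetyl-CoA-dependent butyrolactam branch
#'
#' Installs a lumped CoA-transferase reaction
#' `GABA + acetyl-CoA -> butyrolactam + acetate + CoA` (role `ACT`): the
#' CoA transfer and the subsequent spontaneous cyclization of the GABA-CoA
#' intermediate are lumped into one step because the intermediate is
#' transient. The CoA moiety is conserved (acetyl-CoA in, free CoA out).
#' Transport and exchange reactions for butyrolactam, and for acetate when
#' absent, are added alongside.
#'
#' @param model Host `metabolic_model`; must contain GABA and acetyl-CoA.
#' @param id_map A [species_id_map()].
#' @return The extended model.
#' @export
add_butyrolactam_pathway <- function(model, id_map = species_id_map()) {
  for (sp in c("gaba", "accoa", "coa"))
    if (!id_map[[sp]] %in% metabolite_ids(model))
      stop("cannot resolve species '", sp, "' (id ", id_map[[sp]],
           ") in model ", model$id)
  if (!is.null(reaction_by_role(model, "ACT", required = FALSE)))
    stop("model already has a reaction with role ACT")
  ensure_met <- function(id, name, comp, formula) {
    if (!id %in% metabolite_ids(model))
      model$metabolites[[id]] <<- metabolite(id, name, comp, formula)
  }
  ensure_met(id_map$btl, "butyrolactam", "c", "C4NO")
  ensure_met(id_map$btl_ext, "butyrolactam (extracellular)", "e", "C4NO")
  ensure_met(id_map$ac, "acetate", "c", "C2O2")
  ensure_met(id_map$ac_ext, "acetate (extracellular)", "e", "C2O2")
  add <- list(
    reaction("ACT",
             stats::setNames(c(-1, -1, 1, 1, 1),
                             c(id_map$gaba, id_map$accoa, id_map$btl,
                               id_map$ac, id_map$coa)),
             lower_bound = 0, upper_bound = DEFAULT_BOUND,
             name = "beta-alanine CoA transferase (lumped cyclization)",
             role = "ACT", subsystem = "butyrolactam synthesis"),
    reaction("BTLt", stats::setNames(c(-1, 1), c(id_map$btl, id_map$btl_ext)),
             lower_bound = 0, upper_bound = DEFAULT_BOUND,
             name = "butyrolactam efflux", subsystem = "transport"),
    reaction("EX_btl", stats::setNames(-1, id_map$btl_ext),
             lower_bound = 0, upper_bound = DEFAULT_BOUND,
             name = "butyrolactam exchange", subsystem = "exchange"))
  if (!"EX_ac" %in% reaction_ids(model)) {
    add <- c(add, list(
      reaction("ACt", stats::setNames(c(-1, 1), c(id_map$ac, id_map$ac_ext)),
               lower_bound = 0, upper_bound = DEFAULT_BOUND,
               name = "acetate efflux", subsystem = "transport"),
      reaction("EX_ac", stats::setNames(-1, id_map$ac_ext),
               lower_bound = 0, upper_bound = DEFAULT_BOUND,
               name = "acetate exchange", subsystem = "exchange")))
  }
  for (r in add) {
    if (r$id %in% reaction_ids(model))
      stop("reaction id already present: ", r$id)
    model$reactions[[r$id]] <- r
  }
  validate_model(model)
  model
}
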