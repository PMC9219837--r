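#' Describe a single model edit
#'
#' Edits are applied in order by [apply_edits()]. Supported kinds:
#' \describe{
#'   \item{add_reaction}{`payload = list(reaction = <reaction>)`}
#'   \item{delete_reaction}{`payload = list(rxn = id)`; implemented as
#'     fixing bounds to (0, 0) so the reaction universe stays constant
#'     across strains (delta maps and reports keep one row set).}
#'   \item{set_bounds}{`payload = list(rxn = id, lb =, ub =)` (either bound
#'     may be omitted).}
#'   \item{scale_bounds}{`payload = list(rxn = id, factor =)`; multiplies
#'     both finite bounds.}
#'   \item{set_objective}{`payload = list(objective = id or weight map)`}
#' }
#'
#' @param kind Edit kind (see above).
#' @param ... Payload fields.
#' @param label Free-text label used in error messages and reports,
#'   e.g. `"ΔsucCD"`.
#' @return A `model_edit` object.
#' @export
model_edit <- function(kind = c("add_reaction", "delete_reaction",
                                "set_bounds", "scale_bounds",
                                "set_objective"),
                       ..., label = NULL) {
  kind <- match.arg(kind)
  payload <- list(...)
  required <- switch(kind,
    add_reaction = "reaction", delete_reaction = "rxn",
    set_bounds = "rxn", scale_bounds = c("rxn", "factor"),
    set_objective = "objective")
  missing <- setdiff(required, names(payload))
  if (length(missing))
    stop("edit kind ", kind, " requires payload field(s): ",
         paste(missing, collapse = ", "))
  if (kind == "add_reaction" && !inherits(payload$reaction, "reaction"))
    stop("add_reaction payload must be a reaction object")
  structure(list(kind = kind, payload = payload,
                 label = label %||% kind),
            class = "model_edit")
}

#' Apply an ordered list of edits to a model
#'
#' The input model is never modified; a new model is returned. Deletions
#' retain the reaction with (0, 0) bounds.
#'
#' @param model A `metabolic_model`.
#' @param edits List of [model_edit()] objects (a single edit is accepted).
#' @return The edited model, validated.
#' @export
apply_edits <- function(model, edits) {
  if (inherits(edits, "model_edit")) edits <- list(edits)
  for (e in edits) {
    if (!inherits(e, "model_edit")) stop("not a model_edit object")
    model <- tryCatch(apply_one_edit(model, e), error = function(err)
      stop("edit '", e$label, "': ", conditionMessage(err), call. = FALSE))
  }
  validate_model(model)
  model
}

apply_one_edit <- function(model, e) {
  p <- e$payload
  need_rxn <- function() {
    if (!p$rxn %in% reaction_ids(model))
      stop("unknown reaction ", p$rxn)
    p$rxn
  }
  switch(e$kind,
    add_reaction = {
      r <- p$reaction
      if (r$id %in% reaction_ids(model))
        stop("reaction id already present: ", r$id)
      model$reactions[[r$id]] <- r
      model
    },
    delete_reaction = set_bounds(model, need_rxn(), lb = 0, ub = 0),
    set_bounds = set_bounds(model, need_rxn(), lb = p$lb, ub = p$ub),
    scale_bounds = {
      id <- need_rxn()
      r <- model$reactions[[id]]
      set_bounds(model, id,
                 lb = if (is.finite(r$lower_bound))
                   r$lower_bound * p$factor else r$lower_bound,
                 ub = if (is.finite(r$upper_bound))
                   r$upper_bound * p$factor else r$upper_bound)
    },
    set_objective = set_objective(model, p$objective))
}

#' Medium / constraint configuration
#'
#' Uptake rates are stored positive and applied as negative exchange flux
#' (the standard constraint-based sign convention: negative exchange flux
#' is uptake).
#'
#' @param fixed_uptakes Named numeric vector, exchange reaction id ->
#'   uptake rate (mmol/gCDW/h, >= 0); applied as equality bounds
#'   (-rate, -rate).
#' @param free_exchanges Character vector of exchange ids opened to
#'   (-1000, 1000).
#' @param keep Character vector of exchange ids whose bounds are left
#'   untouched (secretion-only product exchanges, typically).
#' @return A `medium_spec` object.
#' @export
medium_spec <- function(fixed_uptakes = numeric(0),
                        free_exchanges = character(0),
                        keep = character(0)) {
  fixed_uptakes <- unlist(fixed_uptakes) %||% numeric(0)
  if (length(fixed_uptakes) && any(fixed_uptakes < 0))
    stop("uptake rates must be >= 0 (stored positive)")
  structure(list(fixed_uptakes = fixed_uptakes,
                 free_exchanges = free_exchanges, keep = keep),
            class = "medium_spec")
}

#' Apply a medium specification to a model
#'
#' Fixed uptakes become equality bounds (-rate, -rate); free exchanges are
#' opened to (-1000, 1000); every other exchange is closed to uptake
#' (lower bound 0) unless listed in `keep`.
#'
#' @param model A `metabolic_model`.
#' @param medium A [medium_spec()].
#' @return The constrained model (input untouched).
#' @export
set_medium <- function(model, medium) {
  stopifnot(inherits(medium, "medium_spec"))
  ex <- exchange_ids(model)
  referenced <- c(names(medium$fixed_uptakes), medium$free_exchanges,
                  medium$keep)
  unknown <- setdiff(referenced, ex)
  if (length(unknown))
    stop("unknown exchange id(s): ", paste(unknown, collapse = ", "))
  for (id in ex) {
    if (id %in% names(medium$fixed_uptakes)) {
      rate <- medium$fixed_uptakes[[id]]
      model <- set_bounds(model, id, lb = -rate, ub = -rate)
    } else if (id %in% medium$free_exchanges) {
      model <- set_bounds(model, id, lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND)
    } else if (!id %in% medium$keep) {
      r <- model$reactions[[id]]
      model <- set_bounds(model, id, lb = 0, ub = max(r$upper_bound, 0))
    }
  }
  model
}
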