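#' @keywords internal
"_PACKAGE"

## Canonical role tags recognized on reactions. At most one reaction per
## model may carry each tag; they let analyses address "the" biomass,
## aconitase, AKGDH, ... reaction without hard-coding ids.
ROLE_TAGS <- c("BIOMASS", "GLC_UPTAKE", "ACN", "AKGDH", "SUCOAS", "GAD",
               "GABA_EXPORT", "GABA_UPTAKE", "GABA_SHUNT_T", "GABA_SHUNT_D",
               "ACEA", "ACEB", "ACT")

DEFAULT_BOUND <- 1000

#' Create a metabolite
#'
#' @param id Short unique token, conventionally suffixed `_c` (cytosol) or
#'   `_e` (extracellular) in the JSON dialect.
#' @param name Free-text name.
#' @param compartment Compartment token; `"c"` (default) or `"e"`.
#' @param formula Optional elemental composition string, e.g. `"C5NO4"`.
#'   Hydrogen is conventionally omitted (free protons are not modeled);
#'   carrier moieties may use pseudo-element tokens (e.g. `"Z"` for CoA).
#' @param charge Optional integer charge.
#' @return A `metabolite` object.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NULL,
                       charge = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.null(formula)) {
    counts <- parse_formula(formula)
    if (any(counts < 0)) stop("formula counts must be non-negative: ", id)
  }
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula, charge = charge),
            class = "metabolite")
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed: negative for consumed
#' metabolites, positive for produced ones. Reversibility is encoded purely
#' by the bounds; `lower_bound < 0` permits backward flux.
#'
#' @param id Short unique token.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds in mmol/gCDW/h.
#' @param name Free-text name.
#' @param gene_rule Optional boolean gene-association expression (a string).
#' @param subsystem Optional subsystem token (e.g. `"TCA"`).
#' @param role Optional canonical role tag, one of
#'   `r paste(ROLE_TAGS, collapse = ", ")`.
#' @return A `reaction` object.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -DEFAULT_BOUND,
                     upper_bound = DEFAULT_BOUND, name = id,
                     gene_rule = NULL, subsystem = NULL, role = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoichiometry <- unlist(stoichiometry)
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("reaction ", id, ": stoichiometry must be a named numeric vector")
  storage.mode(stoichiometry) <- "double"
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction ", id, ": duplicate metabolite in stoichiometry")
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      is.na(lower_bound) || is.na(upper_bound))
    stop("reaction ", id, ": malformed numeric bound")
  if (lower_bound > upper_bound)
    stop("reaction ", id, ": lower_bound > upper_bound")
  if (!is.null(role)) role <- match.arg(role, ROLE_TAGS)
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gene_rule = gene_rule, subsystem = subsystem, role = role),
            class = "reaction")
}

#' Assemble a metabolic model
#'
#' The model is the S v = 0 universe: a set of metabolites, reactions with
#' signed stoichiometry and flux bounds, and linear objective weights.
#'
#' @param id Model id token.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param objective Named numeric vector of objective weights
#'   (reaction id -> weight); empty for no objective.
#' @return A validated `metabolic_model` object.
#' @export
metabolic_model <- function(id, metabolites, reactions,
                            objective = numeric(0)) {
  mets <- stats::setNames(metabolites, vapply(metabolites, `[[`, "", "id"))
  rxns <- stats::setNames(reactions, vapply(reactions, `[[`, "", "id"))
  model <- structure(list(id = id, metabolites = mets, reactions = rxns,
                          objective = unlist(objective) %||% numeric(0)),
                     class = "metabolic_model")
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate model invariants
#'
#' Checks id uniqueness, stoichiometry references, bound ordering, exchange
#' arity is not enforced (exchanges are single-metabolite by construction),
#' role-tag uniqueness and objective references. Errors on first violation.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  roles <- character(0)
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown))
      stop("reaction ", r$id, ": unresolved metabolite reference ",
           paste(unknown, collapse = ", "))
    if (r$lower_bound > r$upper_bound)
      stop("reaction ", r$id, ": lower_bound > upper_bound")
    if (!is.null(r$role)) roles <- c(roles, r$role)
  }
  if (anyDuplicated(roles))
    stop("duplicate role tags: ",
         paste(unique(roles[duplicated(roles)]), collapse = ", "))
  bad_obj <- setdiff(names(model$objective), rxn_ids)
  if (length(bad_obj))
    stop("objective references unknown reactions: ",
         paste(bad_obj, collapse = ", "))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", length(x$metabolites), "\n",
      "  reactions:   ", length(x$reactions), "\n", sep = "")
  if (length(x$objective))
    cat("  objective:   ",
        paste(sprintf("%s (%g)", names(x$objective), x$objective),
              collapse = " + "), "\n", sep = "")
  roles <- reaction_roles(x)
  if (length(roles))
    cat("  roles:       ",
        paste(sprintf("%s=%s", roles, names(roles)), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a model, in model order
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Metabolite ids of a model, in model order
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
metabolite_ids <- function(model) names(model$metabolites)

## named vector: role tag for each reaction that has one (names = rxn ids)
reaction_roles <- function(model) {
  out <- vapply(model$reactions,
                function(r) r$role %||% NA_character_, "")
  out[!is.na(out)]
}

#' Look up a reaction id by canonical role tag
#'
#' @param model A `metabolic_model`.
#' @param role One of the canonical role tags (e.g. `"BIOMASS"`, `"ACN"`).
#' @param required Error if the role is absent (default) or return `NULL`.
#' @return Reaction id (character scalar), or `NULL`.
#' @export
reaction_by_role <- function(model, role, required = TRUE) {
  role <- match.arg(role, ROLE_TAGS)
  roles <- reaction_roles(model)
  hit <- names(roles)[roles == role]
  if (length(hit) == 0L) {
    if (required) stop("model ", model$id, " has no reaction with role ", role)
    return(NULL)
  }
  hit
}

#' Stoichiometric matrix
#'
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix S (metabolites x reactions), dimnames set,
#'   in model order.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow = length(model$metabolites),
              ncol = length(model$reactions),
              dimnames = list(metabolite_ids(model), reaction_ids(model)))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Flux bounds of all reactions
#' @param model A `metabolic_model`.
#' @return Data frame with columns `reaction`, `lb`, `ub` in model order.
#' @export
flux_bounds <- function(model) {
  data.frame(reaction = reaction_ids(model),
             lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
             ub = vapply(model$reactions, `[[`, 0, "upper_bound"),
             row.names = NULL)
}

#' Is a reaction an exchange?
#'
#' An exchange is a boundary pseudo-reaction touching exactly one
#' metabolite; negative flux is uptake, positive is secretion.
#'
#' @param rxn A `reaction` object.
#' @return Logical scalar.
#' @export
is_exchange <- function(rxn) length(rxn$stoichiometry) == 1L

#' Ids of all exchange reactions
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
exchange_ids <- function(model) {
  ids <- reaction_ids(model)
  ids[vapply(model$reactions, is_exchange, TRUE)]
}

#' Set one reaction's flux bounds (returns a modified copy)
#' @param model A `metabolic_model`.
#' @param rxn_id Reaction id.
#' @param lb,ub New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, rxn_id, lb = NULL, ub = NULL) {
  if (!rxn_id %in% reaction_ids(model))
    stop("unknown reaction: ", rxn_id)
  r <- model$reactions[[rxn_id]]
  if (!is.null(lb)) r$lower_bound <- as.numeric(lb)
  if (!is.null(ub)) r$upper_bound <- as.numeric(ub)
  if (r$lower_bound > r$upper_bound)
    stop("reaction ", rxn_id, ": lower_bound > upper_bound")
  model$reactions[[rxn_id]] <- r
  model
}

#' Set the model objective (returns a modified copy)
#' @param model A `metabolic_model`.
#' @param objective Reaction id (weight 1) or named numeric weight vector.
#' @return The modified model.
#' @export
set_objective <- function(model, objective) {
  w <- as_objective_weights(model, objective)
  model$objective <- w
  model
}

## normalize an objective argument (id string or named weights) to weights
as_objective_weights <- function(model, objective) {
  if (is.character(objective) && length(objective) == 1L &&
      is.null(names(objective)))
    objective <- stats::setNames(1, objective)
  w <- unlist(objective)
  if (length(w) == 0L) stop("empty objective")
  bad <- setdiff(names(w), reaction_ids(model))
  if (length(bad))
    stop("objective references unknown reactions: ",
         paste(bad, collapse = ", "))
  w
}

## structural equality up to numeric tolerance; used by round-trip tests
model_equal <- function(a, b, tol = 1e-9) {
  if (!identical(metabolite_ids(a), metabolite_ids(b))) return(FALSE)
  if (!identical(reaction_ids(a), reaction_ids(b))) return(FALSE)
  for (i in seq_along(a$metabolites)) {
    ma <- a$metabolites[[i]]; mb <- b$metabolites[[i]]
    if (!identical(ma$compartment, mb$compartment)) return(FALSE)
    fa <- if (is.null(ma$formula)) NULL else parse_formula(ma$formula)
    fb <- if (is.null(mb$formula)) NULL else parse_formula(mb$formula)
    if (!identical(fa, fb)) return(FALSE)
  }
  for (i in seq_along(a$reactions)) {
    ra <- a$reactions[[i]]; rb <- b$reactions[[i]]
    sa <- sort(names(ra$stoichiometry))
    if (!identical(sa, sort(names(rb$stoichiometry)))) return(FALSE)
    if (max(abs(ra$stoichiometry[sa] - rb$stoichiometry[sa])) > tol)
      return(FALSE)
    if (abs(ra$lower_bound - rb$lower_bound) > tol) return(FALSE)
    if (abs(ra$upper_bound - rb$upper_bound) > tol) return(FALSE)
    if (!identical(ra$role, rb$role)) return(FALSE)
  }
  oa <- a$objective; ob <- b$objective
  if (length(oa) != length(ob)) return(FALSE)
  if (length(oa)) {
    if (!setequal(names(oa), names(ob))) return(FALSE)
    if (max(abs(oa[names(ob)] - ob)) > tol) return(FALSE)
  }
  TRUE
}
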