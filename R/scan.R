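## Design analytics: the flux-multiplier scan, WT-vs-producer delta maps,
## metabolite node-split accounting and the double-robustness surface.

#' Specification of an ACN flux-multiplier scan
#'
#' @param multipliers Positive ascending multipliers applied to the
#'   wild-type aconitase reference flux (default `c(1, 1.5, 2, 2.5, 3)`).
#' @param biomass_fraction Producer biomass floor as a fraction of the
#'   theoretical maximum (default 0.2).
#' @param product_rxn Product objective reaction id; defaults to the
#'   `GABA_EXPORT`-tagged reaction at scan time.
#' @return A `scan_spec` object.
#' @export
scan_spec <- function(multipliers = c(1, 1.5, 2, 2.5, 3),
                      biomass_fraction = 0.2, product_rxn = NULL) {
  stopifnot(all(multipliers > 0), !is.unsorted(multipliers, strictly = TRUE))
  structure(list(multipliers = multipliers,
                 biomass_fraction = biomass_fraction,
                 product_rxn = product_rxn),
            class = "scan_spec")
}

#' Aconitase flux-multiplier scan
#'
#' Fixes the aconitase flux at k-fold the wild-type reference for each
#' multiplier k, runs the producer optimization (product maximized under
#' the biomass floor, pFBA-canonicalized), and tabulates uptake-normalized
#' flux changes against the wild-type distribution. The wild-type
#' reference flux is the `ACN` flux of the canonical (pFBA) biomass-optimal
#' solution.
#'
#' @param model A producer model with roles `ACN`, `BIOMASS` and (unless
#'   `spec$product_rxn` is given) `GABA_EXPORT`.
#' @param spec A [scan_spec()].
#' @param backend LP backend.
#' @return A `scan_result`: `reference_state` (WT pFBA), `states`
#'   (per-multiplier `flux_state`s, `NULL` where infeasible),
#'   `delta_matrix` (reaction x multiplier, `(v_k - v_wt)` / |glucose
#'   uptake|), `product_trace`, `best_multiplier` (ties broken toward the
#'   smallest multiplier).
#' @export
acn_scan <- function(model, spec = scan_spec(), backend = "simplex") {
  stopifnot(inherits(spec, "scan_spec"))
  acn <- reaction_by_role(model, "ACN")
  biomass <- reaction_by_role(model, "BIOMASS")
  uptake <- reaction_by_role(model, "GLC_UPTAKE")
  product <- spec$product_rxn %||% reaction_by_role(model, "GABA_EXPORT")
  wt <- pfba(model, biomass, backend = backend)
  if (wt$status != "optimal") stop("wild-type optimization is ", wt$status)
  v0 <- wt$fluxes[[acn]]
  if (abs(v0) <= REPORT_TOL)
    stop("scan error: wild-type ", acn, " flux is 0; reference undefined")
  u <- abs(wt$fluxes[[uptake]])
  ## one biomass floor for the whole scan: the fraction refers to the
  ## theoretical maximum of the unconstrained model
  mu_star <- wt$objective_value
  floor_v <- spec$biomass_fraction * mu_star
  ids <- reaction_ids(model)
  K <- length(spec$multipliers)
  delta <- matrix(NA_real_, length(ids), K,
                  dimnames = list(ids, paste0("x", spec$multipliers)))
  states <- vector("list", K)
  names(states) <- paste0("x", spec$multipliers)
  trace <- rep(NA_real_, K)
  for (i in seq_len(K)) {
    k <- spec$multipliers[i]
    mk <- set_bounds(set_bounds(model, acn, lb = k * v0, ub = k * v0),
                     biomass, lb = floor_v)
    st <- tryCatch(pfba(mk, product, backend = backend),
                   error = function(e) NULL)
    if (is.null(st) || st$status != "optimal") next
    st$meta$mu_star <- mu_star
    st$meta$biomass_floor <- floor_v
    states[[i]] <- st
    trace[i] <- st$objective_value
    delta[, i] <- (st$fluxes - wt$fluxes) / u
  }
  feasible <- which(!is.na(trace))
  if (!length(feasible)) stop("scan error: no feasible multiplier")
  best <- feasible[which.max(trace[feasible])]
  ## which.max returns the first (smallest multiplier) among exact ties;
  ## widen to tolerance ties
  ties <- feasible[trace[feasible] >= trace[best] - REPORT_TOL]
  best <- min(ties)
  structure(list(spec = spec, reference_state = wt, states = states,
                 delta_matrix = delta, product_trace = trace,
                 best_multiplier = spec$multipliers[best],
                 acn_reference = v0, uptake = u),
            class = "scan_result")
}

#' Per-reaction flux comparison of two states
#'
#' Normalized deltas (`(alt - wt) /` |uptake|) with a direction class per
#' reaction: `up`, `down`, `unchanged`, or `reversed` when both fluxes are
#' nonzero with opposite signs beyond tolerance (the semantics of
#' flux-map arrows flipping direction).
#'
#' @param wt,alt Optimal `flux_state`s over the same reaction universe.
#' @param uptake_rxn Uptake reaction id used for normalization.
#' @param tol Direction-classification tolerance.
#' @return Data frame: `reaction`, `wt_flux`, `alt_flux`,
#'   `delta_normalized`, `direction`.
#' @export
delta_map <- function(wt, alt, uptake_rxn, tol = 1e-6) {
  stopifnot(inherits(wt, "flux_state"), inherits(alt, "flux_state"),
            wt$status == "optimal", alt$status == "optimal")
  if (!identical(names(wt$fluxes), names(alt$fluxes)))
    stop("flux states cover different reaction universes")
  u <- abs(wt$fluxes[[uptake_rxn]])
  if (u <= tol) stop("uptake flux is 0")
  w <- wt$fluxes; a <- alt$fluxes
  direction <- ifelse(
    abs(a - w) <= tol, "unchanged",
    ifelse(abs(w) > tol & abs(a) > tol & sign(w) * sign(a) < 0, "reversed",
           ifelse(abs(a) > abs(w), "up", "down")))
  data.frame(reaction = names(w), wt_flux = unname(w),
             alt_flux = unname(a),
             delta_normalized = unname((a - w) / u),
             direction = unname(direction), row.names = NULL)
}

#' Consumption split at a metabolite node
#'
#' Fractions of the total consumption of a metabolite carried by each
#' consuming reaction (stoichiometry-weighted and direction-aware: a
#' reversible reaction running backward over a product coefficient
#' consumes). Fractions sum to 1.
#'
#' @param state An optimal `flux_state`.
#' @param model The model the state was computed on.
#' @param met_id Metabolite id (e.g. the alpha-ketoglutarate node).
#' @param tol Fluxes below `tol` are treated as zero.
#' @return Named numeric vector of fractions over consuming reactions.
#' @export
node_split <- function(state, model, met_id, tol = 1e-9) {
  stopifnot(inherits(state, "flux_state"), state$status == "optimal")
  if (!met_id %in% metabolite_ids(model)) stop("unknown metabolite: ", met_id)
  cons <- numeric(0)
  for (r in model$reactions) {
    coef <- r$stoichiometry[met_id]
    if (is.na(coef)) next
    rate <- coef * state$fluxes[[r$id]]   # net production of met by r
    if (rate < -tol) cons[r$id] <- -rate
  }
  total <- sum(cons)
  if (total <= tol)
    stop("undefined node: ", met_id, " has no consumption in this state")
  cons / total
}

#' Double-robustness surface
#'
#' Optimal product flux over a 2-D grid of fixed growth rate and fixed
#' flux through a constrained reaction (AKGDH or SUCOAS in the TCA
#' reprogramming analyses). Each cell fixes both values by equality
#' (bound mode available via `mode = "upper"`) and maximizes the product;
#' infeasible cells are masked, never interpolated.
#'
#' @param model Producer model with a `BIOMASS` role.
#' @param constrained_rxn Reaction id or role tag (`"AKGDH"`/`"SUCOAS"`).
#' @param growth_values,flux_values Ascending grids; defaults to 21 even
#'   points in `[0, mu*]` and `[0, max feasible flux]`.
#' @param product_rxn Product reaction id; defaults to the
#'   `GABA_EXPORT`-tagged reaction.
#' @param mode `"equality"` (default) fixes the constrained flux; `"upper"`
#'   imposes it as an upper bound.
#' @param backend LP backend.
#' @return A `robustness_surface`: `objective_matrix`
#'   (growth x flux, `NA` where infeasible), `feasible_mask`, grids, and
#'   `max_cell` (global maximum and its coordinates).
#' @export
double_robustness <- function(model, constrained_rxn,
                              growth_values = NULL, flux_values = NULL,
                              product_rxn = NULL,
                              mode = c("equality", "upper"),
                              backend = "simplex") {
  mode <- match.arg(mode)
  if (constrained_rxn %in% ROLE_TAGS)
    constrained_rxn <- reaction_by_role(model, constrained_rxn)
  if (!constrained_rxn %in% reaction_ids(model))
    stop("unknown reaction: ", constrained_rxn)
  biomass <- reaction_by_role(model, "BIOMASS")
  product <- product_rxn %||% reaction_by_role(model, "GABA_EXPORT")
  if (is.null(growth_values) || is.null(flux_values)) {
    g <- fba(model, biomass, backend = backend)
    if (g$status != "optimal") stop("biomass optimization is ", g$status)
    if (is.null(growth_values))
      growth_values <- seq(0, g$objective_value, length.out = 21)
    if (is.null(flux_values)) {
      fv <- fva(model, constrained_rxn, objective_fraction = 0,
                objective = biomass, backend = backend)
      flux_values <- seq(0, max(fv$max_flux, 0), length.out = 21)
    }
  }
  stopifnot(!is.unsorted(growth_values), !is.unsorted(flux_values),
            length(growth_values) > 0, length(flux_values) > 0)
  M <- matrix(NA_real_, length(growth_values), length(flux_values),
              dimnames = list(signif(growth_values, 6),
                              signif(flux_values, 6)))
  for (i in seq_along(growth_values)) {
    mg <- set_bounds(model, biomass, lb = growth_values[i],
                     ub = growth_values[i])
    for (j in seq_along(flux_values)) {
      mc <- if (mode == "equality")
        set_bounds(mg, constrained_rxn, lb = flux_values[j],
                   ub = flux_values[j])
      else set_bounds(mg, constrained_rxn,
                      lb = min(model$reactions[[constrained_rxn]]$lower_bound,
                               flux_values[j]),
                      ub = flux_values[j])
      st <- fba(mc, product, backend = backend)
      if (st$status == "optimal") M[i, j] <- st$objective_value
    }
  }
  if (all(is.na(M))) warning("all-infeasible robustness surface")
  mx <- which(M == max(M, na.rm = TRUE), arr.ind = TRUE)
  max_cell <- if (nrow(mx)) list(
    growth = growth_values[mx[1, 1]], flux = flux_values[mx[1, 2]],
    product = M[mx[1, 1], mx[1, 2]]) else NULL
  structure(list(constrained_rxn = constrained_rxn,
                 product_rxn = product,
                 growth_values = growth_values, flux_values = flux_values,
                 objective_matrix = M, feasible_mask = !is.na(M),
                 mode = mode, max_cell = max_cell),
            class = "robustness_surface")
}
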