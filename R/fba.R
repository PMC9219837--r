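## Flux balance analysis on a metabolic_model.
##
## All solutions are returned as flux_state objects: per-reaction fluxes in
## model order, the achieved objective value, and a solver status.  Optimal
## states are guaranteed to satisfy |S v| <= 1e-6 * max(1, max|v|) and the
## flux bounds to within 1e-6.

REPORT_TOL <- 1e-6

new_flux_state <- function(model, fluxes, objective_value, status,
                           objective, meta = list()) {
  st <- structure(list(fluxes = fluxes, objective_value = objective_value,
                       status = status, objective = objective, meta = meta),
                  class = "flux_state")
  if (status == "optimal") {
    S <- stoich_matrix(model)
    resid <- max(abs(S %*% fluxes))
    scale <- max(1, max(abs(fluxes)))
    if (resid > REPORT_TOL * scale)
      stop("steady-state violation: |S v| = ", format(resid))
    bd <- flux_bounds(model)
    if (any(fluxes < bd$lb - REPORT_TOL) || any(fluxes > bd$ub + REPORT_TOL))
      stop("bound violation in optimal flux state")
    st$meta$sv_residual <- resid
  }
  st
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status: ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ",
        paste(names(x$objective), collapse = "+"), " = ",
        format(x$objective_value, digits = 8), sep = "")
  cat("\n")
  invisible(x)
}

## pose the model as a flux-form LP; extra_rows: list(a = named coef vector,
## b =, dir = "eq"|"ge") appended below S v = 0
model_lp <- function(model, extra_rows = list()) {
  S <- stoich_matrix(model)
  bd <- flux_bounds(model)
  A <- S
  b <- rep(0, nrow(S))
  lb <- bd$lb; ub <- bd$ub
  n <- ncol(S)
  n_slack <- sum(vapply(extra_rows, function(r) r$dir == "ge", TRUE))
  if (length(extra_rows)) {
    A <- rbind(A, matrix(0, length(extra_rows), n))
    if (n_slack) A <- cbind(A, matrix(0, nrow(A), n_slack))
    sl <- 0L
    for (k in seq_along(extra_rows)) {
      r <- extra_rows[[k]]
      row <- nrow(S) + k
      A[row, match(names(r$a), colnames(S))] <- r$a
      b <- c(b, r$b)
      if (r$dir == "ge") {        # a'v - s = b, s >= 0
        sl <- sl + 1L
        A[row, n + sl] <- -1
      }
    }
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, rep(Inf, n_slack))
  }
  list(A = A, b = b, lb = lb, ub = ub, n = n)
}

#' Maximize a flux objective (plain FBA)
#'
#' Solves `max c'v` subject to `S v = 0` and the model's flux bounds.
#' The returned flux vector is one optimal vertex and is generally not
#' unique; use [pfba()] for a canonical distribution.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id or named weight vector; defaults to the
#'   model's stored objective.
#' @param backend LP backend (see [lp_solve()]).
#' @return A `flux_state`. Infeasibility/unboundedness is reported in
#'   `$status`, never as silent zeros.
#' @export
fba <- function(model, objective = NULL, backend = "simplex") {
  w <- as_objective_weights(model, objective %||% model$objective)
  lp <- model_lp(model)
  cvec <- numeric(lp$n)
  cvec[match(names(w), reaction_ids(model))] <- w
  res <- lp_solve(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE,
                  backend = backend)
  fl <- stats::setNames(res$x[seq_len(lp$n)], reaction_ids(model))
  new_flux_state(model, fl, res$objective, res$status, w,
                 meta = list(backend = backend, canonical = FALSE))
}

#' Parsimonious FBA
#'
#' Fixes the objective at (a fraction of) its maximum, then minimizes the
#' total absolute flux. The result is the canonical distribution used for
#' all reported flux maps; plain [fba()] vertices depend on the solver's
#' pivot order.
#'
#' @inheritParams fba
#' @param objective_fraction Required fraction of the optimal objective
#'   (default 1.0).
#' @return A `flux_state` with `meta$canonical = TRUE`;
#'   `objective_value` reports `c'v` of the returned vector.
#' @export
pfba <- function(model, objective = NULL, objective_fraction = 1.0,
                 backend = "simplex") {
  w <- as_objective_weights(model, objective %||% model$objective)
  s1 <- fba(model, w, backend = backend)
  if (s1$status != "optimal") return(s1)
  floor_val <- objective_fraction * s1$objective_value
  ids <- reaction_ids(model)
  bd <- flux_bounds(model)
  n <- length(ids)
  S <- stoich_matrix(model)
  ## v = p - q with p, q >= 0; minimize sum(p + q)
  A <- cbind(S, -S)
  lbp <- pmax(bd$lb, 0); ubp <- pmax(bd$ub, 0)
  lbq <- pmax(-bd$ub, 0); ubq <- pmax(-bd$lb, 0)
  cvec <- numeric(2L * n)
  cvec[match(names(w), ids)] <- w
  cvec[n + match(names(w), ids)] <- -w
  ## objective floor row: c'(p - q) - s = floor
  A <- rbind(A, c(cvec))
  A <- cbind(A, c(rep(0, nrow(S)), -1))
  b <- c(rep(0, nrow(S)), floor_val)
  lb <- c(lbp, lbq, 0); ub <- c(ubp, ubq, Inf)
  cost <- c(rep(1, 2L * n), 0)
  res <- lp_solve(cost, A, b, lb, ub, maximize = FALSE, backend = backend)
  if (res$status != "optimal")
    return(new_flux_state(model, stats::setNames(rep(NA_real_, n), ids),
                          NA_real_, res$status, w,
                          meta = list(backend = backend, canonical = TRUE)))
  v <- stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)], ids)
  v <- pmin(pmax(v, bd$lb), bd$ub)
  obj <- sum(w * v[names(w)])
  new_flux_state(model, v, obj, "optimal", w,
                 meta = list(backend = backend, canonical = TRUE,
                             total_flux = sum(abs(v)),
                             objective_fraction = objective_fraction))
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective held at
#' `objective_fraction` of its maximum. Brackets alternate optima: any
#' reaction with `max_flux - min_flux` above tolerance has a non-unique
#' reported flux.
#'
#' @inheritParams pfba
#' @param reactions Reaction ids to bracket (default: all).
#' @return Data frame `reaction`, `min_flux`, `max_flux`.
#' @export
fva <- function(model, reactions = NULL, objective_fraction = 1.0,
                objective = NULL, backend = "simplex") {
  w <- as_objective_weights(model, objective %||% model$objective)
  s1 <- fba(model, w, backend = backend)
  if (s1$status != "optimal")
    stop("fva: base optimization is ", s1$status)
  reactions <- reactions %||% reaction_ids(model)
  stopifnot(all(reactions %in% reaction_ids(model)))
  floor_row <- list(a = w, b = objective_fraction * s1$objective_value,
                    dir = "ge")
  lp <- model_lp(model, extra_rows = list(floor_row))
  ids <- reaction_ids(model)
  out <- data.frame(reaction = reactions,
                    min_flux = NA_real_, max_flux = NA_real_)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], ids)
    cvec <- numeric(ncol(lp$A)); cvec[j] <- 1
    hi <- lp_solve(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE,
                   backend = backend)
    lo <- lp_solve(cvec, lp$A, lp$b, lp$lb, lp$ub, maximize = FALSE,
                   backend = backend)
    if (hi$status != "optimal" || lo$status != "optimal")
      stop("fva: subproblem for ", reactions[k], " is ", hi$status)
    out$min_flux[k] <- lo$objective
    out$max_flux[k] <- hi$objective
  }
  out
}

#' Producer-mode constraint
#'
#' @param product_rxn Reaction id of the product export objective.
#' @param biomass_fraction Required biomass as a fraction of the
#'   theoretical maximum, in `[0, 1]` (default 0.2).
#' @return A `production_constraint` object.
#' @export
production_constraint <- function(product_rxn, biomass_fraction = 0.2) {
  stopifnot(biomass_fraction >= 0, biomass_fraction <= 1)
  structure(list(product_rxn = product_rxn,
                 biomass_fraction = biomass_fraction),
            class = "production_constraint")
}

#' Producer-mode optimization under a biomass floor
#'
#' Computes the biomass maximum, imposes
#' `biomass >= biomass_fraction * max`, maximizes the product flux, and
#' returns the pFBA-canonicalized state. The floor is encoded as a lower
#' bound on the biomass reaction.
#'
#' @param model A `metabolic_model` with a `BIOMASS`-tagged reaction.
#' @param constraint A [production_constraint()].
#' @param backend LP backend.
#' @return A canonical `flux_state`; `meta$mu_star` records the biomass
#'   maximum and `meta$biomass_floor` the imposed floor.
#' @export
production_fba <- function(model, constraint, backend = "simplex") {
  stopifnot(inherits(constraint, "production_constraint"))
  biomass <- reaction_by_role(model, "BIOMASS")
  if (!constraint$product_rxn %in% reaction_ids(model))
    stop("unknown product reaction: ", constraint$product_rxn)
  g <- fba(model, biomass, backend = backend)
  if (g$status != "optimal")
    stop("biomass optimization is ", g$status)
  mu_star <- g$objective_value
  if (mu_star <= REPORT_TOL && constraint$biomass_fraction > 0)
    stop("degenerate producer constraint: biomass maximum is 0 with ",
         "biomass_fraction > 0")
  floor_v <- constraint$biomass_fraction * mu_star
  m2 <- set_bounds(model, biomass, lb = floor_v)
  st <- pfba(m2, constraint$product_rxn, backend = backend)
  st$meta$mu_star <- mu_star
  st$meta$biomass_floor <- floor_v
  st$meta$biomass_fraction <- constraint$biomass_fraction
  st
}

#' Maximal growth with uptakes as capacities
#'
#' Viability evaluation for strain designs: fixed-uptake equalities on
#' exchange reactions are relaxed to capacities (`[-rate, 0]`) and
#' positive lower bounds on internal reactions (maintenance floors) are
#' released, so a strain that cannot sustain any flux is reported as
#' growth 0 rather than as an infeasible program.
#'
#' @param model A `metabolic_model` with a `BIOMASS` role.
#' @param backend LP backend.
#' @return Maximal growth rate (numeric scalar).
#' @export
growth_capacity <- function(model, backend = "simplex") {
  biomass <- reaction_by_role(model, "BIOMASS")
  for (id in reaction_ids(model)) {
    r <- model$reactions[[id]]
    if (is_exchange(r) && r$upper_bound < 0)
      model <- set_bounds(model, id, ub = 0)
    else if (!is_exchange(r) && r$lower_bound > 0)
      model <- set_bounds(model, id, lb = 0)
  }
  st <- fba(model, biomass, backend = backend)
  if (st$status != "optimal")
    stop("growth capacity LP is ", st$status)
  st$objective_value
}

#' Normalize a flux state to its substrate uptake
#'
#' Divides every flux by the absolute uptake flux (the convention of
#' glucose-normalized flux maps); the uptake reaction itself maps to 1.0
#' exactly.
#'
#' @param state An optimal `flux_state`.
#' @param uptake_rxn Uptake exchange reaction id.
#' @return Named numeric vector of normalized fluxes.
#' @export
normalize_to_uptake <- function(state, uptake_rxn) {
  stopifnot(inherits(state, "flux_state"), state$status == "optimal")
  if (!uptake_rxn %in% names(state$fluxes))
    stop("unknown reaction: ", uptake_rxn)
  u <- abs(state$fluxes[[uptake_rxn]])
  if (u <= REPORT_TOL)
    stop("normalization error: uptake flux through ", uptake_rxn, " is 0")
  out <- state$fluxes / u
  out[[uptake_rxn]] <- 1.0
  out
}

#' Theoretical maximum product yield
#'
#' Maximizes product flux with no biomass requirement (the biomass floor is
#' released to 0) and reports mol product per mol substrate taken up.
#'
#' @param model A `metabolic_model` with the substrate uptake fixed
#'   nonzero.
#' @param product_rxn Product exchange reaction id.
#' @param substrate_rxn Substrate exchange reaction id.
#' @param backend LP backend.
#' @return List with `yield` (mol/mol), `state` (the optimal
#'   `flux_state`).
#' @export
theoretical_max_yield <- function(model, product_rxn, substrate_rxn,
                                  backend = "simplex") {
  biomass <- reaction_by_role(model, "BIOMASS", required = FALSE)
  if (!is.null(biomass) && model$reactions[[biomass]]$lower_bound > 0)
    model <- set_bounds(model, biomass, lb = 0)
  st <- pfba(model, product_rxn, backend = backend)
  if (st$status != "optimal")
    stop("yield optimization is ", st$status)
  u <- abs(st$fluxes[[substrate_rxn]])
  if (u <= REPORT_TOL)
    stop("substrate uptake through ", substrate_rxn, " is 0")
  list(yield = st$objective_value / u, state = st)
}
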