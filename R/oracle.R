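#' Exhaustive LP vertex-enumeration oracle
#'
#' Solves the model's FBA problem by brute force, independently of the
#' simplex backends: every vertex of the polytope
#' `{S v = 0, lb <= v <= ub}` is enumerated by choosing, for each subset of
#' `n - rank(S)` variables, every combination of active lower/upper bounds
#' and solving the remaining square-ish linear system. The best feasible
#' vertex is returned. Because an LP over a bounded nonempty polytope
#' attains its optimum at a vertex, this agrees with any correct LP solver.
#' Intended for fixture models only.
#'
#' @param model A `metabolic_model` with finite bounds and at most
#'   `max_free` reactions after removing fixed-zero reactions.
#' @param objective Reaction id or weight map; defaults to the model's.
#' @param max_free Size guard on the enumeration (default 12).
#' @param tol Feasibility tolerance.
#' @return A `flux_state` (status `"optimal"` or `"infeasible"`).
#' @export
oracle_solve <- function(model, objective = NULL, max_free = 12L,
                         tol = 1e-7) {
  w <- as_objective_weights(model, objective %||% model$objective)
  ids <- reaction_ids(model)
  bd <- flux_bounds(model)
  if (any(!is.finite(bd$lb)) || any(!is.finite(bd$ub)))
    stop("oracle_solve requires finite bounds")
  S <- stoich_matrix(model)
  cvec <- numeric(length(ids)); cvec[match(names(w), ids)] <- w

  ## substitute out fixed variables (lb == ub), including fixed-zero ones
  fixed <- which(abs(bd$ub - bd$lb) <= .Machine$double.eps * 100)
  free <- setdiff(seq_along(ids), fixed)
  if (length(free) > max_free)
    stop("oracle scope exceeded: ", length(free), " free reactions (max ",
         max_free, ")")
  v_fixed <- bd$lb[fixed]
  b <- if (length(fixed)) -as.vector(S[, fixed, drop = FALSE] %*% v_fixed)
       else rep(0, nrow(S))
  Sf <- S[, free, drop = FALSE]
  lb <- bd$lb[free]; ub <- bd$ub[free]
  n <- length(free)

  assemble <- function(vf) {
    v <- numeric(length(ids))
    v[fixed] <- v_fixed
    v[free] <- vf
    stats::setNames(v, ids)
  }
  if (n == 0L) {
    v <- assemble(numeric(0))
    feas <- max(abs(S %*% v)) <= tol * max(1, max(abs(v)))
    return(new_flux_state(model, v,
                          if (feas) sum(cvec * v) else NA_real_,
                          if (feas) "optimal" else "infeasible", w,
                          meta = list(backend = "oracle")))
  }

  r <- qr(Sf)$rank
  k <- n - r
  best_v <- NULL; best_obj <- -Inf
  consider <- function(vf) {
    resid <- max(abs(Sf %*% vf - b))
    if (resid > tol * max(1, max(abs(vf)))) return()
    if (any(vf < lb - tol) || any(vf > ub + tol)) return()
    vf <- pmin(pmax(vf, lb), ub)
    obj <- sum(cvec[free] * vf)
    if (obj > best_obj + 1e-12) { best_obj <<- obj; best_v <<- vf }
  }

  if (k == 0L) {
    vf <- tryCatch(qr.solve(Sf, b, tol = 1e-10), error = function(e) NULL)
    if (!is.null(vf)) consider(vf)
  } else {
    subsets <- utils::combn(n, k)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
    for (s in seq_len(ncol(subsets))) {
      J <- subsets[, s]
      Ff <- setdiff(seq_len(n), J)
      SJ <- Sf[, J, drop = FALSE]
      SF <- Sf[, Ff, drop = FALSE]
      qrF <- qr(SF)
      if (qrF$rank < length(Ff)) next   # vertex covered by another subset
      for (g in seq_len(nrow(grid))) {
        vJ <- ifelse(grid[g, ], ub[J], lb[J])
        rhs <- b - as.vector(SJ %*% vJ)
        vF <- qr.coef(qrF, rhs)
        if (anyNA(vF)) next
        vf <- numeric(n); vf[J] <- vJ; vf[Ff] <- vF
        consider(vf)
      }
    }
  }
  if (is.null(best_v))
    return(new_flux_state(model,
                          stats::setNames(rep(NA_real_, length(ids)), ids),
                          NA_real_, "infeasible", w,
                          meta = list(backend = "oracle")))
  v <- assemble(best_v)
  new_flux_state(model, v, sum(cvec * v), "optimal", w,
                 meta = list(backend = "oracle"))
}
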