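## Linear programming layer.
##
## Problems are posed in "flux form":  optimize c'v  s.t.  A v = b,
## lb <= v <= ub  (finite lb required; ub may be +Inf).  Two backends solve
## the same standard-form translation: "simplex", a dense two-phase primal
## simplex implemented here (Dantzig pricing with a Bland's-rule fallback to
## guarantee termination), and "boot", the simplex implementation from the
## boot package.  Backend agreement on fixtures is part of the test suite.

LP_FEAS_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' @param cvec Objective coefficients (length n).
#' @param A Equality constraint matrix (m x n); may have zero rows.
#' @param b Right-hand side (length m).
#' @param lb,ub Variable bounds; all `lb` finite, `ub` may be `Inf`.
#' @param maximize Maximize (default) or minimize.
#' @param backend `"simplex"` (built-in) or `"boot"` (`boot::simplex`).
#' @param tol Feasibility/pivot tolerance.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (length n, `NA` unless optimal) and `objective`.
#' @export
lp_solve <- function(cvec, A, b, lb, ub, maximize = TRUE,
                     backend = c("simplex", "boot"), tol = LP_FEAS_TOL) {
  backend <- match.arg(backend)
  n <- length(cvec)
  stopifnot(ncol(A) == n, length(b) == nrow(A),
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("all lower bounds must be finite")
  if (any(lb > ub + tol)) return(list(status = "infeasible",
                                      x = rep(NA_real_, n),
                                      objective = NA_real_))
  ## shift to x = v - lb >= 0; add slack rows for finite upper bounds
  ub_shift <- ub - lb
  fin <- which(is.finite(ub_shift))
  m <- nrow(A)
  nf <- length(fin)
  Aeq <- matrix(0, m + nf, n + nf)
  Aeq[seq_len(m), seq_len(n)] <- A
  beq <- c(b - as.vector(A %*% lb), ub_shift[fin])
  if (nf) {
    Aeq[cbind(m + seq_len(nf), fin)] <- 1
    Aeq[cbind(m + seq_len(nf), n + seq_len(nf))] <- 1
  }
  cost <- c(if (maximize) -cvec else cvec, rep(0, nf))
  res <- if (backend == "simplex")
    simplex_standard(Aeq, beq, cost, tol = tol)
  else
    boot_standard(Aeq, beq, cost)
  if (res$status != "optimal")
    return(list(status = res$status, x = rep(NA_real_, n),
                objective = NA_real_))
  v <- res$x[seq_len(n)] + lb
  v <- pmin(pmax(v, lb), ub)          # clip solver noise into bounds
  obj <- sum(cvec * v)
  list(status = "optimal", x = v, objective = obj)
}

## min cost'x  s.t.  A x = b, x >= 0  (dense two-phase tableau simplex)
simplex_standard <- function(A, b, cost, tol = LP_FEAS_TOL,
                             max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  ## tableau: columns = n structural + m artificial + rhs; last row = obj
  Tb <- rbind(cbind(A, diag(m), b), 0)
  basis <- n + seq_len(m)
  ## phase-1 objective: minimize sum of artificials
  Tb[m + 1L, ] <- -colSums(Tb[seq_len(m), , drop = FALSE])
  Tb[m + 1L, n + seq_len(m)] <- 0

  pivot <- function(Tb, lr, ec) {
    prow <- Tb[lr, ] / Tb[lr, ec]
    Tb <- Tb - outer(Tb[, ec], prow)
    Tb[lr, ] <- prow
    Tb
  }
  run_phase <- function(Tb, basis, allowed, iter0) {
    it <- iter0
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached")
      obj_row <- Tb[m + 1L, allowed]
      cand <- which(obj_row < -tol)
      if (!length(cand)) return(list(Tb = Tb, basis = basis, it = it,
                                     status = "done"))
      ec <- if (it > 4L * (m + n)) allowed[cand[1L]]          # Bland
            else allowed[cand[which.min(obj_row[cand])]]      # Dantzig
      col <- Tb[seq_len(m), ec]
      ok <- which(col > tol)
      if (!length(ok)) return(list(Tb = Tb, basis = basis, it = it,
                                   status = "unbounded"))
      ratio <- Tb[ok, ncol(Tb)] / col[ok]
      best <- ratio <= min(ratio) + tol
      lr <- ok[best][which.min(basis[ok[best]])]              # Bland tie-break
      Tb <- pivot(Tb, lr, ec)
      basis[lr] <- ec
    }
  }

  ph1 <- run_phase(Tb, basis, seq_len(n + m), 0L)
  if (ph1$status == "unbounded") stop("phase-1 unbounded (internal error)")
  Tb <- ph1$Tb; basis <- ph1$basis
  if (Tb[m + 1L, ncol(Tb)] < -tol * max(1, max(abs(b))) * 10)
    return(list(status = "infeasible"))

  ## drive leftover artificials out of the basis (degenerate rows)
  drop_rows <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] <= n) next
    piv_col <- which(abs(Tb[i, seq_len(n)]) > tol)
    if (length(piv_col)) {
      Tb <- pivot(Tb, i, piv_col[1L])
      basis[i] <- piv_col[1L]
    } else drop_rows <- c(drop_rows, i)   # redundant constraint
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(m), drop_rows)
    Tb <- Tb[c(keep, m + 1L), , drop = FALSE]
    basis <- basis[keep]
    m <- length(keep)
  }

  ## phase 2: rebuild objective row from true costs
  Tb[m + 1L, ] <- 0
  Tb[m + 1L, seq_len(n)] <- cost
  for (i in seq_len(m))
    if (abs(cost[basis[i]]) > 0)
      Tb[m + 1L, ] <- Tb[m + 1L, ] - cost[basis[i]] * Tb[i, ]
  ph2 <- run_phase(Tb, basis, seq_len(n), ph1$it)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- numeric(n)
  inb <- basis <= n
  x[basis[inb]] <- Tb[seq_len(m), ncol(Tb)][inb]
  x[x < 0] <- 0
  list(status = "optimal", x = x, objective = sum(cost * x))
}

## boot::simplex on the same standard form
boot_standard <- function(A, b, cost) {
  ## boot::simplex mishandles linearly dependent constraint rows; keep an
  ## independent row subset (and detect inconsistency = infeasibility)
  qa <- qr(t(A))
  if (qa$rank < nrow(A)) {
    if (qr(t(cbind(A, b)))$rank > qa$rank)
      return(list(status = "infeasible"))
    keep <- sort(qa$pivot[seq_len(qa$rank)])
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
  }
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  out <- boot::simplex(a = cost, A3 = A, b3 = b, maxi = FALSE,
                       n.iter = 50L * (nrow(A) + ncol(A)), eps = 1e-10)
  if (out$solved == -1L) return(list(status = "infeasible"))
  if (out$solved != 1L) stop("boot::simplex did not converge")
  list(status = "optimal", x = as.numeric(out$soln),
       objective = unname(out$value))
}
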