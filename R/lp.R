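# Internal linear-programming kernel: a two-phase dense primal simplex with
# Bland's anti-cycling rule.  Deterministic, no big-M constants, exact up to
# floating point — sized for the small network LPs pFBA generates (tens of
# reactions after fixed-variable elimination).
#
# solve_lp() handles the bounded form
#     max/min  c'x   s.t.  Aeq x = beq,  lb <= x <= ub
# by eliminating fixed variables (lb == ub), shifting the rest to be
# non-negative and turning finite upper bounds into slack rows, then calls
# the standard-form kernel  min c'x, A x = b, x >= 0.

LP_FEAS_TOL <- 1e-6
LP_PIVOT_TOL <- 1e-9

# one simplex run on a tableau; Bland's rule guarantees termination
simplex_iterate <- function(Tab, basis, cost, ncols, maxit = 50000L) {
  m <- nrow(Tab)
  rhs_col <- ncol(Tab)
  for (it in seq_len(maxit)) {
    red <- cost[seq_len(ncols)] -
      as.numeric(cost[basis] %*% Tab[, seq_len(ncols), drop = FALSE])
    ent <- which(red < -LP_PIVOT_TOL)
    if (!length(ent)) return(list(Tab = Tab, basis = basis, status = "optimal"))
    j <- ent[1L]                              # Bland: smallest entering index
    col <- Tab[, j]
    pos <- which(col > LP_PIVOT_TOL)
    if (!length(pos)) return(list(Tab = Tab, basis = basis, status = "unbounded"))
    ratios <- Tab[pos, rhs_col] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + LP_PIVOT_TOL]
    r <- cand[which.min(basis[cand])]         # Bland: smallest leaving variable
    Tab[r, ] <- Tab[r, ] / Tab[r, j]
    others <- setdiff(seq_len(m), r)
    if (length(others))
      Tab[others, ] <- Tab[others, ] - outer(Tab[others, j], Tab[r, ])
    basis[r] <- j
  }
  list(Tab = Tab, basis = basis, status = "maxit")
}

# min cc'x  s.t.  A x = b, x >= 0
simplex_solve <- function(cc, A, b) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  # phase 1: artificial basis
  Tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  p1 <- simplex_iterate(Tab, basis, c(rep(0, n), rep(1, m)), ncols = n + m)
  if (p1$status != "optimal") return(list(status = "numerical", x = NULL))
  Tab <- p1$Tab; basis <- p1$basis
  if (sum(Tab[basis > n, ncol(Tab)]) > 1e-7)
    return(list(status = "infeasible", x = NULL))

  # drive remaining artificials out of the basis; drop redundant rows
  keep <- rep(TRUE, nrow(Tab))
  for (r in which(basis > n)) {
    j <- which(abs(Tab[r, seq_len(n)]) > LP_PIVOT_TOL)[1]
    if (is.na(j)) { keep[r] <- FALSE; next }
    Tab[r, ] <- Tab[r, ] / Tab[r, j]
    others <- setdiff(seq_len(nrow(Tab)), r)
    Tab[others, ] <- Tab[others, ] - outer(Tab[others, j], Tab[r, ])
    basis[r] <- j
  }
  Tab <- Tab[keep, c(seq_len(n), ncol(Tab)), drop = FALSE]
  basis <- basis[keep]

  p2 <- simplex_iterate(Tab, basis, cc, ncols = n)
  if (p2$status == "unbounded") return(list(status = "unbounded", x = NULL))
  if (p2$status != "optimal") return(list(status = "numerical", x = NULL))
  x <- numeric(n)
  x[p2$basis] <- p2$Tab[, ncol(p2$Tab)]
  list(status = "optimal", x = pmax(x, 0), objective = sum(cc * x))
}

solve_lp <- function(obj, Aeq, beq, lb, ub, maximize = FALSE) {
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + LP_FEAS_TOL))
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                message = "variable with lower bound above upper bound"))

  fixed <- which(ub - lb <= LP_FEAS_TOL)
  free <- setdiff(seq_len(n), fixed)
  x <- numeric(n)
  x[fixed] <- (lb[fixed] + ub[fixed]) / 2
  rhs <- beq - if (length(fixed)) as.numeric(Aeq[, fixed, drop = FALSE] %*% x[fixed]) else 0

  if (!length(free)) {
    ok <- all(abs(rhs) <= 1e-5)
    return(list(status = if (ok) "optimal" else "infeasible", x = if (ok) x else NULL,
                objective = if (ok) sum(obj * x) else NA_real_,
                message = "all variables fixed"))
  }

  lo <- lb[free]
  if (any(!is.finite(lo))) stop("solve_lp requires finite lower bounds")
  A2 <- Aeq[, free, drop = FALSE]
  rhs2 <- rhs - as.numeric(A2 %*% lo)
  span <- ub[free] - lo
  bounded <- which(is.finite(span))
  nf <- length(free); nb <- length(bounded)

  # standard form: [A2 0; E I] (x; s) = (rhs2; span), E = rows of I at bounded
  A_std <- matrix(0, nrow(A2) + nb, nf + nb)
  A_std[seq_len(nrow(A2)), seq_len(nf)] <- A2
  if (nb) {
    A_std[cbind(nrow(A2) + seq_len(nb), bounded)] <- 1
    A_std[cbind(nrow(A2) + seq_len(nb), nf + seq_len(nb))] <- 1
  }
  b_std <- c(rhs2, span[bounded])
  cc <- c(if (maximize) -obj[free] else obj[free], rep(0, nb))

  res <- simplex_solve(cc, A_std, b_std)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, objective = NA_real_,
                message = paste("LP", res$status)))
  x[free] <- res$x[seq_len(nf)] + lo
  list(status = "optimal", x = x, objective = sum(obj * x), message = "optimal")
}
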