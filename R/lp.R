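# Dense two-phase primal simplex used as the linear-programming kernel for
# flux balance and flux variability analysis. Problems are the small, dense
# LPs arising from toy and community reconstructions (tens to a few hundred
# columns), so a tableau implementation is adequate and keeps the package
# free of external solver dependencies.
#
# Solves: optimise  c'v   subject to  Aeq v = beq,  lb <= v <= ub.
# Finite lower bounds are required (flux bounds always are here); upper
# bounds may be +Inf. Anti-cycling: Dantzig pricing switching to Bland's
# rule after a fixed number of iterations, which guarantees termination.

# One simplex run on an explicit tableau.
# A: m x p constraint matrix with A[, basis] == I, b >= 0, cost length p.
# Minimises cost' z for z >= 0. Returns status in {"optimal", "unbounded"}.
.simplex_core <- function(A, b, cost, basis, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(A)
  p <- ncol(A)
  bland_after <- 100L + 20L * m
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("simplex iteration limit reached (", max_iter, ")")
    }
    y <- cost[basis]
    # reduced costs d = cost - y'A (A[, basis] = I so d[basis] = 0)
    d <- cost - as.vector(crossprod(A, y))
    d[basis] <- 0
    cand <- which(d < -tol)
    if (length(cand) == 0L) {
      return(list(status = "optimal", A = A, b = b, basis = basis))
    }
    if (iter <= bland_after) {
      j <- cand[which.min(d[cand])]
    } else {
      j <- cand[1L] # Bland: smallest index
    }
    col <- A[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(status = "unbounded", A = A, b = b, basis = basis,
                  entering = j))
    }
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol]
    # Bland-compatible tie-break: leave the variable with smallest index
    i <- ties[which.min(basis[ties])]
    # pivot on (i, j)
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    other <- setdiff(seq_len(m), i)
    f <- A[other, j]
    A[other, ] <- A[other, , drop = FALSE] - outer(f, A[i, ])
    b[other] <- b[other] - f * b[i]
    A[, j] <- 0
    A[i, j] <- 1
    b[b < 0 & b > -tol] <- 0
    basis[i] <- j
  }
}

#' Solve a bounded linear programme
#'
#' Internal LP layer: optimises `obj'v` subject to `Aeq v = beq` and
#' `lb <= v <= ub` with a dense two-phase simplex. All lower bounds must be
#' finite; upper bounds may be `Inf`.
#'
#' @param obj numeric objective coefficients.
#' @param Aeq equality constraint matrix (may have zero rows).
#' @param beq equality right-hand sides.
#' @param lb,ub variable bounds.
#' @param maximize logical; maximise (default) or minimise.
#' @param tol feasibility tolerance.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` and the solution vector `x` (at optimum).
#' @keywords internal
lp_solve <- function(obj, Aeq, beq, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) {
    stop("lp_solve requires finite lower bounds")
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  if (is.null(Aeq) || nrow(Aeq) == 0L) {
    Aeq <- matrix(0, 0, n)
    beq <- numeric(0)
  }
  Aeq <- as.matrix(Aeq)
  # shift x = v - lb >= 0; x <= U where U = ub - lb
  U <- ub - lb
  b1 <- as.vector(beq - Aeq %*% lb)
  ubrows <- which(is.finite(U))
  m1 <- nrow(Aeq)
  m2 <- length(ubrows)
  # columns: n structural + m2 upper-bound slacks
  A <- matrix(0, m1 + m2, n + m2)
  if (m1 > 0L) A[seq_len(m1), seq_len(n)] <- Aeq
  if (m2 > 0L) {
    A[cbind(m1 + seq_len(m2), ubrows)] <- 1
    A[cbind(m1 + seq_len(m2), n + seq_len(m2))] <- 1
  }
  b <- c(b1, U[ubrows])
  # flip rows so b >= 0 (upper-bound rows already are)
  neg <- which(b < 0)
  if (length(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  m <- m1 + m2
  p <- n + m2
  # phase 1: artificials on equality rows; slacks start basic on ub rows
  # (their rhs is >= 0 and their slack column is +1 after no flip)
  nart <- m1
  if (nart > 0L) {
    Aall <- cbind(A, matrix(0, m, nart))
    Aall[cbind(seq_len(m1), p + seq_len(m1))] <- 1
    basis <- c(p + seq_len(m1), if (m2) n + seq_len(m2))
    cost1 <- c(rep(0, p), rep(1, nart))
    r <- .simplex_core(Aall, b, cost1, basis, tol = tol)
    phase1_obj <- sum(cost1[r$basis] * r$b)
    if (phase1_obj > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
    A2 <- r$A
    b2 <- r$b
    basis <- r$basis
    # pivot any basic artificials out (degenerate rows), else drop row
    art <- which(basis > p)
    keep <- rep(TRUE, m)
    for (i in art) {
      row <- A2[i, seq_len(p)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        j <- j[1L]
        piv <- A2[i, j]
        A2[i, ] <- A2[i, ] / piv
        b2[i] <- b2[i] / piv
        other <- setdiff(seq_len(m), i)
        f <- A2[other, j]
        A2[other, ] <- A2[other, , drop = FALSE] - outer(f, A2[i, ])
        b2[other] <- b2[other] - f * b2[i]
        basis[i] <- j
      } else {
        keep[i] <- FALSE
      }
    }
    A <- A2[keep, seq_len(p), drop = FALSE]
    b <- b2[keep]
    basis <- basis[keep]
  } else {
    basis <- n + seq_len(m2)
  }
  cost <- c(if (maximize) -obj else obj, rep(0, m2))
  r <- .simplex_core(A, b, cost, basis, tol = tol)
  if (r$status == "unbounded") {
    return(list(status = "unbounded",
                objective = if (maximize) Inf else -Inf, x = NULL))
  }
  z <- numeric(p)
  z[r$basis] <- r$b
  x <- z[seq_len(n)] + lb
  val <- sum(obj * x)
  list(status = "optimal", objective = val, x = x)
}
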