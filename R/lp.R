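# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves   max c'x   s.t.  Aeq x = beq,  lb <= x <= ub.
#
# Written in-package because no reliable general-purpose LP routine is
# available among the package's dependencies; problems handled here are
# small (tens of variables), so a dense tableau is adequate. Correctness is
# cross-checked in the test suite against an independent vertex-enumeration
# oracle.

LP_TOL <- 1e-9
LP_BIG <- 1e9  # stand-in for infinite bounds; hitting it flags unboundedness

# one tableau pass: minimise obj over {T x = rhs, x >= 0} starting from a
# basic feasible `basis`; T is the full constraint matrix (already B^-1 A).
simplex_iterate <- function(T, basis, obj) {
  nv <- ncol(T) - 1L
  rhs_col <- nv + 1L
  repeat {
    cb <- obj[basis]
    # reduced costs under the current basis
    rc <- obj - as.vector(crossprod(T[, seq_len(nv), drop = FALSE], cb))
    rc[basis] <- 0
    enter <- which(rc < -LP_TOL)
    if (!length(enter)) return(list(T = T, basis = basis, status = "optimal"))
    j <- min(enter)                                   # Bland: smallest index
    col <- T[, j]
    pos <- which(col > LP_TOL)
    if (!length(pos)) return(list(T = T, basis = basis, status = "unbounded"))
    ratio <- T[pos, rhs_col] / col[pos]
    cand <- pos[ratio <= min(ratio) + LP_TOL]
    i <- cand[which.min(basis[cand])]                 # Bland: smallest basic
    piv <- T[i, j]
    T[i, ] <- T[i, ] / piv
    other <- setdiff(seq_len(nrow(T)), i)
    T[other, ] <- T[other, ] - outer(T[other, j], T[i, ])
    basis[i] <- j
  }
}

#' Solve a bounded linear program (internal)
#'
#' @param cvec objective coefficients (maximised).
#' @param Aeq equality constraint matrix (may have redundant rows).
#' @param beq equality right-hand sides.
#' @param lb,ub variable bounds; infinities are capped at an internal big
#'   bound and reported as `unbounded` when attained.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` and `value`.
#' @noRd
lp_solve_max <- function(cvec, Aeq, beq, lb, ub) {
  n <- length(cvec)
  stopifnot(ncol(Aeq) == n, length(beq) == nrow(Aeq),
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + LP_TOL)) return(list(status = "infeasible",
                                         x = rep(NA_real_, n), value = NA_real_))
  capped <- !is.finite(lb) | !is.finite(ub)
  lb2 <- pmax(lb, -LP_BIG)
  ub2 <- pmin(ub, LP_BIG)

  # shift to y = x - lb in [0, u]
  u <- ub2 - lb2
  m <- nrow(Aeq)
  b0 <- as.vector(beq - Aeq %*% lb2)
  A <- Aeq
  flip <- b0 < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b0[flip] <- -b0[flip]

  # standard form over [y, s, a]: A y + a = b0 ; y + s = u
  nv <- 2L * n + m
  T <- matrix(0, m + n, nv + 1L)
  if (m > 0L) {
    T[seq_len(m), seq_len(n)] <- A
    T[cbind(seq_len(m), 2L * n + seq_len(m))] <- 1
    T[seq_len(m), nv + 1L] <- b0
  }
  T[m + seq_len(n), seq_len(n)] <- diag(n)
  T[cbind(m + seq_len(n), n + seq_len(n))] <- 1
  T[m + seq_len(n), nv + 1L] <- u
  basis <- c(if (m > 0L) 2L * n + seq_len(m), n + seq_len(n))

  # phase 1: drive artificials to zero
  obj1 <- c(rep(0, 2L * n), rep(1, m))
  r1 <- simplex_iterate(T, basis, obj1)
  val1 <- sum(obj1[r1$basis] * r1$T[, nv + 1L])
  if (val1 > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
  }
  T <- r1$T
  basis <- r1$basis
  # pivot residual zero-level artificials out of the basis (or drop rows)
  art <- which(basis > 2L * n)
  drop_rows <- integer(0L)
  for (i in art) {
    cols <- which(abs(T[i, seq_len(2L * n)]) > LP_TOL)
    if (!length(cols)) {
      drop_rows <- c(drop_rows, i)
      next
    }
    j <- cols[1L]
    piv <- T[i, j]
    T[i, ] <- T[i, ] / piv
    other <- setdiff(seq_len(nrow(T)), i)
    T[other, ] <- T[other, ] - outer(T[other, j], T[i, ])
    basis[i] <- j
  }
  if (length(drop_rows)) {
    T <- T[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # forbid artificial columns from re-entering
  obj2 <- c(-cvec, rep(0, n), rep(LP_BIG, m))
  r2 <- simplex_iterate(T, basis, obj2)
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))
  }
  y <- numeric(nv)
  y[r2$basis] <- r2$T[, nv + 1L]
  x <- y[seq_len(n)] + lb2
  if (any(capped & (abs(x - ub2) < 1e-3 | abs(x - lb2) < 1e-3) &
          (abs(x) > LP_BIG / 2))) {
    return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))
  }
  list(status = "optimal", x = x, value = sum(cvec * x))
}
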