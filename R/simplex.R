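#' @title Dense two-phase simplex for small feasibility LPs
#'
#' @description
#' The package needs only tiny linear programs (tens of variables and
#' constraints): deciding whether a target marginal transition is realizable
#' under a signal kernel, and the enumeration LPs of the ZD existence search.
#' This is a textbook two-phase tableau simplex with Bland's rule (so it
#' cannot cycle) over free variables split as differences of nonnegatives.
#'
#' @param a_eq,b_eq equality constraints `a_eq x = b_eq` (may be `NULL`).
#' @param a_le,b_le inequality constraints `a_le x <= b_le` (may be `NULL`).
#' @param objective coefficient vector to maximize, or `NULL` for pure
#'   feasibility.
#' @param tol pivoting tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution in the original free variables) and `value`.
#' @export
lp_solve <- function(a_eq = NULL, b_eq = NULL, a_le = NULL, b_le = NULL,
                     objective = NULL, tol = 1e-9) {
  nvar <- if (!is.null(a_eq)) ncol(a_eq) else ncol(a_le)
  if (is.null(a_eq)) { a_eq <- matrix(0, 0, nvar); b_eq <- numeric(0) }
  if (is.null(a_le)) { a_le <- matrix(0, 0, nvar); b_le <- numeric(0) }
  stopifnot(ncol(a_eq) == nvar, ncol(a_le) == nvar,
            nrow(a_eq) == length(b_eq), nrow(a_le) == length(b_le))
  m1 <- nrow(a_eq); m2 <- nrow(a_le); m <- m1 + m2
  # split x = u - v, add slacks for the inequalities
  A <- rbind(cbind(a_eq, -a_eq, matrix(0, m1, m2)),
             cbind(a_le, -a_le, diag(1, m2)))
  b <- c(b_eq, b_le)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  n0 <- ncol(A)
  # phase 1: artificials
  A1 <- cbind(A, diag(1, m))
  cost1 <- c(numeric(n0), rep(1, m))
  basis <- n0 + seq_len(m)
  res1 <- .simplex(A1, b, cost1, basis, tol, forbid = integer(0))
  if (res1$status != "optimal" || res1$value > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  extract <- function(res) {
    x_full <- res$x
    u <- x_full[seq_len(nvar)]
    v <- x_full[nvar + seq_len(nvar)]
    u - v
  }
  if (is.null(objective)) {
    return(list(status = "optimal", x = extract(res1), value = 0))
  }
  # drive leftover artificials out of the basis before phase 2
  Tb <- res1$tableau
  basis <- res1$basis
  for (i in seq_len(m)) {
    if (basis[i] > n0) {
      j <- which(abs(Tb[i, seq_len(n0)]) > tol)[1]
      if (!is.na(j)) {
        Tb[i, ] <- Tb[i, ] / Tb[i, j]
        for (k in seq_len(m)) {
          if (k != i && Tb[k, j] != 0) Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[i, ]
        }
        basis[i] <- j
      }
    }
  }
  # phase 2: maximize objective => minimize -objective
  cost2 <- c(-objective, objective, numeric(m2), numeric(m))
  res2 <- .simplex(A1, Tb[, ncol(Tb)], cost2, basis, tol,
                   forbid = n0 + seq_len(m), tableau = Tb)
  if (res2$status != "optimal") {
    return(list(status = res2$status, x = NULL, value = NA_real_))
  }
  list(status = "optimal", x = extract(res2), value = -res2$value)
}

# Minimize cost'x over Ax = b (b >= 0 at the initial basis), x >= 0.
# `forbid` are column indices that may never enter the basis (spent
# artificials).  Optionally resumes from a previous tableau.
.simplex <- function(A, b, cost, basis, tol, forbid, tableau = NULL,
                     maxit = 5000) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(tableau)) {
    Tb <- cbind(A, b)
    for (i in seq_len(m)) {
      j <- basis[i]
      piv <- Tb[i, j]
      if (abs(piv) < tol) stop("simplex: singular starting basis")
      Tb[i, ] <- Tb[i, ] / piv
      for (k in seq_len(m)) {
        if (k != i && abs(Tb[k, j]) > 0) Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[i, ]
      }
    }
  } else {
    Tb <- tableau
  }
  for (it in seq_len(maxit)) {
    cb <- cost[basis]
    red <- cost[seq_len(n)] - as.vector(cb %*% Tb[, seq_len(n), drop = FALSE])
    cand <- which(red < -tol)
    cand <- setdiff(cand, forbid)
    if (!length(cand)) {
      x <- numeric(n)
      x[basis] <- Tb[, n + 1]
      return(list(status = "optimal", x = x, value = sum(cost * x),
                  basis = basis, rhs = Tb[, n + 1], tableau = Tb))
    }
    j <- min(cand)                       # Bland
    col <- Tb[, j]
    ok <- which(col > tol)
    if (!length(ok)) return(list(status = "unbounded"))
    ratios <- Tb[ok, n + 1] / col[ok]
    best <- min(ratios)
    ties <- ok[ratios <= best + tol * (1 + abs(best))]
    i <- ties[which.min(basis[ties])]    # Bland tie-break
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    for (k in seq_len(m)) {
      if (k != i && abs(Tb[k, j]) > tol * 0) {
        f <- Tb[k, j]
        if (f != 0) Tb[k, ] <- Tb[k, ] - f * Tb[i, ]
      }
    }
    Tb[i, j] <- 1
    basis[i] <- j
  }
  list(status = "maxit")
}
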