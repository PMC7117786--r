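#' @title Linear-algebra kernel: rref, rank, null spaces, subspaces
#'
#' @description
#' Reduced row echelon form with two numeric modes.  Rational input is
#' processed with exact Gauss-Jordan elimination (pivot = first nonzero
#' entry); numeric input uses partial pivoting with a relative tolerance.
#' All higher-level subspace operations (column space, intersection,
#' membership, Rouche-Capelli consistency) are built on this routine so that
#' exact and float modes share one code path.
#'
#' @param a matrix, rational or numeric.
#' @param tol relative tolerance for treating entries as zero in float mode.
#' @return `rref()` returns `list(r = echelon matrix, pivots = pivot column
#'   indices)`.
#' @export
rref <- function(a, tol = 1e-9) {
  if (is_rational(a)) .rref_exact(a) else .rref_float(a, tol)
}

# exact Gauss-Jordan on integer-scaled rows with gcd reduction: rows are
# cleared to integers up front, elimination uses cross-multiplication
# (f1 * row_i - f2 * row_r with f1, f2 coprime), and each resulting row is
# divided by the gcd of its entries.  This keeps entry growth near the
# Bareiss minor bound instead of squaring denominators, and every product is
# guarded against leaving the exact double range.
.rref_exact <- function(a) {
  if (is.null(dim(a$num))) dim(a) <- c(length(a$num), 1)
  n <- nrow(a$num); m <- ncol(a$num)
  if (n == 0 || m == 0) return(list(r = a, pivots = integer(0)))
  N <- matrix(0, n, m)
  for (i in seq_len(n)) {
    L <- 1
    for (d in a$den[i, ]) {
      g <- .rat_gcd(L, d)
      L <- L / g * d
      .rat_guard(L, 1)
    }
    N[i, ] <- a$num[i, ] * (L / a$den[i, ])
    .rat_guard(N[i, ], 1)
    g <- .row_gcd(N[i, ])
    if (g > 1) N[i, ] <- N[i, ] / g
  }
  pivots <- integer(0)
  r <- 1L
  for (j in seq_len(m)) {
    if (r > n) break
    nz <- which(N[r:n, j] != 0)
    if (!length(nz)) next
    piv <- r - 1L + nz[1]
    if (piv != r) { tmp <- N[r, ]; N[r, ] <- N[piv, ]; N[piv, ] <- tmp }
    for (i in seq_len(n)) {
      if (i == r || N[i, j] == 0) next
      pj <- N[r, j]; tj <- N[i, j]
      g <- .rat_gcd(abs(pj), abs(tj))
      f1 <- pj / g; f2 <- tj / g
      if (abs(f1) * max(abs(N[i, ])) > 2^49 || abs(f2) * max(abs(N[r, ])) > 2^49) {
        stop("rational overflow: intermediate integers exceeded 2^49; ",
             "use float mode for this computation")
      }
      row <- f1 * N[i, ] - f2 * N[r, ]
      g2 <- .row_gcd(row)
      if (g2 > 1) row <- row / g2
      N[i, ] <- row
    }
    pivots <- c(pivots, j)
    r <- r + 1L
  }
  num <- matrix(0, n, m)
  den <- matrix(1, n, m)
  for (i in seq_along(pivots)) {
    pv <- N[i, pivots[i]]
    num[i, ] <- N[i, ] * sign(pv)
    den[i, ] <- abs(pv)
  }
  list(r = rational(num, den), pivots = pivots)
}

.row_gcd <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  g <- v[1]
  for (x in v[-1]) {
    g <- .rat_gcd(g, x)
    if (g == 1) break
  }
  g
}

.rref_float <- function(a, tol = 1e-9) {
  if (is.null(dim(a))) dim(a) <- c(length(a), 1)
  n <- nrow(a)
  m <- ncol(a)
  pivots <- integer(0)
  if (n == 0 || m == 0) return(list(r = a, pivots = pivots))
  scale <- max(abs(a), 1)
  r <- 1L
  for (j in seq_len(m)) {
    if (r > n) break
    colvals <- a[r:n, j]
    i0 <- which.max(abs(colvals))
    if (abs(colvals[i0]) <= tol * scale) next
    piv <- r - 1L + i0
    if (piv != r) {
      tmp <- a[r, ]
      a[r, ] <- a[piv, ]
      a[piv, ] <- tmp
    }
    a[r, ] <- a[r, ] / a[r, j]
    for (i in seq_len(n)) {
      if (i != r && abs(a[i, j]) > 0) a[i, ] <- a[i, ] - a[i, j] * a[r, ]
    }
    a[abs(a) < tol * scale] <- 0
    pivots <- c(pivots, j)
    r <- r + 1L
  }
  list(r = a, pivots = pivots)
}

#' Matrix rank
#' @param a matrix (rational or numeric); vectors are treated as one column.
#' @param tol float-mode tolerance.
#' @return integer rank.
#' @export
mat_rank <- function(a, tol = 1e-9) {
  if (is.null(a)) return(0L)
  if (is.null(dim(a))) dim(a) <- c(length(a), 1)
  if (ncol(a) == 0 || nrow(a) == 0) return(0L)
  length(rref(a, tol)$pivots)
}

#' Null-space basis
#'
#' Columns of the result span \{x : a x = 0\}; a matrix with zero columns
#' means the null space is trivial.
#' @param a matrix (rational or numeric).
#' @param tol float-mode tolerance.
#' @return basis matrix with `ncol(a)` rows.
#' @export
null_space <- function(a, tol = 1e-9) {
  exact <- is_rational(a)
  if (is.null(dim(a))) dim(a) <- c(length(a), 1)
  m <- ncol(a)
  rr <- rref(a, tol)
  piv <- rr$pivots
  free <- setdiff(seq_len(m), piv)
  mk <- function(x) if (exact) as_rational(x) else x
  if (length(free) == 0) return(mk(matrix(0, m, 0)))
  basis <- matrix(0, m, length(free))
  if (exact) basis <- rational(basis)
  for (k in seq_along(free)) {
    f <- free[k]
    basis[f, k] <- 1
    if (length(piv)) {
      col <- if (exact) rr$r[seq_along(piv), f, drop = TRUE] else rr$r[seq_along(piv), f]
      basis[piv, k] <- -col
    }
  }
  basis
}

#' Particular solution of a x = b
#' @param a coefficient matrix; `b` right-hand side vector.
#' @param b right-hand side.
#' @param tol float-mode tolerance.
#' @return solution vector, or `NULL` when the system is inconsistent.
#' @export
solve_particular <- function(a, b, tol = 1e-9) {
  exact <- is_rational(a) || is_rational(b)
  if (exact) { a <- as_rational(a); b <- as_rational(b) }
  if (is.null(dim(a))) dim(a) <- c(length(a), 1)
  if (is.null(dim(b))) dim(b) <- c(length(b), 1)
  m <- ncol(a)
  aug <- r_cbind(a, b)
  rr <- rref(aug, tol)
  if ((m + 1) %in% rr$pivots) return(NULL)
  piv <- rr$pivots
  x <- if (exact) rational(numeric(m)) else numeric(m)
  if (length(piv)) {
    rhs <- if (exact) rr$r[seq_along(piv), m + 1, drop = TRUE] else rr$r[seq_along(piv), m + 1]
    x[piv] <- rhs
  }
  x
}

#' Linear subspaces of R^M
#'
#' A subspace is stored as an ambient dimension plus a basis matrix whose
#' columns are linearly independent (an empty basis is the zero subspace).
#' `column_space()` is the canonical constructor: it extracts the pivot
#' columns of its argument.
#'
#' @param basis matrix whose columns span the subspace (need not be
#'   independent), or `NULL` for the zero subspace.
#' @param ambient ambient dimension (inferred from `basis` when omitted).
#' @param tol float-mode tolerance.
#' @return an object of class `"zd_subspace"` with fields `ambient`, `basis`,
#'   `dim`, `exact`.
#' @export
subspace <- function(basis, ambient = NULL, tol = 1e-9) {
  if (is.null(basis)) {
    if (is.null(ambient)) stop("subspace(): ambient needed for the zero subspace")
    return(structure(list(ambient = ambient, basis = matrix(0, ambient, 0),
                          dim = 0L, exact = TRUE, tol = tol),
                     class = "zd_subspace"))
  }
  if (is.null(dim(basis))) dim(basis) <- c(length(basis), 1)
  if (is.null(ambient)) ambient <- nrow(basis)
  if (nrow(basis) != ambient) stop("subspace(): basis rows != ambient dimension")
  piv <- rref(basis, tol)$pivots
  basis <- basis[, piv, drop = FALSE]
  structure(list(ambient = ambient, basis = basis, dim = length(piv),
                 exact = is_rational(basis), tol = tol),
            class = "zd_subspace")
}

#' @rdname subspace
#' @param a matrix whose column space is wanted.
#' @export
column_space <- function(a, tol = 1e-9) subspace(a, tol = tol)

#' @export
print.zd_subspace <- function(x, ...) {
  cat(sprintf("<subspace of R^%d, dim %d, %s mode>\n", x$ambient, x$dim,
              if (x$exact) "exact" else "float"))
  invisible(x)
}

# coerce two objects to a common numeric mode
.common_mode <- function(a, b) {
  ra <- is_rational(a); rb <- is_rational(b)
  if (ra == rb) return(list(a = a, b = b, exact = ra))
  if (ra) a <- as.double(a) else b <- as.double(b)
  list(a = a, b = b, exact = FALSE)
}

#' Intersection of two subspaces
#'
#' Solves the stacked homogeneous system `[A | -B] x = 0` and maps the `A`
#' part back, so the result is exact in rational mode.  The dimension formula
#' lower bound `dim(a) + dim(b) - ambient` is asserted as an internal sanity
#' check.
#'
#' @param a,b subspaces of the same ambient space.
#' @return their intersection as a `"zd_subspace"`.
#' @export
subspace_intersect <- function(a, b) {
  stopifnot(inherits(a, "zd_subspace"), inherits(b, "zd_subspace"))
  if (a$ambient != b$ambient) stop("subspace_intersect(): ambient mismatch")
  tol <- min(a$tol, b$tol)
  if (a$dim == 0 || b$dim == 0) return(subspace(NULL, a$ambient, tol))
  cm <- .common_mode(a$basis, b$basis)
  stacked <- r_cbind(cm$a, if (cm$exact) rational(-1) * cm$b else -cm$b)
  ns <- null_space(stacked, tol)
  if (ncol(if (is_rational(ns)) ns$num else ns) == 0) {
    return(subspace(NULL, a$ambient, tol))
  }
  xa <- ns[seq_len(a$dim), , drop = FALSE]
  inter <- r_mmul(cm$a, xa)
  out <- subspace(inter, a$ambient, tol)
  lb <- a$dim + b$dim - a$ambient
  if (out$dim < lb) stop("subspace_intersect(): dimension formula violated")
  out
}

#' Membership test
#' @param s a `"zd_subspace"`.
#' @param v vector of length `s$ambient`.
#' @param tol float-mode tolerance override.
#' @return `TRUE` iff `v` lies in `s` (exactly in rational mode).
#' @export
subspace_contains <- function(s, v, tol = NULL) {
  stopifnot(inherits(s, "zd_subspace"))
  if (is.null(tol)) tol <- s$tol
  if (is.null(dim(v))) dim(v) <- c(length(v), 1)
  if (nrow(v) != s$ambient) stop("subspace_contains(): length mismatch")
  if (r_all_zero(v)) return(TRUE)
  if (s$dim == 0) return(FALSE)
  cm <- .common_mode(s$basis, v)
  mat_rank(r_cbind(cm$a, cm$b), tol) == s$dim
}

#' Rouche-Capelli consistency of an enforced-relation system
#'
#' The coefficient vectors `alpha_k = (alpha_0k, alpha_1k, ..., alpha_Nk)`
#' of K enforced linear payoff relations are split into the constant row
#' `b = (alpha_01, ..., alpha_0K)` and the coefficient block `a_bar`
#' (N x K).  The payoff vector `e = (1, e_1, ..., e_N)` must satisfy
#' `t(e_bar) %*% a_bar + t(b) = 0`, i.e. `t(a_bar) %*% e_bar = -b`.  The
#' system is consistent iff `rank(a_bar) == rank(rbind(b, a_bar))`, and the
#' full solution set is an affine subspace returned as a particular point
#' plus a null-space basis.
#'
#' @param a_bar N x K coefficient matrix (rows = players).
#' @param b length-K vector of constant coefficients.
#' @param tol float-mode tolerance.
#' @return list with `consistent`, `rank_coeff`, `rank_aug`, `particular`
#'   (length-N point or `NULL`), `nullspace` (N x d basis of the homogeneous
#'   solutions), `k` (number of relations).
#' @export
rouche_capelli <- function(a_bar, b, tol = 1e-9) {
  exact <- is_rational(a_bar) || is_rational(b)
  if (exact) { a_bar <- as_rational(a_bar); b <- as_rational(b) }
  if (is.null(dim(a_bar))) dim(a_bar) <- c(length(a_bar), 1)
  n <- nrow(a_bar)
  k <- ncol(a_bar)
  if (length(if (exact) b$num else b) != k) {
    stop("rouche_capelli(): length(b) must equal ncol(a_bar)")
  }
  if (k == 0) {
    id <- if (exact) rat_diag(n) else diag(n)
    zero <- if (exact) rational(numeric(n)) else numeric(n)
    return(list(consistent = TRUE, rank_coeff = 0L, rank_aug = 0L,
                particular = zero, nullspace = id, k = 0L))
  }
  bm <- b; if (is.null(dim(bm))) dim(bm) <- c(1, k)
  aug <- r_rbind(bm, a_bar)
  r1 <- mat_rank(a_bar, tol)
  r2 <- mat_rank(aug, tol)
  consistent <- r1 == r2
  particular <- NULL
  nullsp <- NULL
  if (consistent) {
    minus_b <- if (exact) rational(-1) * b else -b
    particular <- solve_particular(t(a_bar), minus_b, tol)
    nullsp <- null_space(t(a_bar), tol)
  }
  list(consistent = consistent, rank_coeff = r1, rank_aug = r2,
       particular = particular, nullspace = nullsp, k = k)
}
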