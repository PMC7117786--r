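#' @title Exact rational arithmetic
#'
#' @description
#' A minimal exact-rational number type used by the linear-algebra kernel.
#' Values are stored as reduced numerator/denominator pairs in double
#' precision; all intermediate integers are guarded against leaving the
#' exactly-representable range (< 2^50), so every arithmetic result is exact
#' or an error.  Vectors, matrices and arrays are supported through a shared
#' `dim` attribute, and the usual arithmetic and comparison operators are
#' overloaded.
#'
#' The package's theorem-level claims (subspace dimensions, rank equalities,
#' stationary-distribution identities) are statements of exact linear
#' algebra; this type lets the test suite assert them with `==` rather than
#' tolerances.
#'
#' @param num numeric array of integer-valued numerators.
#' @param den numeric array of integer-valued denominators (recycled).
#' @return an object of class `"rational"`.
#' @examples
#' a <- rational(1, 3) + rational(1, 6)   # exactly 1/2
#' format(a)
#' @export
rational <- function(num, den = 1) {
  if (is_rational(num)) return(num)
  if (!is.numeric(num) || !is.numeric(den)) {
    stop("rational() expects numeric numerators and denominators")
  }
  if (any(den == 0)) stop("rational(): zero denominator")
  if (any(num != round(num)) || any(den != round(den))) {
    stop("rational(): numerator and denominator must be integer-valued")
  }
  d <- dim(num)
  if (length(den) != length(num)) den <- rep_len(as.numeric(den), length(num))
  num <- as.numeric(num)
  den <- as.numeric(den)
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  .rat_guard(num, den)      # before gcd: 2^50+ operands already inexact
  g <- .rat_gcd(abs(num), den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  .rat_guard(num, den)
  if (!is.null(d)) {
    dim(num) <- d
    dim(den) <- d
  }
  structure(list(num = num, den = den), class = "rational")
}

#' Test for the rational class
#' @param x object.
#' @return logical scalar.
#' @export
is_rational <- function(x) inherits(x, "rational")

.RAT_MAX <- 2^50

.rat_guard <- function(num, den) {
  if (any(abs(num) > .RAT_MAX) || any(den > .RAT_MAX)) {
    stop("rational overflow: intermediate integers exceeded 2^50; ",
         "use float mode for this computation")
  }
  invisible(NULL)
}

# vectorized Euclid on non-negative integer-valued doubles
.rat_gcd <- function(a, b) {
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- t
  }
  a
}

#' Convert to rational, exactly
#'
#' Integers convert directly.  Fractional doubles are accepted only when they
#' are exactly representable with denominator at most `max_den` (found by
#' continued fractions and verified by an exact round-trip); otherwise an
#' error asks the caller to stay in float mode.  Character input accepts
#' `"p/q"` and plain integer strings.
#'
#' @param x numeric, character or rational.
#' @param max_den largest denominator tried for fractional doubles.
#' @return a `"rational"` object with the same dim as `x`.
#' @export
as_rational <- function(x, max_den = 1e6) {
  if (is_rational(x)) return(x)
  if (is.character(x)) {
    d <- dim(x)
    parts <- lapply(x, .rat_parse1)
    num <- vapply(parts, `[[`, numeric(1), 1L)
    den <- vapply(parts, `[[`, numeric(1), 2L)
    if (!is.null(d)) { dim(num) <- d; dim(den) <- d }
    return(rational(num, den))
  }
  if (!is.numeric(x)) stop("as_rational(): cannot convert ", class(x)[1])
  d <- dim(x)
  num <- numeric(length(x))
  den <- numeric(length(x))
  for (i in seq_along(x)) {
    nd <- .rat_from_double(x[i], max_den)
    num[i] <- nd[1]
    den[i] <- nd[2]
  }
  if (!is.null(d)) { dim(num) <- d; dim(den) <- d }
  rational(num, den)
}

.rat_parse1 <- function(s) {
  s <- trimws(s)
  if (grepl("/", s, fixed = TRUE)) {
    pq <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(pq) != 2) stop("cannot parse rational: '", s, "'")
    p <- suppressWarnings(as.numeric(pq[1]))
    q <- suppressWarnings(as.numeric(pq[2]))
  } else {
    p <- suppressWarnings(as.numeric(s))
    q <- 1
  }
  if (is.na(p) || is.na(q) || q == 0) stop("cannot parse rational: '", s, "'")
  if (p != round(p) || q != round(q)) return(.rat_from_double(p / q, 1e6))
  c(p, q)
}

.rat_from_double <- function(x, max_den) {
  if (!is.finite(x)) stop("as_rational(): non-finite value")
  if (x == round(x)) return(c(x, 1))
  # continued-fraction convergents
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  for (it in 1:64) {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    if (h / k == x) return(c(h, k))
    frac <- b - a
    if (frac == 0) break
    b <- 1 / frac
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
  }
  stop("as_rational(): ", format(x, digits = 17),
       " is not exactly representable with denominator <= ", max_den)
}

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rational")
  }
  a <- as_rational(e1)
  b <- as_rational(e2)
  d <- if (length(a$num) >= length(b$num)) dim(a$num) else dim(b$num)
  wrap <- function(num, den) {
    if (!is.null(d) && length(num) == prod(d)) { dim(num) <- d; dim(den) <- d }
    rational(num, den)
  }
  switch(.Generic,
    "+" = wrap(a$num * b$den + b$num * a$den, a$den * b$den),
    "-" = wrap(a$num * b$den - b$num * a$den, a$den * b$den),
    "*" = wrap(a$num * b$num, a$den * b$den),
    "/" = {
      if (any(rep_len(b$num, max(length(a$num), length(b$num))) == 0)) {
        stop("rational division by zero")
      }
      wrap(a$num * b$den, a$den * b$num)
    },
    "^" = {
      p <- b$num / b$den
      if (any(p != round(p))) stop("rational ^ requires integer exponent")
      neg <- p < 0
      num <- ifelse(neg, a$den, a$num)^abs(p)
      den <- ifelse(neg, a$num, a$den)^abs(p)
      wrap(num, den)
    },
    "==" = { .rat_guard(a$num * b$den, 1); a$num * b$den == b$num * a$den },
    "!=" = a$num * b$den != b$num * a$den,
    "<"  = a$num * b$den <  b$num * a$den,
    "<=" = a$num * b$den <= b$num * a$den,
    ">"  = a$num * b$den >  b$num * a$den,
    ">=" = a$num * b$den >= b$num * a$den,
    stop(.Generic, " not defined for rational")
  )
}

#' @export
dim.rational <- function(x) dim(x$num)

#' @export
`dim<-.rational` <- function(x, value) {
  dim(x$num) <- value
  dim(x$den) <- value
  x
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, ..., drop = TRUE) {
  structure(list(num = `[`(x$num, ..., drop = drop),
                 den = `[`(x$den, ..., drop = drop)),
            class = "rational")
}

#' @export
`[<-.rational` <- function(x, ..., value) {
  value <- as_rational(value)
  num <- x$num; den <- x$den
  num[...] <- value$num
  den[...] <- value$den
  structure(list(num = num, den = den), class = "rational")
}

#' @export
t.rational <- function(x) {
  structure(list(num = t(x$num), den = t(x$den)), class = "rational")
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  out <- ifelse(x$den == 1, format(x$num, trim = TRUE, scientific = FALSE),
                paste0(format(x$num, trim = TRUE, scientific = FALSE), "/",
                       format(x$den, trim = TRUE, scientific = FALSE)))
  dim(out) <- dim(x$num)
  out
}

#' @export
as.character.rational <- function(x, ...) {
  out <- format(x)
  dim(out) <- dim(x$num)
  out
}

#' @export
print.rational <- function(x, ...) {
  f <- format(x)
  if (is.null(dim(f))) print(unclass(f), quote = FALSE) else print(f, quote = FALSE)
  invisible(x)
}

#' Rational/numeric matrix product
#'
#' Exact when either argument is rational (the other is converted); plain
#' `%*%` otherwise.
#' @param a,b matrices (rational or numeric).
#' @return matrix of the common mode.
#' @export
r_mmul <- function(a, b) {
  if (!is_rational(a) && !is_rational(b)) return(a %*% b)
  a <- as_rational(a); b <- as_rational(b)
  if (is.null(dim(a))) dim(a) <- c(1, length(a))
  if (is.null(dim(b))) dim(b) <- c(length(b), 1)
  n <- nrow(a$num); k <- ncol(a$num); m <- ncol(b$num)
  if (nrow(b$num) != k) stop("non-conformable rational matrices")
  num <- matrix(0, n, m); den <- matrix(1, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- r_sum(a[i, , drop = TRUE] * b[, j, drop = TRUE])
      num[i, j] <- s$num; den[i, j] <- s$den
    }
  }
  rational(num, den)
}

#' Exact sum of a rational vector
#' @param x rational vector.
#' @return rational scalar.
#' @export
r_sum <- function(x) {
  x <- as_rational(x)
  sn <- 0; sd <- 1
  for (i in seq_along(x$num)) {
    g <- .rat_gcd(sd, x$den[i])
    nn <- sn * (x$den[i] / g) + x$num[i] * (sd / g)
    nd <- sd * (x$den[i] / g)
    g2 <- .rat_gcd(abs(nn), nd); if (g2 == 0) g2 <- 1
    sn <- nn / g2; sd <- nd / g2
    .rat_guard(sn, sd)
  }
  rational(sn, sd)
}

#' Column-bind matrices of mixed rational/numeric mode
#' @param ... rational or numeric matrices/vectors with matching row counts.
#' @return rational matrix if any argument is rational, else numeric matrix.
#' @export
r_cbind <- function(...) {
  args <- list(...)
  args <- args[!vapply(args, is.null, logical(1))]
  if (length(args) == 0) return(NULL)
  if (!any(vapply(args, is_rational, logical(1)))) return(do.call(cbind, args))
  args <- lapply(args, function(a) {
    a <- as_rational(a)
    if (is.null(dim(a))) dim(a) <- c(length(a), 1)
    a
  })
  structure(list(num = do.call(cbind, lapply(args, `[[`, "num")),
                 den = do.call(cbind, lapply(args, `[[`, "den"))),
            class = "rational")
}

#' Row-bind matrices of mixed rational/numeric mode
#' @param ... rational or numeric matrices/vectors with matching column counts.
#' @return rational matrix if any argument is rational, else numeric matrix.
#' @export
r_rbind <- function(...) {
  args <- list(...)
  args <- args[!vapply(args, is.null, logical(1))]
  if (length(args) == 0) return(NULL)
  if (!any(vapply(args, is_rational, logical(1)))) return(do.call(rbind, args))
  args <- lapply(args, function(a) {
    a <- as_rational(a)
    if (is.null(dim(a))) dim(a) <- c(1, length(a))
    a
  })
  structure(list(num = do.call(rbind, lapply(args, `[[`, "num")),
                 den = do.call(rbind, lapply(args, `[[`, "den"))),
            class = "rational")
}

#' Zero and identity rational matrices
#' @param nrow,ncol dimensions.
#' @return rational matrix.
#' @export
rat_zeros <- function(nrow, ncol = nrow) rational(matrix(0, nrow, ncol))

#' @rdname rat_zeros
#' @param n size.
#' @export
rat_diag <- function(n) rational(diag(n))

# all entries exactly zero?
r_all_zero <- function(x) {
  if (is_rational(x)) all(x$num == 0) else all(x == 0)
}
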