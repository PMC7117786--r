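#' @title Zero-determinant strategy detection
#'
#' @description
#' A memory-one strategy of player `n` is *zero-determinant* (ZD) when the
#' column space of its Press-Dyson matrix meets the span of the payoff-state
#' matrix `S = (1_M, s_1, ..., s_N)` nontrivially:
#' `V_n = span(PD_n) intersect span(S)`, and the strategy is ZD iff
#' `dim(V_n) >= 1`.  Every vector `u = S alpha` in `V_n` is annihilated by
#' every stationary distribution (Akin's lemma), so the long-run payoffs obey
#' `alpha_0 + sum_n alpha_n e_n = 0` regardless of what the co-players do.
#'
#' `compute_zd_subspace()` returns, per basis vector `u_k` of `V_n`, a
#' combination certificate `c_k` (with `PD_n c_k = u_k`) and a relation
#' certificate `alpha_k` (with `S alpha_k = u_k`; determined only up to
#' `null(S)` when `rank(S) < N + 1`, in which case the report is flagged
#' ambiguous and carries the ambiguity basis).
#'
#' @param strategy a `zd_strategy`.
#' @param game the owning `zd_game`.
#' @return an object of class `"zd_report"`.
#' @export
compute_zd_subspace <- function(strategy, game) {
  v <- validate_strategy(strategy, game)
  if (!v$ok) stop("invalid strategy: ", paste(v$problems$where, collapse = "; "))
  pd <- press_dyson(strategy, game)
  S <- payoff_matrix(game)
  cm <- .common_mode(pd$matrix, S)
  tspace <- column_space(cm$a)
  sspace <- column_space(cm$b)
  V <- subspace_intersect(tspace, sspace)
  certs <- list()
  if (V$dim > 0) {
    for (k in seq_len(V$dim)) {
      u <- if (is_rational(V$basis)) V$basis[, k, drop = TRUE] else V$basis[, k]
      certs[[k]] <- list(
        u = u,
        c = solve_particular(cm$a, u),
        alpha = solve_particular(cm$b, u)
      )
    }
  }
  rank_s <- sspace$dim
  structure(list(player = strategy$player, dim = V$dim, subspace = V,
                 basis = V$basis, certificates = certs,
                 alpha_nullspace = null_space(cm$b),
                 rank_s = rank_s, ambiguous = rank_s < game$n_players + 1,
                 is_zd = V$dim >= 1, press_dyson = pd,
                 exact = V$exact),
            class = "zd_report")
}

#' @export
print.zd_report <- function(x, ...) {
  cat(sprintf("<zd_report: player %d, dim V = %d (%s), rank S = %d%s, %s mode>\n",
              x$player, x$dim, if (x$is_zd) "ZD" else "not ZD", x$rank_s,
              if (x$ambiguous) " [relations ambiguous up to null(S)]" else "",
              if (x$exact) "exact" else "float"))
  invisible(x)
}

#' Linear payoff relations enforced by a ZD strategy
#'
#' One relation per basis vector of `V_n`, each a coefficient vector
#' `alpha = (alpha_0, alpha_1, ..., alpha_N)` meaning
#' `alpha_0 + sum_n alpha_n e_n = 0`, canonically scaled so the first
#' nonzero coefficient is `+1`.  When `rank(S) < N + 1` (e.g. zero-sum
#' games) each relation carries the ambiguity basis `null(S)`.
#'
#' @param report a `zd_report`.
#' @param game the owning `zd_game`.
#' @return list of `"linear_relation"` objects (empty when `dim = 0`).
#' @export
enforced_relations <- function(report, game) {
  if (report$dim == 0) return(list())
  lapply(report$certificates, function(ct) {
    alpha <- ct$alpha
    an <- if (is_rational(alpha)) alpha$num / alpha$den else alpha
    nz <- which(abs(an) > 1e-12)[1]
    if (!is.na(nz)) {
      alpha <- alpha / (if (is_rational(alpha)) alpha[nz, drop = TRUE] else alpha[nz])
    }
    structure(list(alpha = alpha, ambiguous = report$ambiguous,
                   ambiguity = report$alpha_nullspace),
              class = "linear_relation")
  })
}

#' @export
print.linear_relation <- function(x, ...) {
  a <- if (is_rational(x$alpha)) format(x$alpha) else format(x$alpha, digits = 6)
  terms <- character(0)
  for (i in seq_along(a)) {
    nm <- if (i == 1) "1" else paste0("e_", i - 1)
    terms <- c(terms, paste0("(", a[i], ")*", nm))
  }
  cat(paste(terms, collapse = " + "), "= 0",
      if (x$ambiguous) " [up to null(S)]" else "", "\n")
  invisible(x)
}

# common-mode pooled basis matrix from a list of zd_reports (NULL if empty)
.pooled_bases <- function(reports) {
  if (!length(reports)) return(NULL)
  exact <- all(vapply(reports, `[[`, logical(1), "exact"))
  bases <- lapply(reports, function(r) {
    b <- r$basis
    if (!exact && is_rational(b)) b <- as.double(b)
    b
  })
  do.call(r_cbind, bases)
}

#' Consistency of a set of ZD strategies (Rouche-Capelli)
#'
#' Builds a basis `u_1, ..., u_K` of the pooled enforced subspace
#' `span(V_n : n in N')`, writes each `u_k = S alpha_k`, stacks the
#' coefficient vectors into `A = rbind(b, A_bar)` and applies the
#' Rouche-Capelli rank test: the enforced relations admit a common payoff
#' vector iff `rank(A_bar) == rank(A)`.  The full solution set `E` (an
#' affine subspace of `(e_1, ..., e_N)`) is returned when consistent.
#'
#' @param reports list of `zd_report`s, all with `is_zd = TRUE`.
#' @param game the owning `zd_game`.
#' @return an object of class `"consistency_report"`.
#' @export
check_consistency <- function(reports, game) {
  for (r in reports) if (!r$is_zd) stop("player ", r$player, " is not ZD")
  N <- game$n_players
  pooled <- .pooled_bases(reports)
  if (is.null(pooled)) {
    rc <- rouche_capelli(matrix(0, N, 0), numeric(0))
    return(structure(list(a = NULL, a_bar = matrix(0, N, 0), b = numeric(0),
                          k = 0L, consistent = TRUE,
                          rank_coeff = 0L, rank_aug = 0L,
                          solution = list(particular = rc$particular,
                                          nullspace = rc$nullspace)),
                     class = "consistency_report"))
  }
  basis <- subspace(pooled)$basis
  exact <- is_rational(basis)
  S <- payoff_matrix(game)
  if (!exact && is_rational(S)) S <- as.double(S)
  if (exact && !is_rational(S)) { basis <- as.double(basis); exact <- FALSE }
  K <- ncol(if (exact) basis$num else basis)
  alphas <- lapply(seq_len(K), function(k) {
    u <- if (exact) basis[, k, drop = TRUE] else basis[, k]
    a <- solve_particular(S, u)
    if (is.null(a)) stop("internal: basis vector of pooled V not in span(S)")
    a
  })
  A <- do.call(r_cbind, alphas)
  b <- if (exact) A[1, , drop = TRUE] else A[1, ]
  a_bar <- A[-1, , drop = FALSE]
  rc <- rouche_capelli(a_bar, b)
  structure(list(a = A, a_bar = a_bar, b = b, k = K,
                 consistent = rc$consistent,
                 rank_coeff = rc$rank_coeff, rank_aug = rc$rank_aug,
                 solution = list(particular = rc$particular,
                                 nullspace = rc$nullspace)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report: K = %d relations, rank(A_bar) = %d, rank(A) = %d -> %s>\n",
              x$k, x$rank_coeff, x$rank_aug,
              if (x$consistent) "consistent" else "INCONSISTENT"))
  if (x$consistent && !is.null(x$solution$particular)) {
    ns <- x$solution$nullspace
    d <- ncol(if (is_rational(ns)) ns$num else ns)
    cat(sprintf("  solution set E: affine subspace of dimension %d in payoff space\n", d))
  }
  invisible(x)
}

#' Independence of a set of ZD strategies
#'
#' The set is independent when no selection of one nonzero vector per
#' enforced subspace `V_n` is linearly dependent; operationally, for every
#' `n`, `V_n intersect span(union of the other V_m) = {0}`.  On dependence a
#' witness selection is returned.  The result also reports whether the
#' sufficient no-zero-entries hypothesis (every Press-Dyson column of every
#' involved strategy has no zero elements) holds.
#'
#' @param reports list of `zd_report`s, all ZD.
#' @param game the owning `zd_game`.
#' @return list with `independent`, `witness` (named list of vectors on
#'   dependence, else `NULL`), `hypothesis_no_zeros`.
#' @export
check_independence <- function(reports, game) {
  for (r in reports) if (!r$is_zd) stop("player ", r$player, " is not ZD")
  hyp <- all(!vapply(reports, function(r) r$press_dyson$has_zero_elements,
                     logical(1)))
  if (length(reports) <= 1) {
    return(list(independent = TRUE, witness = NULL, hypothesis_no_zeros = hyp))
  }
  exact <- all(vapply(reports, `[[`, logical(1), "exact"))
  getb <- function(r) {
    b <- r$basis
    if (!exact && is_rational(b)) b <- as.double(b)
    b
  }
  for (i in seq_along(reports)) {
    vi <- subspace(getb(reports[[i]]))
    others <- reports[-i]
    pooled <- subspace(.pooled_bases(others))
    inter <- subspace_intersect(vi, pooled)
    if (inter$dim > 0) {
      v <- if (is_rational(inter$basis)) inter$basis[, 1, drop = TRUE] else inter$basis[, 1]
      coef <- solve_particular(pooled$basis, v)
      witness <- list()
      witness[[paste0("player_", reports[[i]]$player)]] <- v
      offset <- 0L
      for (o in others) {
        d <- o$dim
        ob <- getb(o)
        ck <- if (is_rational(coef)) coef[offset + seq_len(d), drop = TRUE] else coef[offset + seq_len(d)]
        w <- r_mmul(ob, if (is.null(dim(ck))) {
          if (is_rational(ck)) { dim(ck) <- c(length(ck), 1); ck } else matrix(ck, ncol = 1)
        } else ck)
        wv <- if (is_rational(w)) w[, 1, drop = TRUE] else w[, 1]
        if (r_all_zero(wv)) wv <- if (is_rational(ob)) ob[, 1, drop = TRUE] else ob[, 1]
        witness[[paste0("player_", o$player)]] <- wv
        offset <- offset + d
      }
      return(list(independent = FALSE, witness = witness,
                  hypothesis_no_zeros = hyp))
    }
  }
  list(independent = TRUE, witness = NULL, hypothesis_no_zeros = hyp)
}

#' Player symmetries of a game
#'
#' Enumerates all permutations `pi` of the players with matching action
#' counts that preserve the payoff structure,
#' `s_{pi(n)}(sigma) = s_n(sigma_pi)` for all joint actions `sigma`, where
#' `sigma_pi = (sigma_{pi(1)}, ..., sigma_{pi(N)})`.  The game is weakly
#' symmetric when every ordered pair of players is connected by some
#' payoff-preserving permutation.
#'
#' @param game a `zd_game`.
#' @param max_players refuse enumeration beyond this player count
#'   (factorially many permutations).
#' @return list with `symmetric_permutations` (list of integer vectors,
#'   always containing the identity), `weakly_symmetric`.
#' @export
check_symmetry <- function(game, max_players = 6) {
  N <- game$n_players
  if (N > max_players) {
    stop("check_symmetry(): ", N, " players means ", factorial(N),
         " permutations; raise max_players explicitly if you mean it")
  }
  perms <- .permutations(N)
  states <- all_states(game)
  m <- game$m
  sidx <- function(tuple) state_index(tuple, game) + 1L
  pay <- lapply(game$payoffs, function(p) if (is_rational(p)) p$num / p$den else p)
  keep <- list()
  for (p in perms) {
    if (!all(game$action_counts == game$action_counts[p])) next
    ok <- TRUE
    for (j in seq_len(m)) {
      tup <- states[j, ]
      jp <- sidx(tup[p])
      for (n in seq_len(N)) {
        if (abs(pay[[p[n]]][j] - pay[[n]][jp]) > 1e-12) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) keep[[length(keep) + 1]] <- p
  }
  weakly <- TRUE
  for (n in seq_len(N)) {
    for (nb in seq_len(N)) {
      if (!any(vapply(keep, function(p) p[n] == nb, logical(1)))) {
        weakly <- FALSE
      }
    }
  }
  list(symmetric_permutations = keep, weakly_symmetric = weakly)
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .permutations(n - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  lapply(out, as.integer)
}

#' The simultaneous two-relation construction
#'
#' Builds the 3x3 symmetric game with `s_1 = (0, r1, 0, r2, 0, ..., 0)`,
#' `s_2 = (0, r2, 0, r1, 0, ..., 0)` and the three-column memory-one
#' strategy of player 1
#' `T_1(1) = (1, 1-p, 1, p', 0, 0, 0, 0, 0)`,
#' `T_1(2) = (0, q, 0, 1-q', 1, 1, 0, 0, 0)`,
#' `T_1(3) = (0, p-q, 0, q'-p', 0, 0, 1, 1, 1)`,
#' valid for `0 <= p, q, p', q' <= 1`, `q <= p`, `p' <= q'`.  When
#' `p'q - pq' != 0` the two Press-Dyson vectors combine to the payoff
#' vectors themselves:
#' `((q'r1 + q r2) T~_1(1) + (p'r1 + p r2) T~_1(2)) / (p'q - pq') = s_1`
#' and the mirrored combination gives `s_2`, so player 1 alone pins
#' `e_1 = e_2 = 0`.  Both identities and `dim V_1 = 2` are re-verified in
#' exact arithmetic before returning.
#'
#' @param r1,r2 payoff parameters (need `r1 != r2`, `r1 != -r2` for two
#'   independent relations).
#' @param p,q,p_prime,q_prime strategy parameters as above.
#' @return list with `game`, `strategy`, `report` (the `zd_report`),
#'   `coefficients` (exact combination coefficients for `s_1` and `s_2`).
#' @export
build_double_control <- function(r1 = 1, r2 = 2, p = 1/2, q = 1/4,
                                 p_prime = 1/4, q_prime = 1/2) {
  qp <- lapply(list(p = p, q = q, p_prime = p_prime, q_prime = q_prime),
               function(x) as_rational(.maybe_exact(x)))
  for (nm in names(qp)) {
    if (qp[[nm]] < 0 || qp[[nm]] > 1) {
      stop("parameter constraint violated: 0 <= ", nm, " <= 1")
    }
  }
  if (qp$q > qp$p) stop("parameter constraint violated: q <= p")
  if (qp$p_prime > qp$q_prime) stop("parameter constraint violated: p' <= q'")
  den <- qp$p_prime * qp$q - qp$p * qp$q_prime
  if (den == 0) stop("degenerate parameters: p'q - pq' = 0")
  r1 <- as_rational(.maybe_exact(r1)); r2 <- as_rational(.maybe_exact(r2))
  game <- fixture_game("two_relation_game", r1 = r1, r2 = r2)
  one <- rational(1); zero <- rational(0)
  col1 <- r_cbind(one, one - qp$p, one, qp$p_prime, zero, zero, zero, zero, zero)
  col2 <- r_cbind(zero, qp$q, zero, one - qp$q_prime, one, one, zero, zero, zero)
  col3 <- r_cbind(zero, qp$p - qp$q, zero, qp$q_prime - qp$p_prime,
                  zero, zero, one, one, one)
  cols <- r_rbind(col1, col2, col3)          # 3 x 9: row = action
  strategy <- strategy_from_columns(game, 1, cols)
  pd <- press_dyson(strategy, game)
  a1 <- (qp$q_prime * r1 + qp$q * r2) / den
  b1 <- (qp$p_prime * r1 + qp$p * r2) / den
  a2 <- (qp$q_prime * r2 + qp$q * r1) / den
  b2 <- (qp$p_prime * r2 + qp$p * r1) / den
  t1 <- pd$matrix[, 1, drop = TRUE]
  t2 <- pd$matrix[, 2, drop = TRUE]
  if (!all(a1 * t1 + b1 * t2 == game$payoffs[[1]]) ||
      !all(a2 * t1 + b2 * t2 == game$payoffs[[2]])) {
    stop("internal: printed combination identities failed exact verification")
  }
  report <- compute_zd_subspace(strategy, game)
  if (!isTRUE(game$degenerate) && report$dim != 2) {
    stop("internal: expected dim V_1 = 2, got ", report$dim)
  }
  list(game = game, strategy = strategy, report = report,
       coefficients = list(s1 = r_cbind(a1, b1), s2 = r_cbind(a2, b2)))
}
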