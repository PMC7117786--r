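#' @title Memory-one strategies and Press-Dyson matrices
#'
#' @description
#' Under public monitoring a memory-one strategy of player `n` is a table
#' `That_n(sigma_n | sigma'_n, tau)`: the probability of playing `sigma_n`
#' next, given the player's own previous action `sigma'_n` and the public
#' signal `tau`.  The table is stored as a 3-d array indexed
#' `[next action, previous action, signal]`; every `(previous, signal)` slice
#' is a probability distribution over the next action.
#'
#' Three derived objects drive all ZD analyses:
#' * the *marginal transition* `T_n(sigma_n | sigma') =
#'   sum_tau W(tau | sigma') That_n(sigma_n | sigma'_n, tau)`;
#' * the *Press-Dyson vectors* `Ttilde_n(sigma_n | sigma') =
#'   T_n(sigma_n | sigma') - delta(sigma_n, sigma'_n)` (marginal minus the
#'   "Repeat" indicator);
#' * the `M x M_n` *Press-Dyson matrix* whose columns are those vectors.
#'
#' Rows of the Press-Dyson matrix sum to zero, entries lie in `[-1, 1]`, and
#' the entry at `(sigma', sigma_n)` is `<= 0` when `sigma'_n = sigma_n` and
#' `>= 0` otherwise.  Akin's lemma states that every stationary distribution
#' of the induced chain annihilates every column.
#'
#' @param player 1-based player index.
#' @param table `M_n x M_n x |B|` array (rational or numeric).
#' @param game the `zd_game` the strategy belongs to.
#' @return an object of class `"zd_strategy"`.
#' @export
memory_one_strategy <- function(player, table, game) {
  stopifnot(inherits(game, "zd_game"))
  if (player < 1 || player > game$n_players) stop("no player ", player)
  mn <- game$action_counts[player]
  nb <- length(game$signals)
  table <- .maybe_exact(table)
  d <- dim(if (is_rational(table)) table$num else table)
  if (is.null(d) || length(d) != 3 || !all(d == c(mn, mn, nb))) {
    stop("strategy table must be ", mn, " x ", mn, " x ", nb,
         " (next action x previous action x signal)")
  }
  structure(list(player = as.integer(player), table = table,
                 exact = is_rational(table)),
            class = "zd_strategy")
}

#' @export
print.zd_strategy <- function(x, ...) {
  d <- dim(if (is_rational(x$table)) x$table$num else x$table)
  cat(sprintf("<memory-one strategy of player %d: %d actions, %d signals, %s mode>\n",
              x$player, d[1], d[3], if (x$exact) "exact" else "float"))
  invisible(x)
}

#' Validate a memory-one strategy against its game
#'
#' Report-style: never throws for content problems; returns a pass/fail per
#' invariant (entries in `[0, 1]`; each `(previous action, signal)` slice sums
#' to one) with the first offending index.
#' @param strategy a `zd_strategy`.
#' @param game the owning `zd_game`.
#' @return list with `ok` and a data frame `problems`.
#' @export
validate_strategy <- function(strategy, game) {
  tab <- strategy$table
  exact <- is_rational(tab)
  num <- if (exact) tab$num / tab$den else tab
  probs <- data.frame(check = character(0), where = character(0))
  bad <- which(num < -1e-12 | num > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad)) {
    probs <- rbind(probs, data.frame(
      check = "range",
      where = sprintf("entry (next=%d, prev=%d, signal=%d)",
                      bad[1, 1], bad[1, 2], bad[1, 3])))
  }
  mn <- dim(num)[1]; nb <- dim(num)[3]
  for (sp in seq_len(mn)) {
    for (b in seq_len(nb)) {
      s <- if (exact) r_sum(tab[, sp, b, drop = TRUE]) else sum(num[, sp, b])
      ok <- if (exact) s == 1 else abs(s - 1) < 1e-9
      if (!ok) {
        probs <- rbind(probs, data.frame(
          check = "row_sum",
          where = sprintf("prev=%d, signal=%d sums to %s", sp, b,
                          if (exact) format(s) else format(s, digits = 12))))
      }
    }
  }
  list(ok = nrow(probs) == 0, problems = probs)
}

#' Marginal transition probabilities T_n(sigma_n | sigma')
#'
#' W-weighted mixture of the per-signal strategy rows; under perfect
#' monitoring this is just the table re-indexed by the full previous state.
#' @param strategy a `zd_strategy`.
#' @param game the owning `zd_game`.
#' @return `M_n x M` column-stochastic matrix (rational when both the game
#'   and the strategy are exact).
#' @export
marginal_transition <- function(strategy, game) {
  n <- strategy$player
  mn <- game$action_counts[n]
  states <- all_states(game)
  exact <- strategy$exact && game$exact
  tab <- if (exact) strategy$table else {
    t0 <- strategy$table
    if (is_rational(t0)) t0$num / t0$den else t0
  }
  W <- if (exact) game$W else { if (is_rational(game$W)) game$W$num / game$W$den else game$W }
  out <- if (exact) rat_zeros(mn, game$m) else matrix(0, mn, game$m)
  for (j in seq_len(game$m)) {
    sp <- states[j, n]
    slice <- tab[, sp, , drop = FALSE]
    dim(slice) <- c(mn, length(game$signals))
    col <- r_mmul(slice, W[, j, drop = FALSE])
    out[, j] <- if (exact) col[, 1, drop = TRUE] else col[, 1]
  }
  out
}

#' Press-Dyson matrix of a strategy
#'
#' @param strategy a `zd_strategy`.
#' @param game the owning `zd_game`.
#' @return an object of class `"press_dyson"`: list with `matrix`
#'   (`M x M_n`, column `sigma_n` is the Press-Dyson vector of that action),
#'   `player`, `has_zero_elements`, `exact`.
#' @export
press_dyson <- function(strategy, game) {
  n <- strategy$player
  mn <- game$action_counts[n]
  states <- all_states(game)
  marg <- marginal_transition(strategy, game)
  exact <- is_rational(marg)
  pd <- t(marg)
  for (j in seq_len(game$m)) {
    sp <- states[j, n]
    pd[j, sp] <- (if (exact) pd[j, sp, drop = TRUE] else pd[j, sp]) - 1
  }
  numpd <- if (exact) pd$num else pd
  structure(list(matrix = pd, player = n,
                 has_zero_elements = any(numpd == 0),
                 exact = exact),
            class = "press_dyson")
}

#' @export
print.press_dyson <- function(x, ...) {
  d <- dim(if (is_rational(x$matrix)) x$matrix$num else x$matrix)
  cat(sprintf("<Press-Dyson matrix of player %d: %d x %d, %s mode, %s zero elements>\n",
              x$player, d[1], d[2], if (x$exact) "exact" else "float",
              if (x$has_zero_elements) "has" else "no"))
  invisible(x)
}

#' Shorthand strategies
#'
#' `strategy_repeat()` repeats the previous own action; its Press-Dyson
#' matrix is identically zero.  `strategy_uniform()` plays every action with
#' equal probability regardless of history.  `strategy_tit_for_tat()` copies
#' the co-player's previous action (2-player perfect monitoring with equal
#' action counts only).
#' @param game a `zd_game`.
#' @param player player index.
#' @return a `zd_strategy`.
#' @export
strategy_repeat <- function(game, player) {
  mn <- game$action_counts[player]
  nb <- length(game$signals)
  tab <- array(0, c(mn, mn, nb))
  for (sp in seq_len(mn)) tab[sp, sp, ] <- 1
  memory_one_strategy(player, as_rational(tab), game)
}

#' @rdname strategy_repeat
#' @export
strategy_uniform <- function(game, player) {
  mn <- game$action_counts[player]
  nb <- length(game$signals)
  tab <- rational(array(1, c(mn, mn, nb)), array(mn, c(mn, mn, nb)))
  memory_one_strategy(player, tab, game)
}

#' @rdname strategy_repeat
#' @export
strategy_tit_for_tat <- function(game, player) {
  if (!game$perfect || game$n_players != 2) {
    stop("tit-for-tat is defined here for 2-player perfect-monitoring games")
  }
  if (length(unique(game$action_counts)) != 1) {
    stop("tit-for-tat needs equal action counts")
  }
  other <- 3 - player
  mn <- game$action_counts[player]
  states <- all_states(game)
  tab <- array(0, c(mn, mn, game$m))
  for (j in seq_len(game$m)) {
    tab[states[j, other], , j] <- 1
  }
  memory_one_strategy(player, as_rational(tab), game)
}

#' Build a perfect-monitoring strategy from full-state columns
#'
#' Takes the matrix `T_n(sigma_n | sigma')` directly (one column per previous
#' joint action) and lifts it to a memory-one table; only meaningful under
#' perfect monitoring, where the signal identifies the previous state.
#' @param game a perfect-monitoring `zd_game`.
#' @param player player index.
#' @param cols `M_n x M` column-stochastic matrix.
#' @return a `zd_strategy` whose [marginal_transition()] equals `cols`.
#' @export
strategy_from_columns <- function(game, player, cols) {
  if (!game$perfect) stop("strategy_from_columns() requires perfect monitoring")
  cols <- .maybe_exact(cols)
  mn <- game$action_counts[player]
  exact <- is_rational(cols)
  tab <- array(0, c(mn, mn, game$m))
  if (exact) tab <- as_rational(tab)
  for (j in seq_len(game$m)) {
    for (sp in seq_len(mn)) {
      tab[, sp, j] <- if (exact) cols[, j, drop = TRUE] else cols[, j]
    }
  }
  st <- memory_one_strategy(player, tab, game)
  v <- validate_strategy(st, game)
  if (!v$ok) stop("strategy_from_columns(): invalid columns: ",
                  paste(v$problems$where, collapse = "; "))
  st
}

#' Random valid memory-one strategy
#'
#' Each `(previous action, signal)` row is drawn uniformly from the simplex
#' (via normalized exponentials) using the current RNG state.  With
#' `eps > 0` entries are bounded away from 0 by mixing with the uniform
#' distribution, producing strategies whose Press-Dyson vectors have no zero
#' elements (the independence proposition's hypothesis).  With
#' `rationalize = D` rows are rounded to exact rationals with denominator
#' `D` (renormalized exactly), so downstream linear algebra stays exact.
#'
#' @param game a `zd_game`.
#' @param player player index.
#' @param eps lower bound on entries (default 0; the hypothesis regime uses
#'   0.05).
#' @param rationalize denominator for exact rounding, or `NULL` to keep
#'   float.
#' @return a `zd_strategy`.
#' @export
random_strategy <- function(game, player, eps = 0, rationalize = 16) {
  mn <- game$action_counts[player]
  nb <- length(game$signals)
  if (!is.null(rationalize) && eps > 0 && floor(rationalize * eps) < 1) {
    stop("rationalize * eps must be >= 1 to keep entries positive")
  }
  if (is.null(rationalize)) {
    tab <- array(0, c(mn, mn, nb))
    for (sp in seq_len(mn)) for (b in seq_len(nb)) {
      p <- stats::rexp(mn)
      p <- p / sum(p)
      tab[, sp, b] <- eps + (1 - mn * eps) * p
    }
    return(memory_one_strategy(player, tab, game))
  }
  D <- as.integer(rationalize)
  base <- if (eps > 0) floor(D * eps) else 0
  num <- array(0, c(mn, mn, nb))
  for (sp in seq_len(mn)) for (b in seq_len(nb)) {
    p <- stats::rexp(mn)
    p <- p / sum(p)
    free <- D - mn * base
    n_i <- floor(p * free)
    rem <- free - sum(n_i)
    if (rem > 0) {
      ord <- order(p * free - n_i, decreasing = TRUE)
      n_i[ord[seq_len(rem)]] <- n_i[ord[seq_len(rem)]] + 1
    }
    num[, sp, b] <- base + n_i
  }
  memory_one_strategy(player, rational(num, array(D, dim(num))), game)
}

#' Realize a target marginal transition under a signal kernel
#'
#' Decides by linear programming whether some memory-one table
#' `That_n(sigma_n | sigma'_n, tau)` has W-marginal equal to `target`, and
#' returns one if so.  Under perfect monitoring any column-stochastic target
#' is realizable; an uninformative kernel forces the marginal to depend on
#' the previous state only through the player's own action, so most targets
#' are infeasible.
#'
#' The LP is solved in floating point; when the inputs are rational the
#' solution is rounded back to rationals and re-verified exactly
#' (`exact_verified` in the result).
#'
#' @param target `M_n x M` column-stochastic matrix.
#' @param game a `zd_game`.
#' @param player player index.
#' @return list with `feasible`, `strategy` (or `NULL`), `status` (LP
#'   certificate status) and `exact_verified`.
#' @export
realize_marginal <- function(target, game, player) {
  mn <- game$action_counts[player]
  nb <- length(game$signals)
  target <- .maybe_exact(target)
  tnum <- if (is_rational(target)) target$num / target$den else target
  if (!all(dim(tnum) == c(mn, game$m))) stop("target must be M_n x M")
  if (any(abs(colSums(tnum) - 1) > 1e-9)) stop("target must be column-stochastic")
  states <- all_states(game)
  W <- if (is_rational(game$W)) game$W$num / game$W$den else game$W
  # variables x[(next, prev, signal)] in column-major array order
  nx <- mn * mn * nb
  vid <- function(a, sp, b) a + mn * (sp - 1) + mn * mn * (b - 1)
  rows_eq <- list(); rhs_eq <- numeric(0)
  for (j in seq_len(game$m)) {
    sp <- states[j, player]
    for (a in seq_len(mn)) {
      r <- numeric(nx)
      for (b in seq_len(nb)) r[vid(a, sp, b)] <- r[vid(a, sp, b)] + W[b, j]
      rows_eq[[length(rows_eq) + 1]] <- r
      rhs_eq <- c(rhs_eq, tnum[a, j])
    }
  }
  for (sp in seq_len(mn)) for (b in seq_len(nb)) {
    r <- numeric(nx)
    r[vid(seq_len(mn), sp, b)] <- 1
    rows_eq[[length(rows_eq) + 1]] <- r
    rhs_eq <- c(rhs_eq, 1)
  }
  a_eq <- do.call(rbind, rows_eq)
  a_le <- -diag(nx)                     # x >= 0
  res <- lp_solve(a_eq = a_eq, b_eq = rhs_eq, a_le = a_le, b_le = numeric(nx))
  if (res$status != "optimal") {
    return(list(feasible = FALSE, strategy = NULL, status = res$status,
                exact_verified = FALSE))
  }
  x <- pmin(pmax(res$x, 0), 1)
  tab <- array(x, c(mn, mn, nb))
  exact_ok <- FALSE
  strat <- NULL
  if (is_rational(target) && game$exact) {
    qtab <- tryCatch(.rationalize_array(tab, 1e6), error = function(e) NULL)
    if (!is.null(qtab)) {
      cand <- tryCatch(memory_one_strategy(player, qtab, game),
                       error = function(e) NULL)
      if (!is.null(cand) && validate_strategy(cand, game)$ok) {
        marg <- marginal_transition(cand, game)
        if (is_rational(marg) && all((marg == target))) {
          strat <- cand
          exact_ok <- TRUE
        }
      }
    }
  }
  if (is.null(strat)) {
    # renormalize rows to machine precision
    for (sp in seq_len(mn)) for (b in seq_len(nb)) {
      tab[, sp, b] <- tab[, sp, b] / sum(tab[, sp, b])
    }
    strat <- memory_one_strategy(player, tab, game)
  }
  list(feasible = TRUE, strategy = strat, status = "optimal",
       exact_verified = exact_ok)
}

.rationalize_array <- function(x, max_den) {
  d <- dim(x)
  num <- numeric(length(x)); den <- numeric(length(x))
  for (i in seq_along(x)) {
    # snap near-integers, else continued-fraction best approximation
    xi <- x[i]
    if (abs(xi - round(xi)) < 1e-9) {
      num[i] <- round(xi); den[i] <- 1
    } else {
      nd <- .rat_best_approx(xi, max_den)
      num[i] <- nd[1]; den[i] <- nd[2]
    }
  }
  dim(num) <- d; dim(den) <- d
  rational(num, den)
}

# best rational approximation with denominator <= max_den (continued fractions)
.rat_best_approx <- function(x, max_den) {
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  for (it in 1:64) {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) return(c(h1, max(k1, 1)))
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(h / k - x) < 1e-13) return(c(h, k))
    frac <- b - a
    if (frac < 1e-13) return(c(h, k))
    b <- 1 / frac
  }
  c(h1, max(k1, 1))
}
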