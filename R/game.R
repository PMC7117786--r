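#' @title Repeated-game instances with public monitoring
#'
#' @description
#' A `zd_game` describes one stage game played repeatedly: `N` players,
#' player `n` choosing among `M_n` actions, a payoff vector `s_n` over the
#' joint-action space `Sigma` (size `M = prod(M_n)`), and a public-monitoring
#' structure: a finite signal set `B` and a signal kernel `W(tau | sigma')`
#' giving the probability that signal `tau` is publicly observed after joint
#' action `sigma'`.  Perfect monitoring is the special case `B = Sigma`,
#' `W(tau | sigma') = 1` iff `tau = sigma'`.
#'
#' Joint actions are ordered lexicographically with player 1 most significant
#' and player N fastest-varying; flat indices are 0-based.  Payoffs supplied
#' as integers, exactly-representable decimals or `"p/q"` strings are kept as
#' exact rationals end-to-end.
#'
#' @param action_counts integer vector `(M_1, ..., M_N)`, each `>= 2`.
#' @param payoffs list of N payoff vectors of length `M` (numeric, `"p/q"`
#'   character, or rational).
#' @param signals character vector of signal labels, or `NULL` for perfect
#'   monitoring.
#' @param W `|B| x M` signal kernel (column `sigma'` is the distribution of
#'   the public signal), or `"perfect"` / `NULL` for perfect monitoring.
#' @return an object of class `"zd_game"`.
#' @export
zd_game <- function(action_counts, payoffs, signals = NULL, W = "perfect") {
  action_counts <- as.integer(action_counts)
  if (any(action_counts < 2)) stop("each player needs at least 2 actions")
  n_players <- length(action_counts)
  m <- prod(action_counts)
  if (!is.list(payoffs) || length(payoffs) != n_players) {
    stop("payoffs must be a list with one vector per player")
  }
  payoffs <- lapply(seq_along(payoffs), function(n) {
    p <- .maybe_exact(payoffs[[n]])
    if (length(if (is_rational(p)) p$num else p) != m) {
      stop("payoff vector of player ", n, " must have length M = ", m)
    }
    p
  })
  perfect <- is.null(signals) || (is.character(W) && identical(W, "perfect"))
  if (perfect) {
    signals <- state_labels(action_counts)
    W <- rat_diag(m)
  } else {
    W <- .maybe_exact(W)
    if (is.null(dim(W))) dim(W) <- c(length(signals), m)
    wn <- if (is_rational(W)) W$num else W
    if (nrow(wn) != length(signals) || ncol(wn) != m) {
      stop("W must be |B| x M = ", length(signals), " x ", m)
    }
  }
  g <- structure(list(n_players = n_players, action_counts = action_counts,
                      m = m, payoffs = payoffs, signals = signals, W = W,
                      perfect = perfect,
                      exact = all(vapply(payoffs, is_rational, logical(1))) &&
                              is_rational(W)),
                 class = "zd_game")
  .validate_game(g)
  g
}

# promote to rationals when exactly representable, else keep numeric
.maybe_exact <- function(x) {
  if (is_rational(x)) return(x)
  if (is.character(x)) return(as_rational(x))
  out <- tryCatch(as_rational(x), error = function(e) NULL)
  if (is.null(out)) x else out
}

.validate_game <- function(g) {
  w <- g$W
  if (is_rational(w)) {
    if (any(w$num < 0) || any(w$num / w$den > 1)) stop("W entries must lie in [0,1]")
    for (j in seq_len(g$m)) {
      if (!(r_sum(w[, j, drop = TRUE]) == 1)) {
        stop("W column ", j, " (state ", state_labels(g$action_counts)[j],
             ") does not sum to 1")
      }
    }
  } else {
    if (any(w < -1e-12) || any(w > 1 + 1e-12)) stop("W entries must lie in [0,1]")
    cs <- colSums(w)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad)) stop("W column ", bad[1], " sums to ", cs[bad[1]], ", not 1")
  }
  invisible(TRUE)
}

#' Human-readable labels "(a1,...,aN)" for all joint actions in flat order
#' @param action_counts integer vector of per-player action counts.
#' @return character vector of length `prod(action_counts)`.
#' @export
state_labels <- function(action_counts) {
  apply(all_states(action_counts), 1, function(s) {
    paste0("(", paste(s, collapse = ","), ")")
  })
}

#' All joint actions in flat-index order
#'
#' Row `i` is the action tuple with flat index `i - 1`.  Player 1 is the most
#' significant digit; player N varies fastest.
#' @param action_counts integer vector, or a `zd_game`.
#' @return `M x N` integer matrix of 1-based actions.
#' @export
all_states <- function(action_counts) {
  if (inherits(action_counts, "zd_game")) action_counts <- action_counts$action_counts
  n <- length(action_counts)
  grids <- lapply(action_counts, seq_len)
  # expand.grid varies the first factor fastest; we want the last
  g <- do.call(expand.grid, rev(grids))[, n:1, drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- NULL
  m
}

#' Flat state index of a joint action
#'
#' @param sigma integer action tuple `(sigma_1, ..., sigma_N)`, 1-based.
#' @param game a `zd_game` (or integer action-count vector).
#' @return 0-based flat index in `0:(M-1)`.
#' @seealso [index_to_state()]
#' @export
state_index <- function(sigma, game) {
  counts <- if (inherits(game, "zd_game")) game$action_counts else as.integer(game)
  if (length(sigma) != length(counts)) {
    stop("action tuple has length ", length(sigma), ", expected ", length(counts))
  }
  idx <- 0
  for (n in seq_along(counts)) {
    if (sigma[n] < 1 || sigma[n] > counts[n] || sigma[n] != round(sigma[n])) {
      stop("action ", sigma[n], " of player ", n, " is outside 1..", counts[n])
    }
    idx <- idx * counts[n] + (sigma[n] - 1)
  }
  as.integer(idx)
}

#' @rdname state_index
#' @param index 0-based flat index.
#' @export
index_to_state <- function(index, game) {
  counts <- if (inherits(game, "zd_game")) game$action_counts else as.integer(game)
  m <- prod(counts)
  if (index < 0 || index >= m) stop("flat index ", index, " outside 0..", m - 1)
  out <- integer(length(counts))
  for (n in rev(seq_along(counts))) {
    out[n] <- index %% counts[n] + 1
    index <- index %/% counts[n]
  }
  out
}

#' The payoff-state matrix S = (1_M, s_1, ..., s_N)
#'
#' Its column span is the target space of every ZD analysis: a strategy is ZD
#' precisely when its Press-Dyson column space meets `span(S)` nontrivially.
#' @param game a `zd_game`.
#' @return `M x (N+1)` matrix, rational in exact mode, with the all-ones
#'   first column.
#' @export
payoff_matrix <- function(game) {
  ones <- if (game$exact) as_rational(rep(1, game$m)) else rep(1, game$m)
  do.call(r_cbind, c(list(ones), game$payoffs))
}

#' @export
print.zd_game <- function(x, ...) {
  cat(sprintf("<zd_game: %d players, actions (%s), M = %d, %s monitoring, %s mode>\n",
              x$n_players, paste(x$action_counts, collapse = ","), x$m,
              if (x$perfect) "perfect" else sprintf("public (%d signals)", length(x$signals)),
              if (x$exact) "exact" else "float"))
  invisible(x)
}

#' Build a perfect-monitoring game
#' @param action_counts integer vector of per-player action counts.
#' @param payoffs list of payoff vectors over the joint-action space.
#' @return a `zd_game` with `B = Sigma` and indicator signal kernel.
#' @export
build_perfect_monitoring_game <- function(action_counts, payoffs) {
  zd_game(action_counts, payoffs, signals = NULL, W = "perfect")
}

#' Named fixture games
#'
#' * `iterated_prisoners_dilemma`: 2x2, payoffs `s_1 = (R,S,T,P)`,
#'   `s_2 = (R,T,S,P)` in state order (CC, CD, DC, DD), action 1 = cooperate.
#' * `rock_paper_scissors`: 2-player 3-action symmetric zero-sum game
#'   (win = +1, loss = -1, tie = 0; rock beats scissors, paper beats rock,
#'   scissors beats paper).
#' * `two_relation_game`: the 3x3 symmetric game with
#'   `s_1 = (0, r1, 0, r2, 0, 0, 0, 0, 0)`, `s_2 = (0, r2, 0, r1, 0, ...)`;
#'   `1_9, s_1, s_2` are linearly independent iff `r1 != r2` and
#'   `r1 != -r2` (a `degenerate` flag is attached otherwise).
#' * `matching_pennies`: 2x2 zero-sum game with `s_1 = (1,-1,-1,1)`; admits
#'   no ZD strategy, used as the negative control in existence tests.
#' * `winner_signal_game`: a synthetic imperfect-monitoring bidding game.
#'   Actions are bids; the public signal is only the round's outcome
#'   (`p1_wins` / `p2_wins` / `tie`), not the bids themselves.  The higher
#'   bid wins a prize `v` minus the own bid; ties split.  This fixture is an
#'   artifact of this package, standing in for auction-style signal
#'   structures; it is not transcribed from any published example.
#' * `random_game`: seeded perfect-monitoring game with integer payoffs
#'   drawn uniformly from `-payoff_range:payoff_range`.
#'
#' @param name fixture name (see above).
#' @param ... fixture parameters: `R,S,T,P` (IPD, default 3,0,5,1);
#'   `r1,r2` (two_relation_game, default 1,2); `v`, `n_actions`
#'   (winner_signal_game, default 3, 2); `seed`, `n_players`,
#'   `action_counts`, `payoff_range` (random_game).
#' @return a validated `zd_game`.
#' @export
fixture_game <- function(name, ...) {
  args <- list(...)
  switch(name,
    iterated_prisoners_dilemma = {
      R <- args$R %||% 3; S <- args$S %||% 0; T <- args$T %||% 5; P <- args$P %||% 1
      build_perfect_monitoring_game(c(2, 2),
        list(c(R, S, T, P), c(R, T, S, P)))
    },
    matching_pennies = {
      build_perfect_monitoring_game(c(2, 2),
        list(c(1, -1, -1, 1), c(-1, 1, 1, -1)))
    },
    rock_paper_scissors = {
      beats <- function(a, b) (a == 1 && b == 3) || (a == 2 && b == 1) || (a == 3 && b == 2)
      st <- all_states(c(3, 3))
      s1 <- apply(st, 1, function(s) {
        if (beats(s[1], s[2])) 1 else if (beats(s[2], s[1])) -1 else 0
      })
      build_perfect_monitoring_game(c(3, 3), list(s1, -s1))
    },
    two_relation_game = {
      r1 <- as_rational(.maybe_exact(args$r1 %||% 1))
      r2 <- as_rational(.maybe_exact(args$r2 %||% 2))
      s1 <- as_rational(rep(0, 9)); s1[2] <- r1; s1[4] <- r2
      s2 <- as_rational(rep(0, 9)); s2[2] <- r2; s2[4] <- r1
      g <- build_perfect_monitoring_game(c(3, 3), list(s1, s2))
      if (isTRUE(r1 == r2) || isTRUE(r1 == rational(-1) * r2)) {
        warning("two_relation_game: r1 = r2 or r1 = -r2; 1_9, s_1, s_2 are ",
                "linearly dependent and only one independent relation exists")
        g$degenerate <- TRUE
      } else {
        g$degenerate <- FALSE
      }
      g
    },
    winner_signal_game = {
      v <- args$v %||% 3
      na <- args$n_actions %||% 2
      st <- all_states(c(na, na))
      pay <- function(own, other) {
        if (own > other) v - own else if (own == other) (v - own) / 2 else 0
      }
      s1 <- apply(st, 1, function(s) pay(s[1], s[2]))
      s2 <- apply(st, 1, function(s) pay(s[2], s[1]))
      sig <- c("p1_wins", "p2_wins", "tie")
      W <- matrix(0, 3, na * na)
      for (j in seq_len(na * na)) {
        s <- st[j, ]
        W[if (s[1] > s[2]) 1 else if (s[2] > s[1]) 2 else 3, j] <- 1
      }
      zd_game(c(na, na), list(s1 * 2, s2 * 2), signals = sig, W = W)
    },
    random_game = {
      seed <- args$seed
      if (is.null(seed)) stop("random_game requires a seed")
      n_players <- args$n_players %||% 2
      counts <- args$action_counts %||% rep(2, n_players)
      rng <- args$payoff_range %||% 6
      m <- prod(counts)
      set.seed(seed)
      pays <- lapply(seq_len(length(counts)), function(n) {
        sample(seq(-rng, rng), m, replace = TRUE)
      })
      build_perfect_monitoring_game(counts, pays)
    },
    stop("unknown fixture game: '", name, "'")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# serialize one rational/numeric vector or matrix for JSON
.ser_num <- function(x) {
  if (is_rational(x)) {
    ch <- as.character(x)
    if (is.null(dim(ch))) as.list(ch) else apply(ch, 1, as.list, simplify = FALSE)
  } else {
    if (is.null(dim(x))) as.list(x) else apply(x, 1, as.list, simplify = FALSE)
  }
}

.deser_vec <- function(x) {
  v <- unlist(x, use.names = FALSE)
  if (is.character(v)) as_rational(v) else .maybe_exact(v)
}

#' Save / load games as structured JSON
#'
#' Rationals are serialized as `"p/q"` strings so `save_game()` followed by
#' `load_game()` is the identity on the numeric content in exact mode.
#' @param game a `zd_game`.
#' @param path file path.
#' @return `load_game()` returns a validated `zd_game`; `save_game()` its
#'   path, invisibly.
#' @export
save_game <- function(game, path) {
  obj <- list(
    n_players = game$n_players,
    action_counts = game$action_counts,
    payoffs = lapply(game$payoffs, .ser_num),
    signals = if (game$perfect) "perfect" else game$signals,
    W = if (game$perfect) "perfect" else .ser_num(game$W)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_game
#' @export
load_game <- function(path) {
  obj <- jsonlite::read_json(path)
  for (f in c("action_counts", "payoffs")) {
    if (is.null(obj[[f]])) stop("game file is missing required field '", f, "'")
  }
  counts <- unlist(obj$action_counts)
  payoffs <- lapply(obj$payoffs, .deser_vec)
  perfect <- is.null(obj$W) || identical(obj$W, "perfect") ||
             identical(obj$signals, "perfect")
  if (perfect) {
    zd_game(counts, payoffs)
  } else {
    W_rows <- lapply(obj$W, .deser_vec)
    W <- do.call(r_rbind, W_rows)
    zd_game(counts, payoffs, signals = unlist(obj$signals), W = W)
  }
}
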