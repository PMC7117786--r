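#' @title The induced Markov chain of a strategy profile
#'
#' @description
#' With one memory-one strategy per player, the joint action follows a Markov
#' chain on `Sigma` with transition probability
#' `T(sigma | sigma') = sum_tau W(tau | sigma') prod_n That_n(sigma_n |
#' sigma'_n, tau)`.  The matrix is stored `(to, from)`: column `sigma'` is
#' the distribution of the next state, matching left-multiplication of state
#' distributions.
#'
#' @param game a `zd_game`.
#' @param strategies list of `zd_strategy`, one per player, in player order.
#' @return `M x M` column-stochastic matrix (rational when game and all
#'   strategies are exact).
#' @export
transition_matrix <- function(game, strategies) {
  N <- game$n_players
  if (length(strategies) != N) stop("need one strategy per player")
  for (n in seq_len(N)) {
    if (strategies[[n]]$player != n) {
      stop("strategies must be listed in player order; slot ", n,
           " belongs to player ", strategies[[n]]$player)
    }
  }
  exact <- game$exact && all(vapply(strategies, `[[`, logical(1), "exact"))
  states <- all_states(game)
  m <- game$m
  nb <- length(game$signals)
  getW <- function() if (exact) game$W else {
    if (is_rational(game$W)) game$W$num / game$W$den else game$W
  }
  W <- getW()
  tabs <- lapply(strategies, function(s) {
    if (exact) s$table else {
      t0 <- s$table
      if (is_rational(t0)) t0$num / t0$den else t0
    }
  })
  out <- if (exact) rat_zeros(m, m) else matrix(0, m, m)
  for (j in seq_len(m)) {
    sprev <- states[j, ]
    col <- if (exact) rational(numeric(m)) else numeric(m)
    for (b in seq_len(nb)) {
      w <- if (exact) W[b, j, drop = TRUE] else W[b, j]
      wz <- if (exact) w$num == 0 else w == 0
      if (wz) next
      # product over players of That_n(. | sigma'_n, tau), expanded over Sigma
      probs <- if (exact) as_rational(rep(1, m)) else rep(1, m)
      for (n in seq_len(N)) {
        pn <- if (exact) tabs[[n]][, sprev[n], b, drop = TRUE] else tabs[[n]][, sprev[n], b]
        probs <- probs * (if (exact) pn[states[, n], drop = TRUE] else pn[states[, n]])
      }
      col <- col + w * probs
    }
    out[, j] <- col
  }
  out
}

#' Recurrent classes and stationary distributions
#'
#' Decomposes the support digraph of the chain into strongly connected
#' components (by boolean reachability, exact), keeps the closed (recurrent)
#' ones, and solves each class's stationary distribution from the null space
#' of `T - I` restricted to the class -- exactly in rational mode.  Every
#' stationary distribution of the chain is a convex combination of the
#' per-class ones; the chain is irreducible iff there is a single class
#' covering all states.
#'
#' @param tm transition matrix from [transition_matrix()].
#' @return an object of class `"stationary_analysis"`: list with
#'   `classes` (list of 1-based state-index vectors), `distributions` (list
#'   of length-M stationary vectors, one per recurrent class),
#'   `irreducible`, `exact`.
#' @export
stationary_distributions <- function(tm) {
  exact <- is_rational(tm)
  P <- if (exact) tm$num != 0 else tm > 1e-14
  m <- nrow(P)
  # reachability closure (to, from): reach[i, j] = j reaches i in >= 0 steps
  reach <- P | diag(TRUE, m)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mutual <- reach & t(reach)
  comp <- integer(m)
  cid <- 0L
  for (i in seq_len(m)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[mutual[i, ]] <- cid
    }
  }
  classes <- list()
  for (k in seq_len(cid)) {
    members <- which(comp == k)
    # closed iff no transition leaves the class
    outside <- setdiff(seq_len(m), members)
    leaves <- length(outside) > 0 && any(P[outside, members])
    if (!leaves) classes[[length(classes) + 1]] <- members
  }
  dists <- lapply(classes, function(members) {
    sub <- tm[members, members, drop = FALSE]
    k <- length(members)
    a <- sub - (if (exact) rat_diag(k) else diag(k))
    ns <- null_space(a)
    nsd <- if (exact) ns$num else ns
    if (ncol(nsd) != 1) stop("recurrent class does not have a 1-dim stationary space")
    v <- if (exact) ns[, 1, drop = TRUE] else ns[, 1]
    tot <- if (exact) r_sum(v) else sum(v)
    v <- v / tot
    full <- if (exact) rational(numeric(m)) else numeric(m)
    full[members] <- v
    full
  })
  structure(list(classes = classes, distributions = dists,
                 irreducible = length(classes) == 1 &&
                               length(classes[[1]]) == m,
                 exact = exact),
            class = "stationary_analysis")
}

#' @export
print.stationary_analysis <- function(x, ...) {
  cat(sprintf("<stationary analysis: %d recurrent class(es), %sirreducible, %s mode>\n",
              length(x$classes), if (x$irreducible) "" else "not ",
              if (x$exact) "exact" else "float"))
  invisible(x)
}

#' Long-run average payoffs e = t(S) rho
#'
#' @param rho stationary distribution (length-M vector, rational or numeric).
#' @param game a `zd_game`.
#' @return vector `(1, e_1, ..., e_N)`; first entry exactly 1.
#' @export
average_payoffs <- function(rho, game) {
  rn <- if (is_rational(rho)) rho$num / rho$den else rho
  if (length(rn) != game$m) stop("rho must have length M")
  if (any(rn < -1e-12) || abs(sum(rn) - 1) > 1e-9) {
    stop("rho is not a probability distribution")
  }
  S <- payoff_matrix(game)
  cm <- .common_mode(S, rho)
  e <- r_mmul(t(cm$a), cm$b)
  if (is_rational(e)) e[, 1, drop = TRUE] else e[, 1]
}

#' Residual of the generalized Akin's lemma
#'
#' For a stationary `rho` of the full chain, the inner product of `rho` with
#' every Press-Dyson column of every player is zero.  Returns the maximum
#' absolute residual `max_sigma_n | t(rho) Ttilde_n(sigma_n) |`; identically
#' zero in rational mode.
#'
#' @param rho stationary distribution.
#' @param pd a `"press_dyson"` object for one player.
#' @param tm optional transition matrix; when supplied, `rho` is first
#'   checked to be stationary and a diagnostic error reports the
#'   fixed-point residual otherwise.
#' @return numeric max-abs residual (0 for exact input).
#' @export
verify_akin <- function(rho, pd, tm = NULL) {
  if (!is.null(tm)) {
    cm <- .common_mode(tm, rho)
    res <- r_mmul(cm$a, cm$b)
    diffv <- if (is_rational(res)) {
      d <- res[, 1, drop = TRUE] - cm$b
      max(abs(d$num / d$den))
    } else max(abs(res[, 1] - cm$b))
    if (diffv > 1e-9) {
      stop("rho is not stationary: max |T rho - rho| = ", format(diffv))
    }
  }
  cm <- .common_mode(pd$matrix, rho)
  r <- r_mmul(t(cm$a), cm$b)
  rn <- if (is_rational(r)) r$num / r$den else r
  max(abs(rn))
}

#' Monte-Carlo play of a strategy profile
#'
#' Simulates the public-monitoring protocol literally: draw a signal from
#' `W(. | sigma')`, then each player draws the next action from her table
#' row.  Reproducible under a fixed seed.
#'
#' @param game a `zd_game`.
#' @param strategies list of per-player `zd_strategy`.
#' @param horizon number of rounds (>= 1).
#' @param seed RNG seed (mandatory: stochastic commands take no silent
#'   entropy).
#' @param initial_state 1-based action tuple for round 0 (default all-1s).
#' @return list with `state_freq` (length-M empirical distribution over
#'   visited states), `payoffs` (empirical mean payoff per player),
#'   `payoff_se` (batch-means standard errors), `horizon`.
#' @export
simulate_play <- function(game, strategies, horizon, seed,
                          initial_state = NULL) {
  stopifnot(horizon >= 1)
  if (missing(seed) || is.null(seed)) stop("simulate_play() requires a seed")
  set.seed(seed)
  N <- game$n_players
  if (is.null(initial_state)) initial_state <- rep(1L, N)
  j <- state_index(initial_state, game) + 1L
  W <- if (is_rational(game$W)) game$W$num / game$W$den else game$W
  tabs <- lapply(strategies, function(s) {
    t0 <- s$table
    if (is_rational(t0)) t0$num / t0$den else t0
  })
  states <- all_states(game)
  counts <- numeric(game$m)
  Smat <- payoff_matrix(game)
  Sn <- if (is_rational(Smat)) Smat$num / Smat$den else Smat
  nb <- length(game$signals)
  traj <- integer(horizon)
  cur <- states[j, ]
  for (t in seq_len(horizon)) {
    tau <- if (nb == 1) 1L else sample.int(nb, 1L, prob = W[, j])
    nxt <- integer(N)
    for (n in seq_len(N)) {
      p <- tabs[[n]][, cur[n], tau]
      nxt[n] <- sample.int(length(p), 1L, prob = p)
    }
    j <- state_index(nxt, game) + 1L
    cur <- nxt
    counts[j] <- counts[j] + 1
    traj[t] <- j
  }
  freq <- counts / horizon
  payoffs <- as.vector(freq %*% Sn[, -1, drop = FALSE])
  # batch-means standard error (30 batches) to respect autocorrelation
  nb_batch <- min(30L, horizon)
  se <- vapply(seq_len(N), function(n) {
    x <- Sn[traj, n + 1]
    bs <- split(x, cut(seq_along(x), nb_batch, labels = FALSE))
    means <- vapply(bs, mean, numeric(1))
    stats::sd(means) / sqrt(length(means))
  }, numeric(1))
  list(state_freq = freq, payoffs = payoffs, payoff_se = se,
       horizon = horizon)
}
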