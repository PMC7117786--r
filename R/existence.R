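#' @title Does a ZD strategy exist in a given game?
#'
#' @description
#' Under perfect monitoring the question is decidable by linear programming.
#' A combination `u = PD_n c` of Press-Dyson columns evaluates at state
#' `sigma'` to `E_p[c] - c_{sigma'_n}` where `p = T_n(. | sigma')` is a free
#' probability vector, so the achievable values sweep exactly the interval
#' `[min(c) - c_{sigma'_n}, max(c) - c_{sigma'_n}]`.  A ZD strategy exists
#' iff some `alpha` and `c` satisfy
#' `min(c) - c_{sigma'_n} <= (S alpha)(sigma') <= max(c) - c_{sigma'_n}`
#' for every state, with `S alpha != 0`.  The search enumerates the
#' (argmin, argmax) index pair of `c` (ties resolved to the lowest index,
#' all ordered pairs covered), normalizes `c_argmin = 0`, `c_argmax = 1`,
#' and excludes the trivial solution by requiring
#' `|(S alpha)(sigma_0)| >= 1` for some enumerated coordinate and sign --
#' each choice one feasibility LP.  On success a witness strategy is
#' reconstructed (mixtures of the argmin/argmax actions) and re-verified via
#' [compute_zd_subspace()], exactly when the rationalized LP point survives
#' an exact re-check.
#'
#' Under imperfect monitoring the feasible set is bilinear in `(c, That)`;
#' no exact procedure is attempted.  A clearly-labelled heuristic fixes `c`
#' (random restarts) and solves the then-linear program over the table and
#' `alpha`; a negative answer is reported as `exists = NA`, status
#' `"heuristic-inconclusive"`, never as a silent "no".
#'
#' @param game a `zd_game`.
#' @param player player index.
#' @param objective optional length `N+1+M_n` vector: when given, the
#'   feasibility LP additionally maximizes `objective' (alpha, c)` (with a
#'   box on `alpha`), which varies the returned witness.
#' @param restarts random-`c` restarts for the imperfect-monitoring
#'   heuristic.
#' @param seed seed for the heuristic restarts (required then).
#' @return list with `exists` (`TRUE`/`FALSE`, or `NA` when the heuristic is
#'   inconclusive), `witness` (`zd_strategy` or `NULL`), `certificate`
#'   (alpha, c, enumeration indices), `status` (`"decided"` or
#'   `"heuristic"`), `exact_verified`, `lps_solved`.
#' @export
zd_existence <- function(game, player, objective = NULL, restarts = 20,
                         seed = NULL) {
  if (game$perfect) {
    .zd_exist_perfect(game, player, objective)
  } else {
    if (is.null(seed)) stop("heuristic existence search requires a seed")
    .zd_exist_heuristic(game, player, restarts, seed)
  }
}

.zd_exist_perfect <- function(game, player, objective = NULL) {
  mn <- game$action_counts[player]
  N <- game$n_players
  m <- game$m
  Sd <- payoff_matrix(game)
  if (is_rational(Sd)) Sd <- as.double(Sd)
  own <- all_states(game)[, player]
  nv <- (N + 1) + mn
  aidx <- seq_len(N + 1)
  cidx <- N + 1 + seq_len(mn)
  lps <- 0L
  for (imin in seq_len(mn)) {
    for (jmax in seq_len(mn)) {
      if (imin == jmax) next
      eq <- list(); eqr <- numeric(0)
      pin <- numeric(nv); pin[cidx[imin]] <- 1
      eq[[1]] <- pin; eqr <- 0                      # c_min = 0
      nrm <- numeric(nv); nrm[cidx[jmax]] <- 1; nrm[cidx[imin]] <- -1
      eq[[2]] <- nrm; eqr <- c(eqr, 1)              # c_max - c_min = 1
      le <- list(); ler <- numeric(0)
      for (k in seq_len(mn)) {
        if (k == imin || k == jmax) next
        r1 <- numeric(nv); r1[cidx[imin]] <- 1; r1[cidx[k]] <- -1
        r2 <- numeric(nv); r2[cidx[k]] <- 1; r2[cidx[jmax]] <- -1
        le <- c(le, list(r1, r2)); ler <- c(ler, 0, 0)
      }
      for (j in seq_len(m)) {
        lo <- numeric(nv)                            # -u + c_min - c_own <= 0
        lo[aidx] <- -Sd[j, ]
        lo[cidx[imin]] <- lo[cidx[imin]] + 1
        lo[cidx[own[j]]] <- lo[cidx[own[j]]] - 1
        hi <- numeric(nv)                            # u - c_max + c_own <= 0
        hi[aidx] <- Sd[j, ]
        hi[cidx[jmax]] <- hi[cidx[jmax]] - 1
        hi[cidx[own[j]]] <- hi[cidx[own[j]]] + 1
        le <- c(le, list(lo, hi)); ler <- c(ler, 0, 0)
      }
      a_eq <- do.call(rbind, eq); a_le0 <- do.call(rbind, le)
      for (s0 in seq_len(m)) {
        for (sgn in c(1, -1)) {
          nt <- numeric(nv); nt[aidx] <- -sgn * Sd[s0, ]
          a_le <- rbind(a_le0, nt); ler2 <- c(ler, -1)
          if (!is.null(objective)) {
            box <- matrix(0, 2 * (N + 1), nv)
            for (i in seq_len(N + 1)) {
              box[2 * i - 1, aidx[i]] <- 1
              box[2 * i, aidx[i]] <- -1
            }
            a_le <- rbind(a_le, box); ler2 <- c(ler2, rep(100, 2 * (N + 1)))
          }
          res <- lp_solve(a_eq = a_eq, b_eq = eqr, a_le = a_le, b_le = ler2,
                          objective = objective)
          lps <- lps + 1L
          if (res$status == "optimal") {
            out <- .zd_exist_witness(game, player, res$x[aidx], res$x[cidx],
                                     imin, jmax)
            out$certificate$nontrivial <- c(state = s0, sign = sgn)
            out$exists <- TRUE
            out$status <- "decided"
            out$lps_solved <- lps
            return(out)
          }
        }
      }
    }
  }
  list(exists = FALSE, witness = NULL, certificate = NULL,
       status = "decided", exact_verified = TRUE, lps_solved = lps)
}

# rebuild a memory-one witness from an LP point (alpha, c); exact when the
# rationalized point still satisfies every constraint exactly
.zd_exist_witness <- function(game, player, alpha, cvec, imin, jmax) {
  mn <- game$action_counts[player]
  own <- all_states(game)[, player]
  Sq <- payoff_matrix(game)
  # exact attempt
  if (game$exact) {
    qa <- tryCatch(.rationalize_array(alpha, 1e6), error = function(e) NULL)
    qc <- tryCatch(.rationalize_array(cvec, 1e6), error = function(e) NULL)
    if (!is.null(qa) && !is.null(qc)) {
      dim(qa) <- c(length(alpha), 1)
      u <- r_mmul(Sq, qa)[, 1, drop = TRUE]
      lam <- u + qc[own, drop = TRUE]  # weight on the argmax action
      okq <- all(lam >= 0) && all(lam <= 1) && !r_all_zero(u)
      if (okq) {
        cols <- rat_zeros(mn, game$m)
        for (j in seq_len(game$m)) {
          lj <- lam[j, drop = TRUE]
          cols[jmax, j] <- lj
          cols[imin, j] <- cols[imin, j, drop = TRUE] + (rational(1) - lj)
        }
        st <- strategy_from_columns(game, player, cols)
        rep <- tryCatch(compute_zd_subspace(st, game), error = function(e) NULL)
        if (!is.null(rep) && rep$is_zd) {
          return(list(witness = st,
                      certificate = list(alpha = qa[, 1, drop = TRUE], c = qc,
                                         pair = c(argmin = imin, argmax = jmax)),
                      exact_verified = TRUE, report = rep))
        }
      }
    }
  }
  # float fallback
  Sd <- if (is_rational(Sq)) as.double(Sq) else Sq
  u <- as.vector(Sd %*% alpha)
  lam <- pmin(pmax(u + cvec[own], 0), 1)
  cols <- matrix(0, mn, game$m)
  for (j in seq_len(game$m)) {
    cols[jmax, j] <- lam[j]
    cols[imin, j] <- cols[imin, j] + 1 - lam[j]
  }
  st <- strategy_from_columns(game, player, cols)
  rep <- compute_zd_subspace(st, game)
  list(witness = st,
       certificate = list(alpha = alpha, c = cvec,
                          pair = c(argmin = imin, argmax = jmax)),
       exact_verified = FALSE, report = rep)
}

.zd_exist_heuristic <- function(game, player, restarts, seed) {
  set.seed(seed)
  mn <- game$action_counts[player]
  N <- game$n_players
  m <- game$m
  nb <- length(game$signals)
  W <- if (is_rational(game$W)) game$W$num / game$W$den else game$W
  Sd <- payoff_matrix(game)
  if (is_rational(Sd)) Sd <- as.double(Sd)
  own <- all_states(game)[, player]
  nx <- mn * mn * nb
  vid <- function(a, sp, b) a + mn * (sp - 1) + mn * mn * (b - 1)
  nv <- nx + (N + 1)
  aidx <- nx + seq_len(N + 1)
  lps <- 0L
  for (r in seq_len(restarts)) {
    cvec <- sort(stats::rnorm(mn))
    cvec <- (cvec - cvec[1]) / (cvec[mn] - cvec[1])   # spread 1, ascending
    eq <- list(); eqr <- numeric(0)
    for (j in seq_len(m)) {
      row <- numeric(nv)
      for (a in seq_len(mn)) {
        for (b in seq_len(nb)) {
          row[vid(a, own[j], b)] <- row[vid(a, own[j], b)] + cvec[a] * W[b, j]
        }
      }
      row[aidx] <- -Sd[j, ]
      eq[[length(eq) + 1]] <- row
      eqr <- c(eqr, cvec[own[j]])
    }
    for (sp in seq_len(mn)) for (b in seq_len(nb)) {
      row <- numeric(nv)
      row[vid(seq_len(mn), sp, b)] <- 1
      eq[[length(eq) + 1]] <- row
      eqr <- c(eqr, 1)
    }
    a_eq <- do.call(rbind, eq)
    a_le0 <- cbind(-diag(nx), matrix(0, nx, N + 1))   # x >= 0
    for (s0 in seq_len(m)) {
      for (sgn in c(1, -1)) {
        nt <- numeric(nv); nt[aidx] <- -sgn * Sd[s0, ]
        res <- lp_solve(a_eq = a_eq, b_eq = eqr,
                        a_le = rbind(a_le0, nt),
                        b_le = c(numeric(nx), -0.05))
        lps <- lps + 1L
        if (res$status == "optimal") {
          x <- pmin(pmax(res$x[seq_len(nx)], 0), 1)
          tab <- array(x, c(mn, mn, nb))
          for (sp in seq_len(mn)) for (b in seq_len(nb)) {
            tab[, sp, b] <- tab[, sp, b] / sum(tab[, sp, b])
          }
          st <- memory_one_strategy(player, tab, game)
          rep <- compute_zd_subspace(st, game)
          if (rep$is_zd) {
            return(list(exists = TRUE, witness = st,
                        certificate = list(alpha = res$x[aidx], c = cvec,
                                           restart = r),
                        status = "heuristic", exact_verified = FALSE,
                        lps_solved = lps))
          }
        }
      }
    }
  }
  list(exists = NA, witness = NULL, certificate = NULL,
       status = "heuristic-inconclusive", exact_verified = FALSE,
       lps_solved = lps)
}

#' Brute-force existence oracle for 2-action players
#'
#' Enumerates perfect-monitoring strategies on a rational grid (one
#' cooperate-probability per previous state) and tests each for the ZD
#' property by exact subspace membership.  Independent of the LP route; used
#' to cross-check [zd_existence()] on small games.
#'
#' @param game a perfect-monitoring `zd_game`; `player` must have 2 actions.
#' @param player player index.
#' @param grid probabilities to try per state (exactly representable values
#'   keep the check exact).
#' @return list with `exists`, `witness_columns` (2 x M matrix or `NULL`),
#'   `tested`.
#' @export
zd_existence_bruteforce <- function(game, player,
                                    grid = c(0, 1/4, 1/2, 3/4, 1)) {
  if (!game$perfect) stop("brute-force oracle needs perfect monitoring")
  mn <- game$action_counts[player]
  if (mn != 2) stop("brute-force oracle implemented for 2-action players")
  m <- game$m
  own <- all_states(game)[, player]
  S <- payoff_matrix(game)
  sspace <- column_space(S)
  qgrid <- as_rational(grid)
  combos <- rep(list(seq_along(grid)), m)
  idx <- do.call(expand.grid, combos)
  tested <- 0L
  for (r in seq_len(nrow(idx))) {
    pvec <- qgrid[as.integer(idx[r, ]), drop = TRUE]
    # Press-Dyson column of action 1: p - [own == 1]
    v <- pvec - as_rational(as.numeric(own == 1))
    tested <- tested + 1L
    if (r_all_zero(v)) next
    if (subspace_contains(sspace, v)) {
      cols <- r_rbind(pvec, rational(1) - pvec)
      return(list(exists = TRUE, witness_columns = cols, tested = tested))
    }
  }
  list(exists = FALSE, witness_columns = NULL, tested = tested)
}

#' Random exact ZD strategy via max-margin linear programming
#'
#' Draws a random normalization functional on `alpha`, maximizes the slack
#' of the existence constraints at the canonical ascending `c`
#' (`c_k = (k-1)/(M_n-1)`), rationalizes the optimum and re-verifies every
#' constraint exactly.  The returned strategy mixes only the lowest and
#' highest actions; for 2-action players a strictly positive margin makes
#' every Press-Dyson entry nonzero (the independence hypothesis).  Uses the
#' current RNG state; seed outside.
#'
#' @param game an exact perfect-monitoring `zd_game`.
#' @param player player index.
#' @param max_tries random normalizations tried before giving up.
#' @param min_margin smallest accepted slack.
#' @return list with `strategy` (exact `zd_strategy`), `alpha` (rational),
#'   `u` (the enforced vector `S alpha`), `margin`; or `NULL` when no ZD
#'   strategy was found for this game.
#' @export
random_zd_strategy <- function(game, player, max_tries = 8,
                               min_margin = 1e-4) {
  stopifnot(game$perfect, game$exact)
  mn <- game$action_counts[player]
  N <- game$n_players
  m <- game$m
  Sq <- payoff_matrix(game)
  Sd <- as.double(Sq)
  own <- all_states(game)[, player]
  cq <- rational(0:(mn - 1), mn - 1)
  cd <- as.double(cq)
  nv <- (N + 1) + 1                       # alpha, margin t
  tidx <- nv
  for (try in seq_len(max_tries)) {
    g <- stats::rnorm(N + 1)
    le <- list(); ler <- numeric(0)
    for (j in seq_len(m)) {
      hi <- numeric(nv); hi[seq_len(N + 1)] <- Sd[j, ]; hi[tidx] <- 1
      ler <- c(ler, 1 - cd[own[j]])       # u + t <= 1 - c_own
      lo <- numeric(nv); lo[seq_len(N + 1)] <- -Sd[j, ]; lo[tidx] <- 1
      ler <- c(ler, cd[own[j]])           # -u + t <= c_own
      le <- c(le, list(hi, lo))
    }
    box <- matrix(0, 2 * (N + 1) + 1, nv)
    for (i in seq_len(N + 1)) {
      box[2 * i - 1, i] <- 1
      box[2 * i, i] <- -1
    }
    box[2 * (N + 1) + 1, tidx] <- 1       # t <= 1/4
    a_le <- rbind(do.call(rbind, le), box)
    b_le <- c(ler, rep(50, 2 * (N + 1)), 1 / 4)
    a_eq <- matrix(0, 1, nv); a_eq[1, seq_len(N + 1)] <- g
    obj <- numeric(nv); obj[tidx] <- 1
    res <- lp_solve(a_eq = a_eq, b_eq = 1, a_le = a_le, b_le = b_le,
                    objective = obj)
    if (res$status != "optimal" || res$value < min_margin) next
    # snap alpha to a coarse exact grid; the LP margin absorbs the rounding
    for (D in c(60, 360, 2520)) {
      qa <- rational(round(res$x[seq_len(N + 1)] * D), D)
      dim(qa) <- c(N + 1, 1)
      u <- r_mmul(Sq, qa)[, 1, drop = TRUE]
      if (r_all_zero(u)) next
      lam <- u + cq[own, drop = TRUE]
      if (any(lam < 0) || any(lam > 1)) next
      cols <- rat_zeros(mn, game$m)
      for (j in seq_len(m)) {
        lj <- lam[j, drop = TRUE]
        cols[mn, j] <- lj
        cols[1, j] <- cols[1, j, drop = TRUE] + (rational(1) - lj)
      }
      st <- strategy_from_columns(game, player, cols)
      return(list(strategy = st, alpha = qa[, 1, drop = TRUE], u = u,
                  margin = res$value))
    }
  }
  NULL
}
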