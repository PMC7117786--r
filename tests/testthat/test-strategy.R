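test_that("validation passes good strategies and localizes bad ones", {
  ipd <- ipd_game()
  expect_true(validate_strategy(strategy_tit_for_tat(ipd, 1), ipd)$ok)
  expect_true(validate_strategy(strategy_repeat(ipd, 1), ipd)$ok)
  tab <- array(0.5, c(2, 2, 4))
  tab[, 2, 3] <- c(0.9, 0.3)                     # sums to 1.2
  st <- memory_one_strategy(1, tab, ipd)
  v <- validate_strategy(st, ipd)
  expect_false(v$ok)
  expect_match(v$problems$where[1], "prev=2, signal=3")
  # the double-control strategy with its printed constraints validates
  dc <- dc_default()
  expect_true(validate_strategy(dc$strategy, dc$game)$ok)
})

test_that("marginal transition: perfect monitoring re-indexes the table", {
  ipd <- ipd_game()
  tft <- strategy_tit_for_tat(ipd, 1)
  marg <- marginal_transition(tft, ipd)
  # cooperate iff opponent cooperated: columns CC,CD,DC,DD
  expect_rat_equal(as.double(marg), rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
})

test_that("uninformative kernel makes columns depend only on own action", {
  gu <- zd_game(c(2, 2), list(c(3, 0, 5, 1), c(3, 5, 0, 1)),
                signals = "null", W = matrix(1, 1, 4))
  set.seed(3)
  st <- random_strategy(gu, 1)
  marg <- marginal_transition(st, gu)
  # states (1,1) and (1,2) share own action 1; (2,1) and (2,2) share 2
  expect_true(all(marg[, 1, drop = TRUE] == marg[, 2, drop = TRUE]))
  expect_true(all(marg[, 3, drop = TRUE] == marg[, 4, drop = TRUE]))
})

test_that("signal-contingent strategy mixes rows by the kernel weights", {
  # 2-bid winner game, strategy reacting to who won; hand-computed mixture
  wg <- fixture_game("winner_signal_game")
  tab <- array(0, c(2, 2, 3))
  tab[1, , 1] <- 1; tab[2, , 1] <- 0      # after p1 wins: play 1
  tab[1, , 2] <- 0; tab[2, , 2] <- 1      # after p2 wins: play 2
  tab[1, , 3] <- 1 / 2; tab[2, , 3] <- 1 / 2
  st <- memory_one_strategy(1, as_rational(tab), wg)
  marg <- marginal_transition(st, wg)
  # state (2,1): p1 wins deterministically -> column = (1,0)
  expect_true(all(marg[, state_index(c(2, 1), wg) + 1, drop = TRUE] == rvec(1, 0)))
  # state (1,1): tie -> column = (1/2, 1/2)
  expect_true(all(marg[, 1, drop = TRUE] == as_rational(c(1, 1)) / 2))
})

test_that("Press-Dyson matrices match the printed examples", {
  ipd <- ipd_game()
  pd <- press_dyson(strategy_tit_for_tat(ipd, 1), ipd)
  expect_true(all(pd$matrix[, 1, drop = TRUE] == rvec(0, -1, 1, 0)))
  expect_true(pd$has_zero_elements)
  # Repeat: identically zero
  pd0 <- press_dyson(strategy_repeat(ipd, 1), ipd)
  expect_true(all(pd0$matrix$num == 0))
  # double-control strategy, first Press-Dyson column at p=1/2, p'=1/4
  dc <- dc_default()
  pdd <- press_dyson(dc$strategy, dc$game)
  expect_true(all(pdd$matrix[, 1, drop = TRUE] ==
                  as_rational(c(0, -1/2, 0, 1/4, 0, 0, 0, 0, 0))))
})

test_that("Press-Dyson invariants hold across random strategies", {
  set.seed(17)
  games <- list(ipd_game(), fixture_game("two_relation_game"),
                fixture_game("winner_signal_game"))
  for (g in games) {
    for (rep in 1:8) {
      n <- sample(seq_len(g$n_players), 1)
      st <- random_strategy(g, n)
      pd <- press_dyson(st, g)$matrix
      mn <- g$action_counts[n]
      # row sums zero (matrix . 1 = 0)
      rs <- r_mmul(pd, as_rational(rep(1, mn)))
      expect_true(all(rs$num == 0))
      # sign structure: diagonal-own entries <= 0, others >= 0
      own <- all_states(g)[, n]
      pdn <- as.double(pd)
      for (a in seq_len(mn)) {
        expect_true(all(pdn[own == a, a] <= 0))
        expect_true(all(pdn[own != a, a] >= 0))
        expect_true(all(abs(pdn[, a]) <= 1))
      }
      # span dimension at most M_n - 1
      expect_lte(mat_rank(pd), mn - 1L)
    }
  }
})

test_that("eps-bounded sampling avoids zero Press-Dyson entries", {
  set.seed(23)
  ipd <- ipd_game()
  for (i in 1:5) {
    st <- random_strategy(ipd, 1, eps = 0.05, rationalize = 60)
    expect_false(press_dyson(st, ipd)$has_zero_elements)
  }
})

test_that("realize_marginal: perfect, uninformative, and constant targets", {
  ipd <- ipd_game()
  tgt <- marginal_transition(strategy_tit_for_tat(ipd, 1), ipd)
  r <- realize_marginal(tgt, ipd, 1)
  expect_true(r$feasible)
  expect_true(r$exact_verified)
  expect_rat_equal(as.double(marginal_transition(r$strategy, ipd)),
                   as.double(tgt))
  # Press-Dyson of the realization equals Press-Dyson of the original
  expect_true(all(press_dyson(r$strategy, ipd)$matrix ==
                  press_dyson(strategy_tit_for_tat(ipd, 1), ipd)$matrix))
  # uninformative kernel cannot realize an opponent-sensitive target
  gu <- zd_game(c(2, 2), list(c(3, 0, 5, 1), c(3, 5, 0, 1)),
                signals = "null", W = matrix(1, 1, 4))
  r2 <- realize_marginal(as.double(tgt), gu, 1)
  expect_false(r2$feasible)
  expect_identical(r2$status, "infeasible")
  # a target constant in sigma' is realizable under any kernel
  wg <- fixture_game("winner_signal_game")
  const <- matrix(c(0.25, 0.75), 2, wg$m)
  r3 <- realize_marginal(const, wg, 1)
  expect_true(r3$feasible)
  expect_equal(as.double(marginal_transition(r3$strategy, wg)), const,
               tolerance = 1e-7)
})

test_that("strategy shorthand errors are informative", {
  wg <- fixture_game("winner_signal_game")
  expect_error(strategy_tit_for_tat(wg, 1), "perfect-monitoring")
  ipd <- ipd_game()
  expect_error(memory_one_strategy(1, array(0.5, c(2, 2, 3)), ipd), "2 x 2 x 4")
  expect_error(memory_one_strategy(3, array(0.5, c(2, 2, 4)), ipd), "no player")
})
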