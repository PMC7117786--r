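test_that("transition matrix: degenerate profiles and TFT dynamics", {
  ipd <- ipd_game()
  # all Repeat -> identity
  tm <- transition_matrix(ipd, list(strategy_repeat(ipd, 1), strategy_repeat(ipd, 2)))
  expect_true(all(tm == as_rational(diag(4))))
  # all uniform -> every column uniform
  tm2 <- transition_matrix(ipd, list(strategy_uniform(ipd, 1), strategy_uniform(ipd, 2)))
  expect_true(all(tm2 == as_rational(matrix(1, 4, 4)) / 4))
  # TFT vs TFT: fixes CC and DD, swaps CD <-> DC
  tft <- lapply(1:2, function(n) strategy_tit_for_tat(ipd, n))
  tm3 <- as.double(transition_matrix(ipd, tft))
  perm <- matrix(0, 4, 4)
  perm[1, 1] <- perm[3, 2] <- perm[2, 3] <- perm[4, 4] <- 1
  expect_identical(tm3, perm)
  expect_error(transition_matrix(ipd, list(strategy_repeat(ipd, 1))), "one strategy per player")
  expect_error(transition_matrix(ipd, list(strategy_repeat(ipd, 2), strategy_repeat(ipd, 2))),
               "player order")
})

test_that("stationary analysis handles reducible and irreducible chains", {
  # identity: every state its own recurrent class
  sa <- stationary_distributions(as_rational(diag(3)))
  expect_identical(length(sa$classes), 3L)
  expect_false(sa$irreducible)
  expect_true(all(sa$distributions[[2]] == rvec(0, 1, 0)))
  # strictly positive chain: unique rho; cross-check power iteration
  p <- matrix(c(1, 2, 1, 3, 1, 2, 2, 1, 1), 3, 3)
  p <- sweep(p, 2, colSums(p), "/")
  sa2 <- stationary_distributions(p)
  expect_true(sa2$irreducible)
  v <- rep(1 / 3, 3)
  for (i in 1:200) v <- as.vector(p %*% v)
  expect_equal(as.double(sa2$distributions[[1]]), v, tolerance = 1e-9)
  # block-diagonal: two classes, two stationary distributions
  blk <- as_rational(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                           c(0, 0, 1, 1), c(0, 0, 1, 1))) / 2
  sa3 <- stationary_distributions(blk)
  expect_identical(length(sa3$classes), 2L)
  for (rho in sa3$distributions) {
    expect_true(r_sum(rho) == 1)
    expect_true(all(r_mmul(blk, r_cbind(rho))[, 1, drop = TRUE] == rho))
  }
  # transient states: class {1} absorbing, state 2 transient
  tr <- as_rational(rbind(c(1, 1), c(0, 1))) ; tr[2, 2] <- rational(1, 2); tr[1, 2] <- rational(1, 2)
  sa4 <- stationary_distributions(tr)
  expect_identical(length(sa4$classes), 1L)
  expect_true(all(sa4$distributions[[1]] == rvec(1, 0)))
})

test_that("average payoffs are t(S) rho with leading 1", {
  ipd <- ipd_game()
  e <- average_payoffs(as_rational(rep(1, 4)) / 4, ipd)
  expect_true(e[1, drop = TRUE] == 1)
  expect_true(e[2, drop = TRUE] == rational(9, 4))
  # concentrated on DC: e_n = s_n(DC)
  rho <- rvec(0, 0, 1, 0)
  e2 <- average_payoffs(rho, ipd)
  expect_true(e2[2, drop = TRUE] == 5 && e2[3, drop = TRUE] == 0)
  # zero-sum: e_1 + e_2 = 0 for any rho
  rps <- fixture_game("rock_paper_scissors")
  set.seed(2)
  w <- stats::rexp(9); w <- w / sum(w)
  e3 <- average_payoffs(w, rps)
  expect_equal(e3[2] + e3[3], 0, tolerance = 1e-12)
  expect_error(average_payoffs(c(0.5, 0.5, 0.5, 0.5), ipd), "not a probability")
})

test_that("Akin's lemma: exact zero residual on every recurrent class", {
  dc <- dc_default()
  g <- dc$game
  profiles <- list(
    list(dc$strategy, strategy_uniform(g, 2)),
    list(dc$strategy, strategy_repeat(g, 2)),
    list(dc$strategy, strategy_tit_for_tat(g, 2))
  )
  for (prof in profiles) {
    tm <- transition_matrix(g, prof)
    sa <- stationary_distributions(tm)
    for (rho in sa$distributions) {
      for (n in 1:2) {
        expect_identical(verify_akin(rho, press_dyson(prof[[n]], g), tm), 0)
      }
    }
  }
  # perturbed rho is rejected with a diagnostic
  tm <- transition_matrix(g, profiles[[1]])
  sa <- stationary_distributions(tm)
  rho <- as.double(sa$distributions[[1]])
  rho[2] <- rho[2] + 0.1   # state (1,2): its Press-Dyson row is nonzero
  rho <- rho / sum(rho)
  expect_error(verify_akin(rho, press_dyson(dc$strategy, g), tm), "not stationary")
  # without the chain, the perturbed rho just yields a nonzero residual
  expect_gt(verify_akin(rho, press_dyson(dc$strategy, g)), 0)
})

test_that("simulation is reproducible and converges where it should", {
  ipd <- ipd_game()
  tft <- lapply(1:2, function(n) strategy_tit_for_tat(ipd, n))
  s1 <- simulate_play(ipd, tft, 500, seed = 42)
  s2 <- simulate_play(ipd, tft, 500, seed = 42)
  expect_identical(s1$state_freq, s2$state_freq)
  # TFT vs TFT from CC stays in CC: empirical e_1 = R = 3
  expect_identical(s1$payoffs, c(3, 3))
  expect_error(simulate_play(ipd, tft, 100), "seed")
  # ergodic chain: empirical payoffs within 3 SE of t(S) rho
  set.seed(9)
  prof <- list(random_strategy(ipd, 1, eps = 0.1), random_strategy(ipd, 2, eps = 0.1))
  tm <- transition_matrix(ipd, prof)
  sa <- stationary_distributions(tm)
  expect_true(sa$irreducible)
  e <- as.double(average_payoffs(sa$distributions[[1]], ipd))[-1]
  sim <- simulate_play(ipd, prof, 2e4, seed = 11)
  expect_true(all(abs(sim$payoffs - e) <= 3 * pmax(sim$payoff_se, 1e-3)))
})
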