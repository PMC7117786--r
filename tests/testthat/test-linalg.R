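test_that("column_space reports ranks, exact and float", {
  expect_identical(column_space(as_rational(diag(3)))$dim, 3L)
  dup <- as_rational(cbind(c(1, 2, 3), c(1, 2, 3), c(0, 1, 0)))
  expect_identical(column_space(dup)$dim, 2L)
  # float mode with near-dependent columns
  m <- cbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1e-12))
  expect_identical(mat_rank(m), 2L)
  # rock-paper-scissors payoff matrix has rank 2 (s2 = -s1)
  S <- payoff_matrix(fixture_game("rock_paper_scissors"))
  expect_identical(column_space(S)$dim, 2L)
})

test_that("null space and particular solutions are exact", {
  a <- as_rational(rbind(c(1, 2, 3), c(2, 4, 6)))
  ns <- null_space(a)
  expect_identical(ncol(ns$num), 2L)
  expect_true(all(r_mmul(a, ns)$num == 0))
  x <- solve_particular(as_rational(rbind(c(1, 1), c(1, -1))), as_rational(c(3, 1)))
  expect_true(all(x == as_rational(c(2, 1))))
  expect_null(solve_particular(as_rational(rbind(c(1, 1), c(1, 1))),
                               as_rational(c(0, 1))))
})

test_that("subspace intersection: worked examples and idempotence", {
  e <- as_rational(diag(3))
  a <- subspace(e[, 1:2])
  b <- subspace(e[, 2:3])
  i <- subspace_intersect(a, b)
  expect_identical(i$dim, 1L)
  expect_true(subspace_contains(i, rvec(0, 1, 0)))
  # a intersect a = a
  aa <- subspace_intersect(a, a)
  expect_identical(aa$dim, a$dim)
  expect_true(subspace_contains(aa, e[, 1, drop = TRUE]))
  expect_error(subspace_intersect(a, subspace(as_rational(diag(4)))),
               "ambient mismatch")
})

test_that("intersection agrees with the rank-formula oracle on random instances", {
  # oracle: dim(A ^ B) = dim A + dim B - rank([A B]); independent of the
  # stacked null-space route used by subspace_intersect
  set.seed(7)
  for (i in 1:25) {
    amb <- sample(3:9, 1)
    da <- sample(1:3, 1)
    db <- sample(1:3, 1)
    A <- rational(matrix(sample(-3:3, amb * da, replace = TRUE), amb, da))
    B <- rational(matrix(sample(-3:3, amb * db, replace = TRUE), amb, db))
    sa <- subspace(A)
    sb <- subspace(B)
    inter <- subspace_intersect(sa, sb)
    oracle <- sa$dim + sb$dim - mat_rank(r_cbind(sa$basis, sb$basis))
    expect_identical(inter$dim, as.integer(oracle))
    # every intersection basis vector is in both spans
    if (inter$dim > 0) {
      for (k in seq_len(inter$dim)) {
        v <- inter$basis[, k, drop = TRUE]
        expect_true(subspace_contains(sa, v))
        expect_true(subspace_contains(sb, v))
      }
    }
  }
})

test_that("generic 2-dim subspaces of R^9 meet only at zero", {
  set.seed(21)
  for (i in 1:5) {
    A <- rational(matrix(sample(-9:9, 18, replace = TRUE), 9, 2))
    B <- rational(matrix(sample(-9:9, 18, replace = TRUE), 9, 2))
    expect_identical(subspace_intersect(subspace(A), subspace(B))$dim, 0L)
  }
})

test_that("membership: zero vector, basis columns, and 1_M exclusion", {
  s <- subspace(as_rational(cbind(c(1, 1, 0), c(0, 1, 1))))
  expect_true(subspace_contains(s, rvec(0, 0, 0)))
  expect_true(subspace_contains(s, rvec(1, 1, 0)))
  expect_false(subspace_contains(s, rvec(1, 0, 0)))
})

test_that("rouche_capelli matches an independent solvability oracle", {
  # oracle: float least-squares residual of t(a_bar) e = -b via qr
  set.seed(13)
  for (i in 1:30) {
    n <- 3
    k <- sample(1:4, 1)
    a_bar <- matrix(sample(-4:4, n * k, replace = TRUE), n, k)
    b <- sample(-4:4, k)
    rc <- rouche_capelli(rational(a_bar), rational(b))
    # SVD pseudoinverse least-squares: independent of the rref route
    sv <- svd(t(a_bar))
    dinv <- ifelse(sv$d > 1e-9 * max(sv$d, 1), 1 / sv$d, 0)
    ls <- sv$v %*% (dinv * crossprod(sv$u, -b))
    resid <- max(abs(t(a_bar) %*% ls + b))
    oracle_consistent <- resid < 1e-6
    expect_identical(rc$consistent, oracle_consistent)
    if (rc$consistent) {
      chk <- r_mmul(t(rational(a_bar)), r_cbind(rc$particular))
      expect_true(all(chk == -rational(matrix(b, k, 1))))
    }
  }
})

test_that("rouche_capelli worked examples", {
  # single relation e_1 = e_2
  rc <- rouche_capelli(as_rational(matrix(c(1, -1), 2, 1)), as_rational(0))
  expect_true(rc$consistent)
  ns <- rc$nullspace
  expect_identical(ncol(ns$num), 1L)
  expect_true(ns[1, 1, drop = TRUE] == ns[2, 1, drop = TRUE])
  # contradictory pair e_1 = 0, e_1 = 1
  rc2 <- rouche_capelli(as_rational(matrix(c(1, 1), 1, 2)), as_rational(c(0, -1)))
  expect_false(rc2$consistent)
  expect_identical(rc2$rank_coeff + 1L, rc2$rank_aug)
  # K = 0: everything allowed
  rc3 <- rouche_capelli(matrix(0, 2, 0), numeric(0))
  expect_true(rc3$consistent)
  expect_identical(ncol(rc3$nullspace), 2L)
})

test_that("exact results are invariant to column scaling and order", {
  a <- rational(matrix(c(1, 2, 0, 1, 1, 1), 3, 2))
  scaled <- r_cbind(a[, 2, drop = FALSE] * rational(7, 3),
                    a[, 1, drop = FALSE] * rational(-2, 5))
  expect_identical(subspace(a)$dim, subspace(scaled)$dim)
  v <- rvec(3, 5, 1)
  expect_identical(subspace_contains(subspace(a), v),
                   subspace_contains(subspace(scaled), v))
})
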