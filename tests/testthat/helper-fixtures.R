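# shared fixtures: built in code, exact rationals throughout

ipd_game <- function(...) fixture_game("iterated_prisoners_dilemma", ...)

dc_default <- function() build_double_control(1, 2, 1/2, 1/4, 1/4, 1/2)

q <- function(p, d = 1) rational(p, d)

rvec <- function(...) as_rational(c(...))

# exact equality helper for rational/numeric vectors and matrices
expect_rat_equal <- function(x, y) {
  cm <- zdgames:::.common_mode(x, y)
  if (is_rational(cm$a)) {
    expect_true(all(cm$a == cm$b))
  } else {
    expect_equal(as.vector(cm$a), as.vector(cm$b), tolerance = 1e-9)
  }
}
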