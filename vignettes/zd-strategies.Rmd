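---
title: "Zero-determinant strategies as exact linear algebra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-determinant strategies as exact linear algebra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdgames)
```

## The model

An $N$-player repeated game without discounting: player $n$ has $M_n \ge 2$
actions, a joint action $\sigma = (\sigma_1,\dots,\sigma_N)$ lives in the
state space $\Sigma$ of size $M = \prod_n M_n$, and player $n$ earns
$s_n(\sigma)$ per round.  Play is *publicly monitored*: after each round a
common signal $\tau \in B$ is drawn with probability $W(\tau\,|\,\sigma')$,
and each player conditions her next action only on her own previous action
and that signal, through a memory-one table
$\hat T_n(\sigma_n\,|\,\sigma'_n,\tau)$.  Perfect monitoring is the special
case $B = \Sigma$, $W(\tau|\sigma') = \delta_{\tau,\sigma'}$.  The joint
action then follows a Markov chain with transition kernel
$T(\sigma|\sigma') = \sum_\tau W(\tau|\sigma')\prod_n \hat
T_n(\sigma_n|\sigma'_n,\tau)$, stored column-stochastic, `(to, from)`.

Three derived objects carry the whole analysis:

* the **marginal transition**
  $T_n(\sigma_n|\sigma') = \sum_\tau W(\tau|\sigma')\,
  \hat T_n(\sigma_n|\sigma'_n,\tau)$ — under imperfect monitoring this is
  *constrained* by $W$, which is exactly why the ZD strategy space shrinks
  relative to perfect monitoring (see `realize_marginal()`);
* the **Press–Dyson matrix** $\mathbb{T}_n$, $M \times M_n$, with columns
  $\tilde T_n(\sigma_n) = (T_n(\sigma_n|\sigma') -
  \delta_{\sigma_n,\sigma'_n})_{\sigma'}$.  Its rows sum to zero
  ($\mathbb{T}_n \mathbf{1}_{M_n} = \mathbf{0}_M$, so
  $\dim\mathrm{span}\,\mathbb{T}_n \le M_n - 1$), and the entry at
  $(\sigma',\sigma_n)$ is $\le 0$ when $\sigma'_n = \sigma_n$ and $\ge 0$
  otherwise;
* **Akin's lemma**, here in its public-monitoring form: every stationary
  distribution $\rho$ of the induced chain satisfies
  $\rho^\top \tilde T_n(\sigma_n) = 0$ for every player and action
  (`verify_akin()` returns the residual, identically zero in exact mode).

With $S = (\mathbf 1_M, s_1, \dots, s_N)$ and $e = (1, e_1, \dots, e_N)^\top
= S^\top\rho$ the long-run payoffs, a strategy is **zero-determinant** when
$V_n = \mathrm{span}\,\mathbb{T}_n \cap \mathrm{span}\,S$ is nontrivial:
each $u = S\alpha \in V_n$ forces $e^\top\alpha = \rho^\top S \alpha =
\rho^\top u = 0$, i.e. the linear payoff relation
$\alpha_0 + \sum_n \alpha_n e_n = 0$, unilaterally.

## What the package computes, and how

**Detection** (`compute_zd_subspace`).  $V_n$ is computed as a genuine
subspace intersection: solve the stacked homogeneous system
$[A\,|\,-B]x = 0$ for basis matrices $A$ of $\mathrm{span}\,\mathbb{T}_n$
and $B$ of $\mathrm{span}\,S$, and map the $A$-part back.  Each basis
vector $u_k$ carries two certificates that re-multiply exactly: $c_k$ with
$\mathbb{T}_n c_k = u_k$ and $\alpha_k$ with $S\alpha_k = u_k$.  When
$\mathrm{rank}\,S < N+1$ (zero-sum games such as rock–paper–scissors),
$\alpha_k$ is only determined up to $\mathrm{null}(S)$; the report carries
the ambiguity basis and an `ambiguous` flag rather than silently picking a
representative.

**Relations and consistency** (`enforced_relations`, `check_consistency`).
Relations are canonically scaled so the first nonzero coefficient is $+1$.
For a set of ZD players, a basis $u_1,\dots,u_K$ of the pooled span of the
$V_n$ is written as $u_k = S\alpha_k$; stacking
$A = \begin{pmatrix} b^\top \\ \bar A\end{pmatrix} =
(\alpha_1,\dots,\alpha_K)$, the payoffs must solve $\bar A^\top \bar e =
-b$, which is solvable iff $\mathrm{rank}\,\bar A = \mathrm{rank}\,A$
(Rouché–Capelli).  The solution set $E$ is returned as a particular point
plus a null-space basis.  That *every* ZD set passes this test is a
theorem, not an assumption — the test suite attacks it with 200 randomized
(game, ZD-set) instances and would fail on a single counterexample.

**Independence** (`check_independence`).  A set of ZD strategies is
independent when no selection of one nonzero vector per $V_n$ is linearly
dependent.  We implement the equivalent subspace condition: for every $n$,
$V_n \cap \mathrm{span}(\bigcup_{m\ne n} V_m) = \{0\}$.  Equivalence: if
some selection $\{v_n\}$ is dependent, a nontrivial vanishing combination
puts one $v_n$ (with nonzero coefficient) inside the span of the others;
conversely a nonzero $v_n$ in that intersection extends to a dependent
selection by choosing the combination's constituents for the players with
nonzero coefficients and arbitrary nonzero vectors (every $V_m$ has
dimension $\ge 1$) for the rest — zero *coefficients* are allowed, zero
*vectors* are not.  This is the joint reading of independence; the
pairwise reading would be strictly weaker for three or more players.
The sufficient hypothesis — no zero entries in any Press–Dyson column — is
reported alongside, and on dependence a witness selection is returned
(e.g. the mirrored tit-for-tat pair, whose witness is $v_2 = -v_1$).

**Existence** (`zd_existence`).  Under perfect monitoring the rows of
$\mathbb{T}_n$ at state $\sigma'$ are a free probability vector minus the
own-action indicator, so the value at $\sigma'$ of any column combination
$u = \mathbb{T}_n c$ sweeps exactly the interval
$[\min_i c_i - c_{\sigma'_n},\ \max_i c_i - c_{\sigma'_n}]$.  A ZD
strategy exists iff some $\alpha, c$ satisfy
$\min_i c_i - c_{\sigma'_n} \le (S\alpha)(\sigma') \le \max_i c_i -
c_{\sigma'_n}$ for all $\sigma'$ with $S\alpha \ne 0$.  We enumerate the
(argmin, argmax) pair of $c$ (ties to the lowest index; all ordered pairs),
pin $c_{\text{argmin}} = 0$, $c_{\text{argmax}} = 1$, and replace the
non-convex $S\alpha \ne 0$ by enumerating a coordinate and sign with
$|(S\alpha)(\sigma_0)| \ge 1$ — at most $M_n(M_n-1)\cdot 2M$ feasibility
LPs, each solved by the package's small two-phase simplex.  A positive
answer reconstructs a witness strategy (mixtures of the argmin/argmax
actions) and re-verifies it through `compute_zd_subspace`, exactly when the
rationalized LP point survives an exact constraint re-check.  Under
imperfect monitoring the constraint set is bilinear in $(c, \hat T)$; the
package offers only a clearly-labelled heuristic (random $c$ restarts, LP
over table and $\alpha$ at fixed $c$) whose negative answers are reported
as *inconclusive*, never as non-existence.

**Stationary verification** (`stationary_distributions`).  Recurrent
classes come from an exact boolean reachability closure; each class's
stationary distribution is the (one-dimensional) null space of $T - I$
restricted to the class, normalized exactly.  Reducible chains matter
here: the double-control chain against many opponents is reducible, and
every claim is verified on *every* extreme stationary distribution, plus
convex combinations.

## The double-control construction

In the symmetric $3\times 3$ game with
$s_1 = (0, r_1, 0, r_2, 0, 0, 0, 0, 0)^\top$,
$s_2 = (0, r_2, 0, r_1, 0, 0, 0, 0, 0)^\top$ (states in lexicographic
order, player 1 most significant), the strategy of
`build_double_control()` with parameters $0 \le p, q, p', q' \le 1$,
$q \le p$, $p' \le q'$, $p'q \ne pq'$ has Press–Dyson vectors that combine
to the payoff vectors themselves:

$$\frac{q'r_1 + qr_2}{p'q - pq'}\tilde T_1(1) +
  \frac{p'r_1 + pr_2}{p'q - pq'}\tilde T_1(2) = s_1,$$

and the mirrored combination gives $s_2$.  At
$(r_1, r_2, p, q, p', q') = (1, 2, \tfrac12, \tfrac14, \tfrac14, \tfrac12)$
the first coefficient is exactly $-16/3$.  Both identities are re-verified
in rational arithmetic inside the constructor, which refuses parameter
violations by naming the violated inequality.  Consequence: $\dim V_1 = 2$
and the enforced relations solve uniquely to $e_1 = e_2 = 0$ — one player
controls both payoffs.  In any *symmetric* two-player game this is the only
possibility ($e_1 = e_2 = C$): if player 1 could pin $(C_1, C_2)$ with
$C_1 \ne C_2$, symmetry would let player 2 pin $(C_2, C_1)$, contradicting
consistency.  A caution surfaced by testing: it is *not* true that every
zero-payoff state is absorbing under an arbitrary co-player strategy (the
co-player can move the state within the zero-payoff set); what holds, and
what the tests assert, is that every recurrent class yields
$e_1 = e_2 = 0$ exactly.

## Numerical design

* **Exact rationals.**  Values are reduced numerator/denominator pairs in
  doubles; any intermediate integer beyond $2^{50}$ raises an error rather
  than silently losing exactness.  Elimination is integer-preserving
  Gauss–Jordan: rows are cleared to integers, combined by coprime
  cross-multiplication, and divided by their gcd — entry growth then tracks
  minors (Bareiss) instead of squaring denominators.  Inputs given as
  integers, `"p/q"` strings, or exactly-representable decimals stay exact
  end-to-end; anything else stays floating with a relative rank tolerance
  of $10^{-9}$ (singular values / pivots below $10^{-9}\times$ scale count
  as zero).
* **Simplex.**  Two-phase dense tableau with Bland's rule (no cycling),
  free variables split, artificials driven out before phase 2; pivot
  tolerance $10^{-9}$.  LP answers feed exact re-verification wherever an
  exact claim depends on them, so float LP never decides an exact question
  by itself on the positive side; infeasibility (e.g. rock–paper–scissors,
  all 108 LPs) rests on the phase-1 optimum being bounded away from zero.
* **Ties and canonical forms.**  rref pivots take the first nonzero (exact)
  or largest-magnitude (float) candidate; relation vectors are scaled to a
  leading $+1$; argmin/argmax enumeration resolves ties to the lowest
  index but covers all ordered pairs anyway, so tie-breaking cannot lose
  solutions.
* **Degenerate inputs.**  $r_1 = \pm r_2$ collapses the two-relation game
  to rank-2 $S$ (warning + `degenerate` flag); $p'q = pq'$ is a hard
  degeneracy error; reducible chains are the expected case, not an error.

## Synthetic data: what the generators emulate

`random_strategy()` draws each conditional distribution uniformly from the
simplex (normalized exponentials), optionally bounded away from zero by
`eps` — the regime in which the independence proposition's hypothesis (no
zero Press–Dyson entries) holds — and rounds to denominator 16 (60 in the
eps regime) so that downstream algebra is exact.  `random_zd_set()` builds
the randomized (game, ZD-set) instances for the property sweeps from three
families: random-payoff 2×2 games with one or two LP-generated exact ZD
players (`random_zd_strategy()`, a max-margin LP whose optimum is snapped
to a coarse rational grid and re-verified exactly), and double-control
instances with random admissible parameters.  What a green sweep
establishes: the consistency and independence theorems hold on 200
instances of these families with exact arithmetic.  What it does not:
coverage of large $N$, large action spaces, or imperfect-monitoring ZD
sets — the families are 2–3 actions, 2 players, perfect monitoring,
because that is where exact ZD strategies can be constructed
systematically.  The `winner_signal_game` fixture (bids, prize, and a
winner/tie-only public signal) is this package's own synthetic stand-in
for auction-style monitoring; it is not transcribed from any published
example.

## Limitations

* No discounting ($\delta = 1$ only) and memory-one strategies only.
* The existence decision is complete only under perfect monitoring; the
  imperfect-monitoring search is a labelled heuristic.
* Exact mode is bounded by the $2^{50}$ integer guard; pathological
  denominator growth (e.g. many-pivot eliminations on fine-grained random
  rationals) errors out rather than degrading — re-run such cases in float
  mode or with coarser strategy grids.
* The impossibility statements for $N$-dimensional ZD strategies in weakly
  symmetric games are exercised empirically on small games (no witness of
  dimension $N$ is ever found under their hypotheses); the package proves
  nothing, it checks.
* Brute-force existence grids are sound but incomplete certificates; the
  LP is the decision procedure (see the test suite's two-directional
  agreement checks).
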