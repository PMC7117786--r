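# zdgames

Exact linear-algebraic analysis of **zero-determinant (ZD) strategies** in
repeated games — for game theorists and evolutionary-dynamics researchers who
want to *verify*, not just simulate, payoff-control claims.

## The problem

In an infinitely repeated game without discounting, a memory-one strategy of
player *n* is summarized by its **Press–Dyson matrix**
𝕋ₙ = (T̃ₙ(1), …, T̃ₙ(Mₙ)), whose column for action σₙ is the marginal
transition probability minus the "Repeat" indicator:

    T̃ₙ(σₙ | σ′) = Tₙ(σₙ | σ′) − δ(σₙ, σ′ₙ),
    Tₙ(σₙ | σ′) = Σ_τ W(τ | σ′) T̂ₙ(σₙ | σ′ₙ, τ),

where W(τ | σ′) is a public-monitoring signal kernel (perfect monitoring is
W(τ | σ′) = δ(τ, σ′)). **Akin's lemma** says every stationary distribution ρ
of the induced Markov chain satisfies ρᵀT̃ₙ(σₙ) = 0.  With
S = (1_M, s₁, …, s_N) the payoff-state matrix and e = Sᵀρ the long-run
payoff vector, a strategy is **zero-determinant** when

    Vₙ = span(𝕋ₙ) ∩ span(S)  has  dim Vₙ ≥ 1:

every u = Sα in Vₙ then forces the linear payoff relation
α₀ + Σₙ αₙ eₙ = 0 on *all* stationary outcomes, whatever the co-players do.
The package detects this exactly, extracts and solves the enforced
relations, decides **consistency** of multi-player ZD sets by the
Rouché–Capelli rank test, decides **independence**, searches a game for ZD
**existence** by linear programming, and verifies everything against the
exact stationary distributions of the induced chain (including reducible
chains) and by Monte-Carlo simulation.

All fixture arithmetic is exact: probabilities and payoffs given as
rationals stay rationals end-to-end, so `dim V`, ranks, and stationary
payoffs are computed without tolerances.

## Worked example

Tit-for-tat in the iterated prisoner's dilemma, payoffs
s₁ = (3, 0, 5, 1), s₂ = (3, 5, 0, 1) over (CC, CD, DC, DD):

```r
library(zdgames)
ipd  <- fixture_game("iterated_prisoners_dilemma")
tft  <- strategy_tit_for_tat(ipd, 1)
report <- compute_zd_subspace(tft, ipd)
report
#> <zd_report: player 1, dim V = 1 (ZD), rank S = 3, exact mode>
enforced_relations(report, ipd)[[1]]
#> (0)*1 + (1)*e_1 + (-1)*e_2 = 0
```

Tit-for-tat is ZD with a one-dimensional enforced subspace, pinning
e₁ = e₂.  A three-action player can enforce **two relations at once**: in
the symmetric 3×3 game with s₁ = (0, r₁, 0, r₂, 0, …, 0),
s₂ = (0, r₂, 0, r₁, 0, …, 0), the double-control strategy gives

```r
dc <- build_double_control(r1 = 1, r2 = 2, p = 1/2, q = 1/4,
                           p_prime = 1/4, q_prime = 1/2)
dc$report
#> <zd_report: player 1, dim V = 2 (ZD), rank S = 3, exact mode>
format(dc$coefficients$s1)    # exact combination coefficients giving s1
#>      [,1]    [,2]
#> [1,] "-16/3" "-20/3"
```

so player 1 alone pins e₁ = e₂ = 0 — confirmed on the actual chain against
a uniformly random opponent:

```r
tm <- transition_matrix(dc$game, list(dc$strategy, strategy_uniform(dc$game, 2)))
sa <- stationary_distributions(tm)
format(average_payoffs(sa$distributions[[1]], dc$game))
#> [1] "1" "0" "0"     # (1, e_1, e_2): both payoffs exactly zero
```

Existence queries: `zd_existence(fixture_game("rock_paper_scissors"), 1)`
decides (all 108 enumeration LPs infeasible) that rock–paper–scissors
admits **no** ZD strategy, while the IPD and the two-relation game do.

## Command line

```sh
Rscript inst/cli/zd-tool.R --command detect-zd \
  --fixture iterated_prisoners_dilemma --strategy tit_for_tat,repeat \
  --player 1 --out report.json
```

Commands: `validate`, `detect-zd`, `relations`, `consistency`,
`independence`, `exists-zd`, `symmetry`, `stationary`, `simulate`,
`double-control`.  Games load from JSON (see `inst/extdata/ipd.json`;
rationals as `"p/q"` strings).

## Layout

- `R/rational.R`, `R/linalg.R` — exact rational kernel; rref, null spaces,
  subspace intersection, Rouché–Capelli.
- `R/game.R`, `R/strategy.R` — games, signal kernels, memory-one
  strategies, Press–Dyson matrices, marginal realizability.
- `R/markov.R` — induced chain, recurrent classes, exact stationary
  distributions, Akin residuals, simulation.
- `R/zd.R`, `R/existence.R`, `R/sweeps.R` — ZD detection, relations,
  consistency, independence, symmetry, existence search, property-sweep
  instance generator.
- `R/cli.R`, `inst/cli/zd-tool.R` — requests, reports, command line.
- `vignettes/zd-strategies.Rmd` — the methods vignette: model, algorithms,
  numerical design, limitations.
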