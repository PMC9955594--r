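# castvote

Optimal sequential decision-making and the casting-vote algorithm.

## The problem

A group of `N` respondents answers a binary question (one option correct,
one wrong) *in order*. Respondent `n` has an **ability** `p_n ∈ (0.5, 1)` —
the probability that their private, independent guess (their **primary
choice**) is correct — and, before answering publicly, sees the answers of
all earlier respondents. Everyone knows everyone's abilities, assumes their
antecedents answered optimally, and answers so as to maximise their own
probability of being correct.

The key structural fact is that each respondent's optimum is all-or-nothing:
either answer the primary choice regardless of the antecedents (a **casting
voter**, whose answer therefore reveals their primary choice), or copy the
side favoured by the antecedent evidence and ignore the primary choice
entirely (a **non-casting voter**, whose answer carries no new information).
Writing `r*_m = log(p_m / (1 − p_m))` for the log-odds weight of respondent
`m`, and `S`, `T` for the sets of earlier casting voters whose answers match
/ oppose the first answer, the rule for respondent `n` is

```
Δ = Σ_{m∈S} r*_m − Σ_{m∈T} r*_m
|Δ| < r*_n  →  casting voter: answer the primary choice
otherwise   →  non-casting voter: answer the side of sign(Δ)
```

and the likelihoods of the two options given the observed answers are
`L_s = Π_{m∈S} p_m Π_{m∈T} (1 − p_m)` and its mirror image — products over
**casting voters only**. Iterating the rule classifies the whole chain
(`run_sequence()`), gives each respondent's conditional performance
`π_n = max(L·p_n, L'·(1 − p_n)) / (L·p_n + L'·(1 − p_n))`, and exposes the
phenomena the package quantifies:

- in an equal-ability chain the casting-vote count difference
  `d_n = |S| − |T|` is a random walk absorbed at ±2, so collective
  intelligence stops improving once two casting votes separate the options;
  mean performance approaches the ceiling `π_max(p) = p²/(p² + (1 − p)²)`,
  worth only a simultaneous majority of 5–7 independent voters
  (`effective_voters()`, `crossing_ability()`);
- with three respondents, the third's mean performance drops sharply as
  soon as the first respondent is abler than the second, because the second
  then follows blindly and an information cascade forms
  (`three_person_analysis()`);
- a lone expert among equals gains from answering later if modestly better,
  but an *unrecognised* expert (`q > π_max(p)`, unaware) loses accuracy the
  later they answer (`expert_performance()`).

## Worked example

```r
library(castvote)

prof <- generate_profile("equal", n = 5, p = 0.7)
run_sequence(prof, c("s", "t", "t", "t", "s"))
#> <seq_result: 5 respondents, casting S = {1}, T = {2, 3, 4}, non-casting R = {5}>
#> # A tibble: 5 × 6
#>   order ability primary answer is_casting conditional_performance
#>   <int>   <dbl> <chr>   <chr>  <lgl>                        <dbl>
#> 1     1     0.7 s       s      TRUE                         0.7
#> 2     2     0.7 t       t      TRUE                         0.5
#> 3     3     0.7 t       t      TRUE                         0.7
#> 4     4     0.7 t       t      TRUE                         0.845
#> 5     5     0.7 s       t      FALSE                        0.7
```

Respondents 2–4 are casting voters (their answers expose their primaries);
after three `t` votes against one `s` the difference hits −2, so respondent
5 ignores their own primary and copies `t`. The conditional performances are
the posterior probabilities of being right given what each respondent saw:
respondent 4, looking at a 1–2 split plus their own primary, reaches the
two-agree posterior 0.845 = π_max(0.7).

Exact enumeration, the closed form, and simulation agree:

```r
exact_curve(prof)$performance
#> [1] 0.700 0.700 0.784 0.784 0.81928
mean_performance_equal(0.7, 1:5)
#> [1] 0.700 0.700 0.784 0.784 0.81928
tidy(simulate_chain(prof, n_runs = 10000, seed = 1))
```

and the simultaneous-voting comparison shows how little an infinite chain
is worth:

```r
effective_voters_curve(c(0.6, 0.7, 0.8, 0.9))
#> # A tibble: 4 × 4
#>       p pi_max   n_e majority_at_ne
#>   <dbl>  <dbl> <int>          <dbl>
#> 1   0.6  0.692     7          0.710
#> 2   0.7  0.845     7          0.874
#> 3   0.8  0.941     5          0.942
#> 4   0.9  0.988     5          0.991
```

A thin command-line wrapper lives at `inst/scripts/castvote`
(`castvote simulate --kind equal --p 0.7 --n 20 --runs 10000 --seed 42
--out sim.csv`).

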