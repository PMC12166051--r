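# ynat

Simulation and repetition-bias modelling for the Y-navigation task.

## The problem

People tend to repeat action sequences they have performed before — the
*law of exercise* — independently of whether those sequences were
rewarded.  Separating this repetition bias from ordinary goal-directed
reward seeking requires a task in which the two pull apart, and a choice
model in which each has its own parameter.  `ynat` is for computational
cognitive modellers who want to simulate such a task, fit the competing
models, and validate the whole pipeline on synthetic cohorts before
touching real data.

The task: a player crosses a 5-by-5 grid with exactly four moves drawn
from {up-left `L`, down `D`, up-right `R`}, collecting the point circle of
every visited cell, to match a trial-specific goal.  Leaving the grid or
revisiting a cell is forbidden; from the grid-center start exactly 36
four-move sequences are valid.  Rows are numbered 0–4 top to bottom, so
`D` is +1 row.  A highlighted *default action sequence* (DAS, default
`DDRR`) has a constant expected point sum (default 120) and earns a
probabilistic +20 bonus (p = 0.25) in half the blocks.  The trial reward
is

    Reward_t = max{0, 100 − 2·|Goal_t − Points_t|}.

## The model

The repetition-bias model (EVPRM) scores each sequence π by a
precision-weighted expected-reward term times a count-based prior:

    p(π | R̂, α) ∝ ( R̂_π / Σ R̂ )^β · ( α_π / Σ α ),   α_π = 1/h + γ_π

where γ_π counts past uses of π, β is the precision over expected
rewards, and h ∈ (0,1] is the repetition bias strength.  Expected rewards
use the sequence's observed point sum within the current block and an
approximated reward R₀ for unobserved sequences.  Nested alternatives
drop the prior (EVPM), replace it with a constant DAS bias (EVPBM), use
exact rewards for all sequences (EVM), or respond uniformly (UNIFORM).
Fitting is Bayesian per participant (MAP, Laplace, or adaptive-Metropolis
MCMC) under weakly informative priors; model comparison uses PSIS-LOO.

## Worked example

```r
library(ynat)

design  <- build_default_design()               # frozen 16 x 20 session
agent   <- model_params("EVPRM", beta = 5, r0 = 70, h = 0.91)
session <- simulate_agent(agent, design, seed = 1)

summarize_participant(session, design)
#> Participant agent_1
#>   p(DAS) 0.466 (halves 0.325 / 0.606)  partial-DAS 0.697
#>   distinct sequences 31  mean reward 51.4  timeouts 0

fit_map("EVPRM", session, design, seed = 1)
#> MAP fit: EVPRM on 320 trials
#>   log-posterior: -710.91  log-likelihood: -705.48
#>   EVPRM ( beta = 4.48, r0 = 66.25, h = 0.7353 )

psis_loo(fit_laplace("EVPRM", session, design, seed = 1))
#> PSIS-LOO over 320 trials ( 400 draws )
#>   elpd_loo -708.07 (SE 30.21)  p_loo 2.16  looic 1416.15
```

The summary shows the hallmark of a strong repetition bias: DAS usage
rising from 0.33 in the first half of the session to 0.61 in the second,
even though the goal structure repeats across halves.  The fit recovers a
high repetition strength (h ≈ 0.74 for a generating value of 0.91 —
strong biases are systematically underestimated) and a precision near the
generating β = 5.  The LOOIC of 1416 compares against the uniform
baseline's closed form 2·320·ln 36 ≈ 2293.5.

Other entry points: `simulate_cohort()` (multi-agent tables),
`fit_mcmc()` (posterior draws with split-R̂ diagnostics),
`compare_models()` (group and per-participant LOOIC tables),
`ppc_match()` (posterior predictive choice-match rates),
`run_parameter_recovery()` / `run_model_recovery()` (validation
pipelines), `reproduce_session_dynamics()` (the rise of the DAS prior
over a session), and CSV/JSON round-trips via
`write_participant_table()` / `read_participant_table()` /
`write_design_json()`.

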