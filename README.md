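# bedalloc

Data-driven allocation of scarce inpatient beds between **urgent** and
**regular** elective patients.

Large public hospitals run their specialty wards at essentially 100%
occupancy with hundreds of patients backlogged on the waiting list. Every
morning a bed manager must decide, before knowing how many beds today's
discharges will free or how many new requests will arrive, how much of the
expected capacity to offer to urgent patients (who deteriorate while
waiting) versus regular patients (who can wait). Public hospitals must
balance revenue against equity, which the models here fold into a single
*adjusted per-unit revenue* per admission, `r1` for urgent and `r2` for
regular with `r1 > r2`: the urgent premium is priority, not money.

`bedalloc` is for health-operations researchers and bed managers who want
to evaluate such allocation rules on historical or synthetic demand data.
It provides three model layers, all driven by data rather than assumed
distributions:

1. **Single-period two-class newsvendor.** Split `K` beds to maximise
   `r1·E[min(D1, Q1)] + r2·E[min(D2, K − Q1)]`. Solvers: `solve_exact()`
   (exact integer sweep for any discrete demand distribution, using
   `E[min(D, Q)] = Σ_{j<Q} P(D > j)`), `solve_saa()` (sample-average
   approximation on demand histories), and `solve_ko()` (kernel
   optimization: maximise the Nadaraya–Watson estimate of the conditional
   expected revenue given features such as day of week and season). The
   first-order balance condition `r1·P(D1 ≥ q) = r2·P(D2 ≥ K − q)` is
   available as a verification predicate (`balance_condition()`).
2. **Multiperiod admission with random capacity.** State
   `(B, X, W1, W2)`; each period a fraction `α` of the free-plus-released
   beds is protected for the urgent class, with same-day spillover of
   unused protection. `evaluate_improvement()` benchmarks the one-step
   kernel-optimization policy (`policy_ko()`) against the incumbent
   fixed-ratio policy (`policy_fa()`) over hundreds of simulated episodes
   with common random numbers.
3. **Multiperiod revenue + equity.** Day-of-week reservation quotas,
   waiting costs `ρ1, ρ2` and an extra-bed (corridor-bed) penalty `b`;
   `run_horizon()` evaluates a control `(ξ, α, β1..β5)` on a hospital
   trace, and `sweep_controls()` / `sweep_cost()` produce the sensitivity
   tables and the optimal reservation curve `ξ*(b)`.

Because the hospital records the models were built around are restricted,
the package ships calibrated synthetic generators (`gen_sinusoidal_demand()`,
`gen_released_beds()`, `gen_feature_history()`, `gen_hospital_trace()`)
plus waiting-list CSV ingestion (`read_waiting_list()`,
`aggregate_to_trace()`) for real data in the same schema.

## Worked example

```r
library(bedalloc)

# one year of weekday-tagged two-class demand
hist <- gen_feature_history(260, seed = 42)
prob <- two_class_problem(K = 25, r1 = 3, r2 = 1)

solve_saa(hist$D1, hist$D2, prob)
#> <bed_allocation> [ saa ] Q1 = 8  Q2 = 17  objective = 32.8308

x_new <- hist[260, c("weekday", "season_sin", "season_cos")]
solve_ko(hist, x_new, prob)
#> <bed_allocation> [ ko ] Q1 = 7  Q2 = 18  objective = 33.4064
```

Ignoring features, 8 of the 25 beds would be protected for urgent demand;
conditioning on tomorrow's weekday and season shifts one bed to the
regular class and raises the estimated expected adjusted revenue from
32.8 to 33.4 (in `r`-units per day).

```r
evaluate_improvement(c(5, 10, 20), n_instances = 100, seed = 7)
#>    K ko_reward fa_reward improvement_pct          se
#> 1  5    174.54    164.12       6.3490129 0.258824502
#> 2 10    376.00    344.78       9.0550496 0.327198371
#> 3 20    544.51    544.45       0.0110203 0.006297974
```

The kernel policy beats the fixed 60/40 split by 6–9% while beds are
scarce relative to demand and by nothing once capacity is ample — adaptive
allocation pays exactly where preemption between the classes matters.

```r
tr  <- gen_hospital_trace(193, seed = 11)       # saturated 140-bed unit
glance(run_horizon(tr, equity_params()))
#>       f f_total     T    xi alpha     b mean_extra mean_holding
#> 1 -447.  -86293   193     0     1   500       2.70        0.715
```

At the default cost rates, exhausting all predicted capacity every day
(`ξ = 0`) loses money: about 2.7 corridor beds per day at `b = 500` per
bed-day overwhelm the admission revenue. Sweeping the reservation
proportion against the extra-bed rate:

```r
cs <- sweep_cost(tr, equity_params(alpha = 1, beta = rep(0, 5)),
                 b_grid = c(500, 900, 1300), xi_grid = seq(0, 0.5, 0.1))
attr(cs, "xi_star")
#>       b xi_star f_star
#> 1   500     0.4   703.
#> 2   900     0.4   691.
#> 3  1300     0.4   679.
```

reserving ~40% of predicted capacity is optimal across this range, and
the optimal reservation never decreases as corridor beds get more
expensive — a structural property the test suite verifies along with the
exact conservation `B1 + B2 + X = K` and the affinity of the objective in
`b`.

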