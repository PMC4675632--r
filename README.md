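# aversim

Simulation of aversive behaviour as a competition between **goal-directed**
and **Pavlovian** control, arbitrated by **controllability** and **threat
distance**.

## The problem

Aversive behaviour in animals is not one system. A rat that has learned which
lever avoids a shock can plan prospectively; the same rat, facing a cue it
cannot control, freezes — an innate Pavlovian reaction that is often
maladaptive (freezing instead of acting guarantees the shock). Classic
phenomena — Pavlovian interference with avoidance, increased fear under
uncontrollable punishment, learned helplessness transferring to novel
contexts, freezing when threats are imminent but risk assessment when they
are distant — all hinge on *which controller is in charge, when*. aversim
implements a computational model of that arbitration and the simulated-rat
avoidance experiments that probe it, for researchers in computational
cognitive neuroscience and reinforcement learning who want a reproducible,
scriptable test bed.

## The model

Per trial, a cue `c` appears and both controllers run:

- **Goal-directed**: learned transition counts give
  `P(outcome | c, a)`; learned outcome values `v(o)` (delta rule on received
  reinforcers) give a planning buffer `q(a) = Σ_o P(o|c,a) v(o)`; a plan is
  sampled by softmax with temperature `τ`.
- **Pavlovian**: a learned cue value `pv(c)` (delta rule on received
  reinforcers) drives a fixed innate response (freezing) with activation
  `pv(c)`.
- **Arbitration**: instrumental ability
  `IA = b + w_gdp·max_a q(a) + w_sc·SC + w_pr·pv(c) + w_gc·GC + w_tstd·TSTD`,
  where `SC = max q − min q` (specific controllability), `GC` is a slow
  running average of `SC` that survives context switches (generalised
  controllability), and `TSTD` scales with the signalled delay to threat.
  Behaviour is goal-directed with probability `σ(IA)`, otherwise Pavlovian.

After acting, the experienced transition count, the outcome value, the cue's
Pavlovian value, and `GC` are updated — strictly after all decisions, from
pre-update predictions.

Five preset experiments (`run_sim1()` … `run_sim5()`) cover goal-directed
acquisition, Pavlovian interference (the freezing "vicious circle"),
specific controllability with matched shock rates, learned helplessness with
yoked 500- vs 7000-trial uncontrollable pretraining, and threat-distance
modulation with signalled 3 s vs 30 s delays. See the vignette
(`vignettes/aversive-arbitration.Rmd`) for the full model account and the
calibration of the default parameters.

## Worked example

A single agent on the Pavlovian-interference task:

```r
library(aversim)
library(dplyr)

run <- run_agent(task_sim2(n_per_cue = 1000), agent_config(), seed = 11)
glance(run)
#> # A tibble: 1 × 7
#>   task   seed n_trials shock_rate p_goal_directed f_goal_directed gc_final
#>   <chr> <int>    <int>      <dbl>           <dbl>           <dbl>    <dbl>
#> 1 sim2     11     2000      0.488           0.900           0.901    0.585
```

Half the trials end in shock: the black cue's best action still fails 80% of
the time. Control is goal-directed on 90% of trials overall — but not under
the black cue, and decreasingly so:

```r
run$trace |>
  filter(cue == "black") |>
  summarise(
    p_goal_directed_first100 = mean(p_goal_directed[1:100]),
    p_goal_directed_last100  = mean(p_goal_directed[(n() - 99):n()]),
    pv_final                 = pv_post[n()]
  )
#> # A tibble: 1 × 3
#>   p_goal_directed_first100 p_goal_directed_last100 pv_final
#>                      <dbl>                   <dbl>    <dbl>
#> 1                    0.863                   0.798   -0.929
```

The cue's Pavlovian value has sunk to −0.93 — close to the certainty of
shock while freezing — and goal-directed control has eroded from 0.86 to
0.80 and keeps falling: freezing causes shocks that further depress the value
that causes freezing.

Multi-seed experiments return per-seed summary tibbles and ggplot methods:

```r
s3 <- run_sim3(seeds = 1:5)
s3
#> <aversim_sim> sim3: 5 seeds, 10000 trials total
#> # A tibble: 10 × 5
#>     seed cue       sc p_goal_directed f_goal_directed
#>    <int> <chr>  <dbl>           <dbl>           <dbl>
#>  1     1 black 0.168            0.681           0.627
#>  2     1 red   0.0151           0.636           0.65
#>  3     2 black 0.214            0.725           0.745
#>  4     2 red   0.0343           0.655           0.675
#> # …
autoplot(s3)
```

Both cues shock 80% of the time under the best action, but the black cue —
where one action is better than the others — retains more goal-directed
control (`p_goal_directed` ≈ 0.70 vs 0.64) and a wider value spread
(`sc` ≈ 0.19 vs 0.03): controllability, not punishment rate, drives the
difference.

A thin CLI wraps the runners:

```sh
Rscript inst/cli/aversim.R run sim4 --seeds 20 --out out/ --plot
Rscript inst/cli/aversim.R sweep sim5 --grid grid.csv --seeds 5 --out out/
```

Task contingencies are plain YAML (`inst/extdata/sim*.yaml`) and can be
edited or written from scratch (`read_task_spec()` / `write_task_spec()`).

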