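# homestay

Digital-phenotyping pipeline linking **homestay** (the fraction of time a
person spends at their inferred home, a passive-sensing proxy for social
isolation) to **state affect** (momentary positive/negative ratings from
ecological momentary assessment), moderated by trait **social anxiety**
(SIAS, 0–80) and **depression** (DASS-21 depression subscale, 0–21).

It is written for researchers running ambulatory mobile-sensing studies:
smartphones record a GPS fix roughly every 150 seconds and prompt
participants up to 6 times per day (random times inside six 2-hour windows,
9 AM–9 PM) for visual-analog affect ratings coded 0–100. The package turns
those raw streams into a reproducible analysis, and ships a synthetic-cohort
generator with known ground truth so every stage is testable without any
participant data.

## The pipeline

1. **simulate** *(optional)* — generate a cohort (default 63 participants ×
   14 days) with home-anchored mobility, jittered GPS fixes, gap-run
   missingness, partial EMA compliance, and a configurable latent coupling
   between affect and homestay.
2. **preprocess** — cluster fixes into stay points (sequential scan, 30 m
   spatial threshold; stays under 5 min dropped as travel; same-place visits
   ≤ 30 min apart merged), infer home as the cluster holding the most
   nighttime (12–6 AM) fixes, impute data gaps by last observation carried
   forward, and audit completeness over the 10 AM–6 PM workday (192 possible
   fixes at 150-s sampling).
3. **features** — build analysis windows: consecutive-prompt pairs up to 4 h
   apart (affect change scores) and daily workday windows aligned to
   same-day, next-day and previous-day affect means. The continuous outcome
   is each window's home fraction divided by the participant's study-wide
   average (log-transformed, T = log(frac/personal_avg + ε)); the binary
   outcome is "any time at home in the window".
4. **fit** — generalized mixed models, e.g. for negative affect:

   `T_si = β₀ + β₁·NA + β₂·SIAS + β₃·DASS + β₄·NA×SIAS + β₅·NA×DASS + S_0s + D_0i + e_si`

   with crossed random intercepts `S_0s ~ N(0, τ²₀₀)` for subject and
   `D_0i` for calendar day (plus a window-length random slope in the 4-hour
   framing), REML for the Gaussian models and Laplace-approximate ML for the
   logistic ones, Wald z tests, and a marginal (fixed-effects) R².
   2 outcomes × 4 temporal framings × 2 affect variables = 16 fits → 48
   reported effects. Separate between-subjects models regress raw homestay
   on the two traits.
5. **report** — assemble the 48-effect table, count significances at
   α = .05, and compare that count against chance with an exact
   Binomial(48, .05) upper tail (in the reference study, 8 of 48 effects
   were significant; P(X ≥ 8) = 0.00245).

## Worked example

Simulate a world where negative affect on a day is coupled to the *next*
day's homestay, more strongly for socially anxious participants, then run
the whole pipeline in-process:

```r
library(homestay)
cfg <- hs_config(seed = 20, coupling_na = 10, moderation_na_sias = 25,
                 coupling_lag = 1L)
out <- run_pipeline(cfg, "demo-run")
print(out$summary)
out$table[significant == 1]
```

Output from that exact run:

```
6 of 48 effects significant at alpha = 0.05; P(X >= 6) = 0.0317095
      outcome  framing      term       beta            p significant
1: continuous same_day NA x SIAS 0.07714829 2.711549e-02           1
2: continuous next_day        NA 0.14199150 2.769219e-04           1
3: continuous next_day NA x SIAS 0.27860420 1.409172e-15           1
4:     binary same_day NA x SIAS 0.01852054 2.672316e-02           1
5:     binary next_day        NA 0.02217486 3.229978e-02           1
6:     binary next_day NA x SIAS 0.06258135 1.749606e-08           1
```

The injected signal surfaces where it should: the next-day NA main effect
and the NA × SIAS interaction, in both the continuous (standardized beta)
and binary (unstandardized logit beta) panels, and the binomial summary
flags the excess over the 2.4 hits expected by chance. With all couplings
at their default of 0 the same pipeline returns 0–4 significant effects
(5% of 48 ≈ 2.4 expected). `demo-run/` also contains `effects.csv`,
`binomial.txt`, per-stage logs, and `interaction_next_day.pdf` (predicted
next-day home probability at ±1 SD of SIAS).

The same five stages are available as a file-based CLI
(`inst/cli/homestay`): `simulate`, `preprocess`, `features`, `fit`,
`report`, each taking `--config`, `--in`, `--out`.

## Documentation

`vignettes/homestay-methods.Rmd` describes the generative model, the
preprocessing rules and their rationale, the model grid, numerical choices,
and what the synthetic tests do and do not establish.
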