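# allonurse

Tools for testing which decision rules drive allonursing — a lactating
female nursing another mother's offspring — in plural-breeding mammals.
Three mechanistic rules are distinguished:

* **direct reciprocity** — help someone who previously helped you;
* **generalized reciprocity** — help anyone if helped by someone;
* **kin discrimination** — preferentially help closer kin.

The package takes behavioral event logs (solicitations scored as bouts,
rejections or attempts), mother attribute tables and pairwise genetic
relatedness matrices, and carries them through the full analysis chain:
event scoring, ordered-dyad help counts, the reciprocity index, dominance
hierarchies, the mixed-model battery, latency rules and a cross-group
meta-analysis. A decision-rule simulator generates event streams with
known parameters so every stage can be validated by parameter recovery.

## The statistics in brief

**Reciprocity index.** For an unordered pair of mothers {A, B} with
`a_AB` allonursing bouts given by A to B's offspring and `a_BA` in the
other direction, the reciprocal allonursing frequency index is

```
RAFI = 1 - | a_AB/(a_AB + a_BA) - a_BA/(a_AB + a_BA) |
```

0 means strictly one-sided helping, 1 complete reciprocation; values >=
0.5 indicate a tendency to reciprocate and >= 0.8 strong reciprocity.
The index is undefined for dyads that never exchanged help.

**Models.** Help given within ordered dyads is modelled by Poisson (or,
under overdispersion, negative binomial) mixed models with the
help-received x relatedness interaction, absolute rank difference,
offspring sex similarity and birth-mass difference as fixed effects and
both dyad members as random intercepts; the likelihood of a successful
solicitation by logistic mixed models with RAFI and relatedness;
RAFI x 100 (rounded) as a count response on relatedness; per-mother
totals with a log observation-days offset for generalized reciprocity;
and log latencies (direct vs generalized pairing of each given bout with
the most recent receipt) by a Gaussian mixed model. Exponentiated
coefficients are reported as incidence rate ratios / odds ratios with
95% Wald intervals, plus Nakagawa's conditional R², Pearson dispersion,
VIF, |z| > 3.3 outlier screens and case-deletion influence measures with
cutoffs 2/sqrt(N) and 4/N.

**Meta-analysis.** Per-group effects are pooled on the log scale by
fixed-effect inverse variance (weights 1/SE²), with Cochran's Q,
DerSimonian–Laird tau² (Q-profile CI), I² and H (Higgins–Thompson
test-based CIs).

**Dominance.** Win/loss matrices from resolved agonistic interactions,
Landau's linearity index `h = 12/(N³-N) * sum_a (V_a - (N-1)/2)²`, and
integer ranks (largest = most dominant).

## Worked example

Simulate a study season under a pure direct-reciprocity rule and fit the
dyadic count model:

```r
library(allonurse)

cfg <- sim_config(delta_direct = 1.2, seed = 7)   # 25 mothers, 65 days
sim <- simulate_group(cfg)
sim
#> sim_output: group G2012, 25 mothers, 65 days
#>   8930 solicitations (2303 allonursing bouts), 4446 agonistic interactions

dy  <- build_dyad_table(sim$events, sim$mothers, sim$relatedness)
fit <- fit_glmm(model_spec(
  "a_ij", "poisson",
  fixed  = c("received", "r", "abs_rank_diff", "sex_similarity", "birth_mass_diff"),
  random = c("giver_id", "receiver_id")), dy)
fit$exponentiated[fit$exponentiated$term %in% c("received", "r"), ]
#>   term      ratio    ci_low  ci_high
#>   received  1.053    1.031    1.074
#>   r         1.248    0.540    2.882
```

The help-received incidence rate ratio of 1.05 (95% CI 1.03–1.07) says a
mother is expected to give about 5% more allonursing per extra bout
received from the same partner — the direct-reciprocity signature the
generator planted — while relatedness shows no effect (`kappa_kin = 0`
in this world). The latency comparison separates the two reciprocity
rules:

```r
lat <- rbind(direct_latencies(sim$events, sim$mothers, sim$relatedness, year = 2012L),
             generalized_latencies(sim$events, sim$mothers, sim$relatedness, year = 2012L))
cmp <- compare_rules(lat)
cmp$summary
#>   rule            n mean_days se_days  min_days max_days
#> 1 direct       1859    10.8    0.225   0.00139     59.0
#> 2 generalized  2275     0.682  0.0160  0.0000694    5.10
cmp$difference_days
#> [1] 10.08
```

Pooling printed per-group ratios replicates a published-style
meta-analysis:

```r
eff <- study_effects(c("g2012", "gclose", "gdist"),
                     ratio   = c(1.05, 0.96, 1.12),
                     ci_low  = c(1.01, 0.83, 0.92),
                     ci_high = c(1.09, 1.10, 1.34))
pool_fixed(eff)
#> Fixed-effect inverse-variance pooling of 3 studies (ci_derived SEs)
#>   pooled ratio 1.046 (95% CI 1.009-1.085), p = 0.014
#>   weights: g2012 89.7%, gclose 6.6%, gdist 3.7%
#>   Q = 1.97 (df = 2, p = 0.37); tau2 = 0.0000; I2 = 0.0%; H = 1.00
```

A thin command-line wrapper over the same functions ships in
`inst/cli/allonurse.R` (subcommands `simulate`, `run`, `meta`).

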