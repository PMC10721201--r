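---
title: "Decision rules of reciprocal allonursing: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision rules of reciprocal allonursing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonurse)
```

## The scientific question

Allonursing — a lactating female nursing another mother's offspring — is
costly to the donor, so its persistence calls for an evolutionary
explanation. Three mechanistic decision rules can each sustain it:
*direct reciprocity* (help someone who previously helped you), which
requires individual recognition and memory of past partners;
*generalized reciprocity* (help anyone if helped by someone), which only
requires remembering that help was received; and *kin discrimination*
(preferentially help closer kin), which trades direct for indirect
fitness. In observational data these rules leave overlapping signatures,
so the package tests them jointly: dyadic help counts against help
received and relatedness, solicitation outcomes against dyadic
reciprocity, per-mother totals against totals received, and — the one
contrast able to separate the two reciprocity rules — the latency
between receiving and giving help under partner-specific versus
partner-agnostic pairing.

## Event scoring

A solicitation is scored a **bout** when the offspring suckled 5 s or
more, a **rejection** when it suckled under 5 s and the female ended the
contact, and an **attempt** when the offspring approached within a head
of the udder but never suckled. Suckling episodes of the same pair
separated by less than 20 s of lost contact belong to one bout
(durations summed); 20 s or more terminates it. These two constants are
field conventions for ungulate nursing studies and are exposed as
defaults, not hard-coded.

Bouts are summed within *ordered* dyads: `a_ij` counts bouts mother `i`
gave to mother `j`'s offspring, excluding filial nursing. The unordered
dyad's reciprocity index is

$$\mathrm{RAFI} = 1 - \left|\frac{a_{AB}}{a_A + a_B} - \frac{a_{BA}}{a_A + a_B}\right|,$$

undefined when the dyad exchanged nothing. Undefined values are
*excluded* from the likelihood and RAFI-response models rather than
imputed as zero: the index is a 0/0 form there, and imputation would
conflate "never asked" with "asked and strictly refused".

## The model battery

All mixed models are fitted by maximum likelihood with the Laplace
approximation (`lme4`), Gaussian models by REML with Satterthwaite
degrees of freedom (`lmerTest`); Wald z inference is used for the
generalized families, with an alpha of 0.05 throughout and no correction
across predictions.

* **Help given** (`a_ij`, Poisson; both dyad members as random
  intercepts): fixed effects are the help-received x relatedness
  interaction plus absolute rank difference, offspring sex similarity
  and birth-mass difference. The interaction is fitted first and dropped
  when non-significant, so conditional main effects are interpretable. A
  subset refit on dyads with RAFI >= 0.5 probes whether the association
  strengthens among reciprocating pairs.
* **Likelihood of allonursing** (solicitation success 0/1, logistic):
  RAFI x relatedness with the same branch logic, plus offspring sex,
  rank difference, birth-mass difference.
* **RAFI as response**: RAFI x 100 rounded to an integer (half away from
  zero, so 0.505 becomes 51) modelled as a count on relatedness, rank,
  birth-mass and mother-age differences.
* **Generalized reciprocity**: per-mother total help given on total help
  received with `log(observation days)` as offset and mother and year
  random intercepts, so groups observed 65 and 25 days pool on a common
  rate scale.
* **Latency comparison**: `log(latency in days)` on the pairing rule,
  mother age, offspring sex and relatedness, with mother and year random
  intercepts. Raw per-rule means are reported alongside; back-transformed
  log-scale means are never presented as raw means (Jensen's
  inequality).

Diagnostics follow the battery used in field studies of this design:
absolute z-scores above 3.3 flag outliers; exact case-deletion dfbetas
and Cook's distances are flagged at `2/sqrt(N)` and `4/N` with `N` the
number of mothers (25 gives 0.40 and 0.16; 8 gives 0.71 and 0.50);
variance inflation factors of 5 or more flag collinearity (interaction
models with little covariate spread can push VIF into the hundreds — the
refit without the interaction resolves it); Pearson dispersion above 1.5
triggers a negative-binomial refit. The 1.5 threshold is a package
convention (the field reports "overdispersed" without a number) and is
recorded in each run log so users can override it.

Conditional R² uses the Nakagawa variance-partition form with
distribution-specific residual variance: the residual variance for
Gaussian fits, $\pi^2/3$ on the logit scale, and the trigamma
approximation $\psi_1(\lambda)$ for Poisson — $\psi_1((1/\lambda +
1/\theta)^{-1})$ for negative binomial — with $\lambda$ from an
intercept-plus-random-effects null model. This matches the convention
under which published conditional R² values for such models are
computed.

## Latency pairing

Each given bout is anchored on the **most recent** earlier receipt —
from the specific partner for direct reciprocity, from anyone for
generalized reciprocity — measured end-of-receipt to start-of-gift in
days (seconds/86400). Missing receipt end times are imputed as start +
15 s, the mean allonursing bout duration; since latencies typically span
days, the imputation is immaterial. Most-recent (rather than
first-unreturned) pairing is the minimal-memory reading of the
generalized rule and makes the per-event dominance property exact:
whenever both latencies exist for a given bout, the generalized latency
cannot exceed the direct one. One receipt may anchor several subsequent
gifts until a newer receipt supersedes it; a receipt is not "consumed".
Non-positive latencies (overlapping bouts) are excluded with a warning.

## Meta-analysis

Per-group log effects are pooled with fixed-effect inverse-variance
weights $w_i = 1/SE_i^2$. Heterogeneity is summarised by Cochran's Q,
DerSimonian–Laird $\tau^2$ (floored at zero, Q-profile CI), $I^2 =
\max(0,(Q-df)/Q)$ and $H=\sqrt{Q/df}$ with Higgins–Thompson test-based
intervals. Two SE provenances are supported and recorded: `model_se`
(straight from refitted models) and `ci_derived` (back-calculated from
printed ratio CIs with the fixed multiplier 1.959964). Replicating a
published pooling from printed CIs reproduces pooled ratios to two
decimals, but small-study weights can differ by a point or two from the
published ones — consistent with the original pooling having used model
SEs, which is why both paths exist and neither is asserted as canonical.

## The simulator

`simulate_group()` generates a full study season: mother attributes, a
relatedness matrix (iid normal off-diagonals clipped to a target range),
an agonistic log from a latent linear hierarchy (win probability is
logistic in the latent rank difference), and a chronological
solicitation stream. Acceptance of a non-filial solicitation is
modelled on the logit scale,

$$\mathrm{logit}(p) = \mathrm{logit}(p_\mathrm{base})
  + \delta_\mathrm{direct}\,[\text{partner previously helped me}]
  + \gamma_\mathrm{gen}\,[\text{anyone helped me within } \tau]
  + \kappa_\mathrm{kin}\, r,$$

which makes the three rules orthogonal, switchable generators. Refused
solicitations become rejections or attempts; a configurable fraction
become stolen bouts independent of the female's decision (milk theft).
Stolen bouts still update the recipient's state — milk received is milk
received, however obtained.

Defaults emulate the larger of the study conditions the package
addresses: 25 mother-offspring pairs, 65 observation days, four 1 h
daily sessions, 2.5 non-filial solicitations per offspring-day with
baseline acceptance 0.33 (together yielding on the order of 1400–2300
allonursing bouts a season), lognormal bout durations with mean 15 s
(allonursing) and 40 s (filial), a relatedness matrix centred on -0.009
with range [-0.144, 0.239], and about 15 resolved agonistic interactions
per pair. The 8-mother, 25-day geometry of relatedness-selected groups
is a one-argument change. Everything derives from a single integer seed;
identical config and seed give bit-identical output.

What the simulator does **not** emulate: seasonal trends in solicitation
pressure, offspring aging and weaning, partner choice by offspring
(targets are uniform among non-mothers), observer effort gaps, and
mother-specific acceptance heterogeneity beyond the decision rules.
Passing parameter-recovery tests therefore demonstrates that the
pipeline detects the rules it models, under its own assumptions — not
that field data satisfy those assumptions.

## Numerical and design choices

* Birth-mass difference enters models as the **absolute** difference, by
  parallel with the absolute rank and age differences; the signed
  variant is available (`signed_birth_mass = TRUE`) since field
  reporting is ambiguous on this point.
* Dominance in a pair goes to the animal with the majority of resolved
  wins; exact ties and unobserved pairs contribute 0.5 to each animal's
  score (the classical continuity convention). Ranks descend by
  dominance score with ties broken by total wins, then id — fully
  deterministic and invariant to relabeling.
* RAFI-to-count rounding is half away from zero, matching common
  spreadsheet/statistical practice.
* Relatedness matrices are symmetrized only within 1e-9; larger
  asymmetry is an input error, as are conflicting duplicate pairs in
  long format.
* When every random-intercept variance collapses to numerical zero the
  mixed fit coincides with the corresponding fixed-effects fit (checked
  to 1e-4) — the degeneracy that arises routinely in the 8-mother
  groups.
* The test suite sizes its simulations for a desktop run: single
  full-scale streams (25 mothers x 65 days) where an oracle comparison
  needs one, 100 replicates per world for the power and coverage
  batteries, 40–60 replicates for the module-level simulation checks.

## Known limitations

The dyadic count model uses every ordered pair as a row, so each dyad's
two counts appear once as response and once as the partner row's
predictor. Help received is therefore not an exogenous covariate, and
Wald intervals for the help-received effect are anti-conservative: in
null simulations their coverage sits in the mid-80s% rather than 95%
(an independent minimal experiment — independent Poisson count matrices
fitted both ways — reproduces the same inflation, while one-row-per-pair
fits are calibrated). This is a structural property of the reciprocity
regression design itself, which the package reproduces faithfully;
coverage for exogenous covariates such as relatedness is nominal. Users
reading the help-received CIs should treat them as slightly narrow, and
the parameter-recovery report makes the gap visible rather than
papering over it.

Relatedness is consumed as an input (a pairwise estimate matrix);
genotyping, parentage assignment and relatedness estimation are out of
scope, as are duration-weighted reciprocity variants, randomization
tests for hierarchy linearity (de Vries' h'), Elo/David's scores, and
survival-style latency models.
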