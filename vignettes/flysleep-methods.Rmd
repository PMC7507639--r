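---
title: "Methods: sleep scoring, starvation resistance and the models that couple them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring, starvation resistance and the models that couple them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`flysleep` implements the analysis chain of a classic *Drosophila
melanogaster* sleep/starvation study design: infrared beam-break counts
from TriKinetics activity monitors are scored into sleep phenotypes,
starvation resistance is estimated as the hours to 50% death in vial
survival censuses (LD50), whole-body glucose and triglyceride (TGA)
measurements are normalized with control-genotype plate QC, and the
three phenotype layers are joined in linear and Bayesian models of
starvation resistance. This vignette explains each method, its
assumptions, the tunable parameters, the generative model behind the
synthetic-data module, and the numerical conventions chosen where the
underlying definitions leave room.

## Experimental design and time conventions

The design emulated throughout is two wild-derived populations — a
temperate one (ME, Maine) and a tropical one (PC, Panama City), the
endpoints of the North American latitudinal cline — with 10 isofemale
lines each, both sexes, reared and assayed at 21 °C and 25 °C under a
12 h:12 h light:dark cycle.

Time is handled in Zeitgeber hours (ZT): hours since lights-on. Lights
come on at 10:00 clock time by default, so ZT 0 = 10:00. Day phase is
the half-open interval ZT ∈ [0, 12), night ZT ∈ [12, 24); half-open
intervals avoid double-counting the lights-off minute, and phase can
change only at ZT 0 and ZT 12. Monitor recordings cover 2 acclimation
days (retained, flagged, never scored), 2 fed baseline days, and a 24 h
starvation window that begins at 13:00 — ZT 3 — of the following day.
The three fed hours of the starvation day before food removal belong to
neither window: they are labelled `fed` but `baseline = FALSE` and are
excluded from both summaries. `dam_protocol()` exposes all of these
timings.

## Sleep scoring

Sleep is defined the standard way for beam-break data: a maximal run of
at least `min_bout = 5` consecutive minutes with zero counts. The
threshold is a parameter but five minutes is the field convention and
the default everywhere, including under starvation (no re-thresholding).
`score_sleep()` returns exactly the maximal zero runs of the scoring
window, clipped to the window: a run truncated below 5 min by a window
boundary does not count as sleep. Every scored bout is checked in the
test suite against an independent brute-force scan on random traces.

Per-fly phenotypes (`summarize_sleep()`) follow directly from the bout
set: total sleep as a percentage of window minutes, bout number, mean
bout length, and mean waking movement (beam breaks per awake minute,
where "awake" is any window minute not inside a scored bout). A bout
that spans the day/night boundary is split at the boundary for sleep
*minutes* — so day + night sleep minutes always equal whole-window
sleep minutes, an invariant the tests enforce exactly — but counted
once, in its starting phase, for phase-level bout number, with its full
length entering that phase's mean bout length. The product identity
(sleep minutes = bout number × mean bout length) therefore holds for
the whole window, not per phase; phase-level bout statistics describe
bouts *initiated* in that phase.

The within-fly percent change in sleep under starvation is
100 × (starved − fed)/fed on whole-day total sleep; negative values
mean suppression. A fly with zero fed sleep has no defined change and
is excluded with a logged reason — a stand-in rule, since the usual
normalization leaves this case undefined.

Flies that die or escape during recording leave a long terminal run of
zero counts. `flag_dead_or_escaped()` flags a fly whose terminal zero
run is at least 12 h (configurable) and truncates its trace; flagged
flies are excluded from fed-period summaries. The threshold is a
deliberately conservative, testable stand-in: the underlying study
design does not state a dead-fly rule, and per-fly monitor-based death
times are retained only as a cross-check, never for LD50.

## Starvation resistance (LD50)

Each vial holds 10 flies on agar; survivors are counted three times a
day at 21 °C and six times a day at 25 °C. `vial_ld50()` linearly
interpolates the survival step function between consecutive censuses
and reports the earliest time it reaches half the initial count. Linear
interpolation is the minimal-assumption estimator of the "time when
half are dead"; a step-function alternative (earliest census at or
below half) is available via `method = "step"` for sensitivity checks.
An exact tie at a census time returns that census time (earliest
crossing). Vials that never reach half are censored at the last census,
flagged, and excluded from line means with a logged count. Line-level
summaries report both mean and median across vials — they are nearly
interchangeable for unimodal death-time distributions, which the tests
verify by simulation — and downstream models consume the mean. A
census-schedule property is also enforced: the estimate deviates from
the true half-death time by less than one inter-census interval.

## Metabolite normalization and plate QC

Each well's analyte quantity is divided by its protein quantity
(mg glucose or mg TGA per mg protein), removing fly-size variation.
Because plate-level measurement effects multiply every well on a plate
alike, dividing each well's per-protein value by the plate's mean
CantonS per-protein value cancels any multiplicative plate effect
*exactly* — an algebraic identity the tests assert to machine
precision — and demonstrably shrinks between-plate variance on
simulated plates. Downstream models consume the per-protein values (the
scale on which the phenotypes are reported); CantonS-normalized values
are emitted alongside for QC and sensitivity analysis.

Plate QC exploits the Akhr (adipokinetic hormone receptor) mutant
control: Akhr flies store elevated TGA but normal glucose relative to
CantonS. Per plate, a one-sided Welch test of Akhr TGA > CantonS TGA
must be significant at α = 0.05 and a two-sided Welch test of Akhr vs
CantonS glucose must not be; otherwise the plate fails and its wells
are excluded. "Significantly deviated" is not otherwise quantified in
the underlying protocol, so an explicit, configurable α = 0.05 rule was
chosen. Plates with fewer than two replicate control wells per genotype
are "indeterminate": kept, flagged.

## The statistical layer

**Pairwise tests.** Population contrasts use two-tailed Welch t-tests
with Bonferroni control: a comparison is significant iff its raw p is
below α divided by the family size. Family definitions are explicit —
one family per summary block (condition × period), i.e. the set of
ME-vs-PC comparisons across sex × temperature that share a table.

**Nested ANOVA and MANOVA.** LD50 is analyzed by sequential (Type I)
ANOVA on sex, temperature, population, and line nested within
population; with 10 lines per population the nested term carries
2 × (10 − 1) = 18 df and population 1 df, structural identities the
acceptance checks recompute. Sleep phenotypes (total sleep %, bout
length, bout number, waking movement) are analyzed jointly by MANOVA
(Pillai's trace) with univariate follow-ups; a singular response
covariance (e.g. duplicated responses) is a hard error advising
response reduction.

**Per-population regressions.** Line-mean LD50 is regressed on
line-mean sleep-when-starved and on percent change in sleep, separately
per population (× sex), with 95% confidence bands; this is the analysis
that distinguishes a coupled population (positive slope) from an
uncoupled one.

**The starvation-resistance model.** `fit_ld50_model()` fits line-mean
LD50 (hours) on either the *metabolism* predictor set
{sex, temperature, population, glucose/protein, TGA/protein} or the
*behavior* set {sex, temperature, population, percent change in sleep,
starved waking movement, total sleep when starved}. Factors use
treatment coding with reference levels Female, 21 °C, ME, so effects
read as Sex(M), Temperature(25), Population(PC). Continuous predictors
enter on their measured scales (standardization is available behind a
flag). On the full 20-line design the tables have 80 rows and the F
statistics carry (5, 74) and (6, 73) df respectively — which is also
why the model is fixed-effects only: those residual dfs leave no room
for a line-level varying intercept, and line-level structure is
instead examined by the nested ANOVA.

Bayesian inference for the same model runs a Gaussian linear regression
by MCMC in JAGS. The design matrix is QR-reparameterized before
sampling (the sampler works on the orthogonalized coefficients, which
decorrelates the posterior and also certifies that the design has full
rank), with near-flat normal priors on the rotated coefficients
(sd = 1000 × sd(y)) and a half-t(3) prior on the residual scale with
scale max(2.5, mad(y)) — weakly-informative defaults in the spirit of
standard Bayesian regression software. Four chains of 2000 iterations
(half warm-up) are run by default with per-chain seeds derived from one
user seed. Convergence is assessed by the potential-scale-reduction
diagnostic on the back-transformed coefficients; if any rHat exceeds
1.05 the fit warns and withholds its coefficient table (the draws
remain available for diagnosis). Summaries report the posterior mean,
sd, and central 95% credible interval per coefficient, plus rHat, ESS
and the Monte-Carlo standard error. Posterior-predictive replicates are
stored for the density-overlay check (`plot()` on a Bayesian fit), and
with these priors the posterior mean provably coincides with OLS up to
Monte-Carlo error — the package's large-n equivalence check.

## The synthetic-data generator

The simulator exists so that every stage of the pipeline can be tested
against known truth; its defaults *are* the study conditions above
(2 × 10 lines, both sexes, two temperatures, 24 flies per line per sex
per temperature, six 10-fly vials per line, the 2 + 2 + 1 day protocol).

**Sleep.** Each fly is a two-state semi-Markov chain over minutes.
Awake minutes enter sleep with a phase-specific per-minute hazard; a
sleep bout drawn at onset lasts a shifted-geometric number of minutes
with a 5-minute floor and the configured phase-specific mean (a
log-normal alternative sits behind `bout_dist = "lognormal"`). The
geometric choice is the simplest distribution parameterized by a mean
bout length, and memorylessness beyond the floor matches the hazard
formulation. With hazard *h* and bout mean *m* the stationary fraction
asleep is m/(m + 1/h); defaults (hazard 0.020/min day, 0.035/min night;
bout means 12/22 min for ME, 12/40 min for PC) put fed total sleep near
30% (ME) and 40% (PC) with the PC excess arising from longer night
bouts — the qualitative structure of the population contrast, at
realistic fly magnitudes. Starvation multiplies bout length by 0.6 and
waking activity by 1.3 while leaving bout initiation untouched,
reproducing the observed pattern that food deprivation shortens bouts
and raises activity but leaves bout number roughly unchanged. Waking
minutes emit zero-truncated Poisson beam breaks (means 2.5/min ME,
1.5/min PC — the temperate population moves more). The truncation is a
documented simulator simplification: if quiet waking minutes could emit
zero counts they would be indistinguishable from sleep under the 5-min
rule, and the ledger could not be exact. Because of it, the per-fly
phenotypes bookkept by the generator from its own sleep indicator equal
the pipeline's scored phenotypes *exactly*, minute for minute — the
strongest cross-check in the test suite.

**Survival.** Line-mean death times are
base (40 h) + population offset (+15 h ME) + sex offset (+8 h F) +
temperature offset (+6 h at 21 °C) + a line effect (sd 6 h), with vial
(sd 2 h) and fly (sd 5 h) noise; negative draws are resampled and
counted. The line effect can be coupled to line-level starved sleep
with correlation ρ per population (defaults ρ_PC = 0.8, ρ_ME = 0),
generating the coupled-in-PC / uncoupled-in-ME structure; when realized
sleep summaries are supplied the coupling conditions on them, otherwise
a latent standardized sleep score is drawn jointly. Vials are censused
on the temperature's schedule (8 h vs 4 h intervals), so census
discretization error behaves exactly as in the real design.

**Plates.** Line-true metabolite ratios carry population means
(glucose 0.8 ME / 1.0 PC; TGA 1.2 ME / 0.9 PC — opposite-signed
population contrasts), log-normal line variation (sd 0.10) and well
noise (cv 0.10), multiplied by a per-plate log-normal factor (sd 0.15).
Every plate carries CantonS and Akhr control wells (four each per
analyte by default; Akhr TGA three-fold elevated). `invert_rate`
injects QC-violating plates whose Akhr TGA elevation is inverted, for
power checks of the QC rule.

All randomness flows from one master seed through fixed per-module
streams; identical seed and configuration give byte-identical output
files.

**What the simulator does not emulate.** Circadian anticipation peaks
and siesta fine structure, temperature-dependent kinetics beyond group
mean offsets, monitor artifacts (dead channels, bin slippage), death
during the fed baseline, and any non-multiplicative plate pathology.
Passing recovery tests therefore demonstrates that the pipeline
faithfully measures data *of this generative structure*; it does not
validate the biological model against real flies.

## Validation sizes and numerical choices

The shipped checks run, by design, at these problem sizes: sleep
scoring against a brute-force oracle on 10,000 random traces;
conservation identities on every fly of a simulated experiment; LD50
on 1,000 random censuses plus exact toy tables; Bayesian/OLS agreement
on 2,000 rows (with the Monte-Carlo comparison applied simultaneously
across coefficients at a Šidák-adjusted 95% threshold); 95%
credible-interval coverage over 100 replicates at the 80-row design
size; coupling detection over 200 simulated experiments of 10 lines
per population; and plate-QC power over 60 simulated plate sets with
inverted controls. `scripts/acceptance.R` recomputes all of the
corresponding quantities from scratch at the same sizes.

Remaining conventions worth knowing: monitor files must have constant
bin width, with sub-minute bins summed to minutes (all phenotypes are
per-minute); timestamps must strictly increase; LD50 ties at a census
take the earliest crossing; aggregation standard errors are sample
sd/√n; rank-deficient model designs are hard errors naming the aliased
terms; and factors held constant by a reduced design are dropped from
models with a message rather than failing.
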