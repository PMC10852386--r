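---
title: "Methods: outage exposure metrics and the case-crossover model"
author: "outagecc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outage exposure metrics and the case-crossover model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(outagecc)
```

## The estimation problem

Utility outage feeds report, for each power operating locality (POL) and each
30-minute interval, the number of customers served and the number without
power. Hospitalizations are individual records with an admission timestamp
and a residential census block group. The scientific question is whether
recent outage exposure raises the short-term odds of hospitalization.

Two features make an ordinary cohort regression unattractive. First, the
outcome is rare and strongly patterned in time (hour of day, day of week,
season). Second, the important confounders are personal and time-invariant
(household composition, chronic conditions, neighborhood deprivation).
The time-stratified case-crossover design handles both: each case serves as
its own control, comparing exposure at the admission time with exposure at
referent times matched on hour of day, day of week, calendar month and year.
Time-invariant confounding cancels exactly; the matching absorbs diurnal,
weekly and seasonal structure.

## Exposure metric

For a threshold $\tau$ and window $W$, the exposure at time $t$ of the POL
serving a block group is

$$E_{\tau,W}(t) = \tfrac{1}{2}\,\#\{\text{30-minute intervals } s \in
[t - W, t) : \text{out}(s)/\text{served}(s) \ge \tau\},$$

in hours. The window is half-open and excludes the admission hour itself:
the metric is the burden *immediately preceding* admission. The comparison
with $\tau$ is inclusive. Defaults follow the study grid: $\tau \in \{0.01,
0.10, 0.20, 0.50\}$ and $W \in \{12, 24, 36, 48\}$ hours with $W = 36$ h as
the primary window.

Decisions taken where the convention was open:

* **Intervals enter by their start time.** An interval belongs to the window
  when its start lies in $[t - W, t)$; midpoint conventions differ by at most
  one interval.
* **Missing intervals count as non-outage** and are tallied in
  `n_missing_intervals`. This biases toward the null rather than fabricating
  exposure. Feeds are pre-filtered to at most 5% missingness, capping the
  distortion.
* **Quality control** drops POLs with modal customers served below 30 or
  missing-interval fraction above 5%, both strict inequalities (a POL with
  exactly 30 customers, or exactly 5% missingness, is retained — this is the
  literal reading of the exclusion rules). The *modal* customer count is used
  because metered counts drift over time in real feeds.
* **Timestamps** live in a fixed-offset zone (UTC−5, no daylight saving).
  Hour-of-admission matching across a DST change is otherwise ambiguous; the
  simplification is deliberate and documented here.

## Referent selection and covariates

Referents are every other timestamp in the same calendar month and year
sharing the case's day of week and hour of day — three or four per case,
since a month contains four or five of any weekday. Look-backs at referent
times may cross into the prior month; truncating them would misclassify
early-month referents.

Weather confounders are aligned on PRISM days. A PRISM day $D$ is taken as
the 24 hours ending at noon UTC of $D$, i.e. $[\text{noon UTC } D-1,
\text{noon UTC } D)$; the source convention fixes only the noon-UTC start, so
the direction is pinned down here and applied uniformly to admissions and
referents. Daily mean temperature (°C) enters through a natural cubic spline
with three knots — two free columns, continuous second derivative, linear
beyond the boundary knots — built from the truncated-power formula. Knots
default to the 10th/50th/90th percentiles of case-day temperatures;
placement is configurable, and with only three knots estimates are
insensitive to it. Cumulative precipitation (mm) enters linearly. Both vary
across referent days within a stratum, which is what makes them estimable in
the conditional likelihood.

Exposure enters continuously in hours, scaled so the coefficient is per
`scale_hours` (default 4 h). A dichotomized variant
(`dichotomize_at` hours) is available because "at least four hours of
outage" is a natural reporting unit; the continuous form is the default
since it uses the full gradient of exposure.

## Conditional logistic regression

With one case among the $m_s$ rows of stratum $s$,

$$\ell(\beta) = \sum_s \left[ x_{\text{case},s}^\top\beta -
\log \sum_{j \in s} \exp(x_{j,s}^\top\beta) \right].$$

`fit_clogit()` maximizes this by Newton–Raphson with analytic score and
observed information. Numerical choices:

* **Initialization** at $\beta = 0$; the log-likelihood is concave, so the
  start point affects only the iteration count.
* **Overflow safety**: per-stratum max-subtraction before exponentiation.
* **Step-halving** enforces monotone ascent; a Levenberg-style ridge
  ($10^{-8}\times$ the information diagonal) handles numerically singular
  information near flat directions.
* **Convergence** when the largest absolute score component falls below
  `tol = 1e-8`; the covariance is the inverse observed information and
  confidence intervals are Wald.
* **Concordant strata** (identical covariates on all rows) carry no
  information; they are dropped from the iteration but kept in the reported
  `n_strata` and log-likelihood, and the separately reported
  `n_informative_strata` counts sets with within-stratum exposure variation.
* **Separation**: if any coefficient exceeds 10 in absolute value (on the
  supplied covariate scale) the likelihood has no useful finite maximizer;
  the fit is flagged and no estimates are returned rather than reporting an
  enormous odds ratio.
* **Degenerate inputs**: designs with no informative stratum raise a flat
  likelihood error; strata without exactly one case are rejected.

Cells of the analysis grid with fewer than `min_informative` (default 10)
exposure-informative strata report "insufficient data" instead of an
estimate.

Testing oracles are kept independent of this path: a grid-search/bisection
one-dimensional maximizer, the unguarded likelihood formula, the paired-logit
equivalence for 1:1 strata, and `survival::clogit` as an external
cross-check.

## Injury coding

ICD-10 external-cause codes are matched by longest prefix against a pattern
matrix over fifteen base categories. A bundled subset of the standard
external-cause-of-injury framework ships with the package (the full matrix is
an external artifact; any matrix in the same two-column format can be
supplied). Resolution to a single analysis category applies, in order:
merge the two transport and the two poisoning subcategories; attribute
poisoning + fire/burn combinations to fire/burn (smoke-inhalation
admissions dominate that pair); drop the unspecific "other" category when
any specific category is present; a single survivor wins; two or more
specific survivors become "multiple"; "other" alone becomes
"other specified"; an empty set is "unspecified" and excluded. The
fire/burn collapse is applied *before* the multiple rule, so poisoning +
fire/burn + a third specific cause resolves to "multiple" of fire/burn and
the third cause — the composite case is not pinned down by the source rules,
and this ordering is the package's choice.

## Urbanicity

A POL's rural share is population-weighted areal interpolation over block
groups: $\sum_b r_b a_{b}$ / $\sum_b p_b a_{b}$ with $a_b$ the fraction of
block group $b$'s area inside the POL. Rural share strictly above one half
classifies the POL rural, otherwise urban; POLs in the five NYC counties are
NYC regardless of rural share. For POLs straddling county lines the
area-majority county decides NYC membership (the source rule is county-based
but silent on straddling units). Toy geometries are axis-aligned rectangles,
so crosswalk fractions are exact; tests validate them against a fine-grid
rasterized overlay.

## What the synthetic generator does and does not emulate

The generator draws outage events per POL as Poisson onsets (default 0.08
events/POL-day), log-normal durations (median 4 h, `sdlog` 0.8) and
Beta(2, 1.2) affected fractions — right-skewed outage-hour distributions,
with overlapping events taking the larger fraction. Admissions are drawn
hourly with intensity

$$\lambda(bg, t) = \frac{\text{baseline}}{24}\, h(t)\, d(t)\, m(t)\,
\exp\!\left(\beta\,\frac{E(t)}{\text{scale}} + c_T\,(T - 12)^2 +
c_P\, P\right),$$

where $h, d, m$ are hour-of-day, day-of-week and month multipliers
(normalized to mean one) so that referent matching is genuinely load-bearing
in tests, and $E(t)$ is the windowed metric at the generating threshold and
window. $E(t)$ is computed from the recorded (post-missingness) series — the
truth is defined with respect to the exposure the analysis can observe, so
parameter-recovery checks measure estimation error, not measurement error.
Diagnosis codes are drawn from a category-frequency fixture and deliberately
plant every tie-breaking combination (specific + other, fire/burn +
poisoning, two specifics, unspecified-only), with the planted truth stored
alongside for exact verification. Ages follow a four-band pediatric
marginal; both fixtures are editable CSVs under `inst/extdata/`.

Default scale: seven POLs (3 rural / 3 urban non-NYC / 1 NYC), two block
groups each, 2017–2020, baseline 0.098 admissions per block-group-day —
about 2,000 admissions over four years, sized so replicated studies run in
seconds each. The default outage rate is far above real outage climatology:
at realistic rates almost no matched set is exposure-informative at the 50%
threshold at this cohort size, and recovery studies would estimate nothing.
Passing tests therefore demonstrate correctness of the estimation machinery
under the stated generating model — not that real outage data carry this
much information, and not that the generating hazard is how admissions
actually arise. Other things real data have that the generator does not:
spatially correlated outages (storms), weather-outage dependence,
multi-night exposure autocorrelation beyond single events, diagnostic coding
error, and realistic geography.

The replicated studies use 200 replicates for parameter recovery (true OR
1.30 per 4 h at $\tau = 0.5$, $W = 36$ h) and 500 one-year replicates
(~400 admissions each) for the type-I-error check at $\alpha = 0.05$;
`scripts/acceptance.R` re-runs smaller versions (60 and 200 replicates) of
the same studies.

```{r recovery, eval = FALSE}
reps <- run_recovery(200, sim_config(true_log_or = log(1.30), seed = 1))
summarize_recovery(reps)   # mean OR, CI coverage, rejection rate
```

## Known limitations

* One case per stratum only: no exact conditional likelihood for m:n
  matching, no Firth correction, no random effects.
* Wald intervals only (matching the reporting convention of this design);
  profile intervals are not implemented.
* Exposure misclassification inherent to the design — residence-based POL
  assignment, no information on whether the child was home — is not modeled.
* The bundled injury matrix is a subset; production use with real claims
  data requires the full external-cause matrix in the same CSV format.
* Fixed-offset timezone; feeds recorded in civil time with DST need
  pre-conversion.
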