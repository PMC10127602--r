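---
title: "Methods and design notes for regulonkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for regulonkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonkit)
```

regulonkit bundles the quantitative steps of a bacterial
promoter-induction study: reporter-enzyme activity computation, induction
kinetics, a replicate-distance statistic, qRT-PCR induction quotients, and a
transcription-start-site (TSS) caller for stranded 5′-read-start count
tracks. This vignette explains each model, its assumptions and tunable
parameters, the numerical choices made where the design was open, and what
the synthetic-data generators do and do not emulate.

## Reporter-enzyme activities

Two assay variants convert o-nitrophenol extinction into enzyme activity
(1 U = 1 nmol o-nitrophenol per minute at 30 °C):

* microtiter plate, with a scattering correction:
  $A = 315.8\,(E_{420} - 1.75\,E_{550}) / t$;
* tube assay, no correction: $A = 355.6\,E_{420} / t$,

with $t$ the reaction time in minutes. The constants 315.8 and 355.6 are
lumped calibration factors absorbing the optical path length and the molar
extinction coefficient of o-nitrophenol for the respective vessel; they are
treated as fixed assay properties, not user parameters. The two formulas
differ only by this constant, which the test suite exploits as an exact
invariant.

When $E_{420} < 1.75\,E_{550}$ the corrected extinction is negative. The
activity is then reported negative with a warning rather than clamped to
zero: these readings are dominated by scattering noise, and clamping would
bias the baseline of any downstream time-course fit upward. Specific
activity is activity divided by cellular dry mass (U/mg); dry-mass
determination itself (e.g. from turbidity calibrations) is left to the user.
No blank subtraction is assumed; if a per-plate blank exists, subtract it
from the extinctions before calling `activity_plate()`.

## Induction kinetics

A reporter time course $y(t)$ (specific activity, U/mg) under a given
condition is summarized by an unweighted least-squares line
$y = a + b\,t$ fitted to all points at $t \ge 60$ min (`window_start`,
configurable). The window excludes the activation transient so that $b$
measures the steady rise of reporter output. Fits are computed on the
per-time mean across replicates by default (`on = "means"`), matching the
practice of fitting mean curves; `on = "replicates"` fits the raw points
instead. Parameter uncertainties are the standard errors of the linear
model.

**Shared intercept.** Within one strain the induced and uninduced courses
start from the same basal expression level, so the default report estimates
one common $a$ jointly for the two conditions with separate slopes
(`shared_intercept_with`). This reproduces the convention of printing one
intercept per strain. The simplification is imperfect when the induced
course has a long lag: the back-extrapolated induced line then has a lower
effective intercept than the uninduced course, and the shared $a$ is a
compromise between the two. An independent-intercept mode (omit
`shared_intercept_with`) is available for such data.

**Lag time.** The liftoff delay is computed literally as
$t_{lag} = [y(0) - a + 60\,b]/b$, where $y(0)$ is the mean observed
activity at the earliest time point at or below 5 min (`y_zero()`,
configurable). The $+60b$ term makes data lying exactly on the fitted line
from $t = 0$ yield a lag of exactly 60 min, and exact piecewise data that
are flat until $L \ge 60$ min yield $L + 60$; the formula is kept literal
rather than re-derived because it is the established reporting convention
for these assays. Negative lags mean "no detectable lag" and are stored as
signed numbers; `format_lag()` renders them as the sentinel `"<0"` in
reports.

**Quadratic alternative.** `fit_polynomial()` fits $y = a + b t + c t^2$
over the whole course. A linear rise after a lag and a quadratic rise are
two descriptions of the same delayed-activation phenomenon — the quadratic's
derivative grows with time much as a lagged line's average slope does — so
both are reported and the choice is left to the user.

**Goodness of fit.** The regression coefficient column is
$100 \times r^2$ between observed and fitted values. This definition is an
assumption (dispersion conventions differ between fitting programs), but it
is consistent with low percentages observed for near-flat courses. On
exactly constant observed data the correlation is undefined; fit objects
report `NA` there, and `regression_coefficient()` itself signals an error.

**Slope ratios.** $Q(b) = b_{mut}/b_{parent}$ compares regulatory output
between strains under the same inducer; it is flagged significant when the
distance statistic on the two slope estimates (using their fit standard
errors as deviations) exceeds 1.

## The distance statistic D

Two means with deviations are compared by
$D = |m_1 - m_2| / (d_1 + d_2)$; $D > 1$ holds exactly when the intervals
$m \pm d$ do not overlap (a property the test suite verifies by brute
force). The replicate-count mapping — $\ge$ 95 % at $n = 3$, $\ge$ 97.5 % at
$n = 4$, $\ge$ 99 % at $n = 5$, $\ge$ 99.9 % at $n = 8$ — is an empirical
convention that assumes the two deviations are of similar magnitude; the
package reports the label without re-deriving coverage. Counts between
anchors inherit the next lower anchor's level, and $n = 2$ is floored at
the $n = 3$ label, both conservative choices. For users preferring a
conventional p value, `t_statistic()` provides Welch's t test from the same
summaries. No multiple-testing correction is applied anywhere, matching the
single-comparison usage these statistics are designed for.

## qRT-PCR induction quotients

For a target gene $T$ and reference gene $R$ measured induced and
uninduced, the reference-normalized induction quotient is
$Q = (\bar T_{ind}/\bar R_{ind}) / (\bar T_{un}/\bar R_{un})$. Averaging is
nested by default: technical (cDNA) replicates are averaged within each
biological replicate first, then biological means are averaged — the order
appropriate when technical replicates are not independent samples. For
balanced designs nested and flat means coincide exactly (an algebraic
identity the tests assert); a flat mode exists for unbalanced data. The
quotient's deviation is first-order (delta-method) propagation of the four
means' relative dispersions, with dispersion taken as the SD over
biological replicates — technical variance enters only through the
biological means. Genes with $Q \ge 2$ are flagged induced (boundary
inclusive). Ct records are converted by $level = eff^{-Ct}$ with a default
efficiency of 2 (perfect doubling); supply per-assay efficiencies when
calibrations are available. `rpoZ`, an RNA-polymerase subunit gene, is the
default internal standard, and its own un-normalized quotient is reported
as a stability check (values near 1 indicate a usable reference).

## TSS calling

Input is a sparse map of 5′-read-start counts $n_{io}$ per 1-based position
$i$ and orientation $o$, plus the library's total mapped read count $N$
(taken per sequencing library, all replicons jointly). Normalization is
reads per million, $RRS_{io} = (n_{io}/N) \times 10^6$; when the sparse map
accounts for every mapped read the RRS values sum to $10^6$ exactly.

The caller then applies, in order:

1. **Cutoff**: keep positions with $RRS \ge 5$ (boundary inclusive), per
   orientation independently.
2. **Clustering**: single-linkage grouping of same-orientation candidates
   within 5 bp (`cluster_value`, the up-/downstream clustering window). The
   cluster representative is the maximal-RRS position; exact ties resolve
   to the 5′-most position relative to the orientation, preferring the
   transcript's outermost start. Output labels follow the
   `TSS_<position>+<k>` convention, where `k` is the cluster span width.
3. **Reproducibility**: cluster representatives are matched across
   biological replicates (same orientation, within `match_dist = 5` bp) and
   only TSSs present in **all** replicates are kept by default
   (`require_all`). Calls carry per-replicate RRS and their mean.
4. **Score**: the score is the mean RRS divided by the mean control RRS at
   the site. Scoring without a control — score = mean RRS — is the default
   mode, appropriate when control libraries are shallow; when a control is
   supplied, a pseudo-floor of 1 RRS unit on the control mean guards the
   division. The threshold `score_min = 10` is applied to the mean across
   replicates after replicate matching (a per-call summary); applying it
   per replicate before matching would be stricter and can be emulated by
   raising `cutoff`.

Condition contrasts use `condition_fold_change()`: the ratio of mean scores
with D-statistic significance, integer-rounded for reporting when ≥ 10.
Promoter windows are extracted 290 bp upstream to 110 bp downstream of the
TSS (both configurable — the conventional "290 to 110 bp around" phrasing
is directional, and the asymmetry reflects that regulatory elements sit
mostly upstream), reverse-complemented for minus-strand TSSs so sequences
always read 5′→3′ of the transcript. Windows beyond the ends of a linear
replicon are truncated with a warning; circular replicons wrap. File I/O
accepts a 1-based TSV dialect and 0-based half-open BED, converted at the
boundary; coordinates are 1-based inclusive everywhere inside the package.
Read trimming and mapping are out of scope: the input is already-mapped
5′-end counts.

## Synthetic data

The generators are pure functions of (parameters, seed) — the caller's RNG
state is saved and restored — and their outputs are valid inputs for every
reader in the package.

* `gen_time_course()` draws Gaussian noise around a piecewise mean: baseline
  $a_0$, a small (typically negative) uninduced drift, a lag, then a linear
  and optionally quadratic rise, with an optional saturation ceiling for
  regimes past the concentration optimum. Default magnitudes in the tests
  (baseline ≈ 20 U/mg, induced slopes 0.078–0.405 U/mg/min, lags 0–60 min,
  noise 5 % of baseline) match the scale of real reporter data.
* `gen_absorbance()` inverts the plate formula, so zero-noise tables
  round-trip exactly.
* `gen_qpcr()` plants per-gene fold changes over a flat reference with
  mean-preserving lognormal noise, in the standard 2-biological ×
  2-technical design.
* `gen_read_starts()` draws background counts Poisson(`background_rate`)
  at every position/orientation and planted counts
  Poisson(strength × N / 10⁶), so a peak's expected RRS equals its planted
  strength. A negative-binomial option (`overdispersion` = NB size) is
  provided because the true overdispersion of 5′-end libraries is unknown;
  Poisson is the default. If drawn totals exceed the nominal $N$ (possible
  only at near-saturation strengths) the track's $N$ is raised to the
  drawn total with a warning, keeping the track valid.
* `gen_genome()` produces uniform-random nucleotide sequence with motifs
  planted at fixed positions (collisions are an error).

What the generators deliberately do **not** emulate: sequencing error,
mapping bias, genome composition, autocorrelated plate-reader drift, or any
mechanistic dose–response. Passing recovery tests therefore demonstrates
correctness of the computational pipeline under its stated statistical
assumptions, not robustness to every artifact of real instruments and
libraries.

## Verification at a glance

The test suite pairs each stage with an independent oracle: hand arithmetic
for the assay formulas, algebraic identities for lag and shared-intercept
recovery, dense-enumeration and transitive-closure re-implementations for
cutoff filtering and clustering, interval logic for $D > 1$, and seeded
round-trips through the generators. The simulation-based checks use 50
tracks of 10 kb with 5 planted TSSs each for end-to-end recovery (expecting
exactly the planted call set), 200 simulated course pairs for slope-recovery
bias (< 5 % at 5 % noise), and 100 random tracks for RRS conservation —
sizes chosen to make sampling error negligible relative to the asserted
tolerances while keeping the suite quick to run. `scripts/acceptance.R`
recomputes the same quantities from scratch under a user-supplied seed.

```{r example}
specs <- data.frame(pos = c(1200, 4000), strand = c("+", "-"),
                    strength = c(500, 60))
sim <- gen_read_starts(8000, specs, background_rate = 0.1, N = 1e6,
                       n_replicates = 3, seed = 11)
call_tss(sim[[1]])
```

## Known limitations

* The significance labels attached to D are asserted conventions, not
  derived coverage probabilities; for unequal deviations or very small n
  they can be optimistic.
* The shared-intercept default distorts fits of strongly lagged courses
  (see above); use independent intercepts there.
* Quotient deviations assume approximately independent, small relative
  errors (first-order propagation).
* The TSS caller assumes replicate libraries of comparable depth; no
  between-replicate normalization beyond RRS is applied.
* Dose–response curves are generated for plotting only and never fitted;
  changepoint regression beyond the literal lag formula is out of scope.
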