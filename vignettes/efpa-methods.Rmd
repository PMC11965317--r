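---
title: "Predicting relative metabolic flux from enzyme expression with eFPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting relative metabolic flux from enzyme expression with eFPA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efpa)
```

## The problem

Changes in the expression of a metabolic enzyme often fail to predict changes
in the flux of the reaction it catalyses: flux control is typically
distributed over a pathway, and individual enzymes are weak control points.
Pathway-level coordination is more informative — when several enzymes along a
linear route covary, the flux through that route tends to follow. Enhanced
flux potential analysis (eFPA) turns this observation into a predictor: the
relative flux capacity of a *reaction of interest* (ROI) is estimated by
integrating enzyme expression over the ROI's network neighborhood, with the
neighborhood delimited by a metabolite-connectivity-aware distance and a
bounded distance-decay function.

## The flux potential LP

Let $S$ be the stoichiometric matrix of a metabolic model after every
reversible reaction has been split into two irreversible directed copies, so
all fluxes satisfy $v \ge 0$. For a chosen ROI direction, eFPA solves

$$
\max\; v_{\mathrm{ROI}}
\quad \text{s.t.} \quad
S v = 0,\qquad 0 \le v \le u,\qquad \sum_j w_j\, v_j \le A ,
$$

where $A > 0$ is the *flux allowance* and the weight of each directed
reaction is

$$
w_j \;=\; \mathrm{decay}(d_j)\;\times\;\frac{1}{\max(e_j,\ \varepsilon)} .
$$

Here $e_j \in [0,1]$ is the reaction's *relative expression* in the condition
being scored (both directions of a base reaction share one enzyme complement
and hence one penalty), $d_j$ is its network distance from the ROI, and
$\varepsilon$ caps the penalty of unexpressed reactions. The optimal value is
the *flux potential* (FP). Well-expressed or distant reactions have small
weights and can carry flux almost freely; poorly expressed reactions near
the ROI eat into the shared allowance and limit the attainable ROI flux. FP
is normalised by the FP of a hypothetical *super condition* in which every
data-bearing reaction is at its maximal observed expression (all penalties
1), giving the *relative flux potential* rFP $= \mathrm{FP}/\mathrm{FP}_{\text{super}}
\in [0,1]$. rFP is invariant to $A$ (both FPs scale linearly in $A$ while
bounds are slack), so the default $A = 1$ is arbitrary.

Assumptions worth keeping in mind: steady state; no objective other than the
ROI (no growth or maintenance demand is imposed); nutrient exchanges open
unless explicitly blocked through bound overrides; expression is treated as
a *relative* quantity per reaction across conditions, never compared between
reactions.

## From genes to penalties

Gene levels are mapped to reactions through gene–protein–reaction (GPR)
rules: `and` (complex subunits) takes the minimum of its children, `or`
(isozymes) their sum. Unmeasured genes are excluded from `or` sums; an `and`
with some unmeasured children uses the minimum of the measured ones. Either
exclusion downgrades the reaction to *partial*; a reaction whose genes are
all unmeasured — or that has no GPR — is *missing*. The distinction between a
zero and an absence is preserved end to end: zeros (for instance single-cell
dropout) are data and yield relative expression 0, penalty $1/\varepsilon$;
absences yield penalty 0, excluding the reaction from the weighted sum so it
carries flux freely. This exclusion is what makes *gap-filling* predictions
possible: an ROI with no expression data of its own is scored entirely from
its neighborhood.

Raw reaction values are normalised per reaction by the row maximum across
conditions, so every measured reaction attains 1 somewhere. The default
$\varepsilon = 10^{-3}$ caps penalties at 1000: large enough that an
unexpressed reaction effectively blocks budgeted flux, small enough to keep
the LP well-scaled.

## Network distance and decay

Reactions are nodes of a directed adjacency graph with an edge $u \to v$
whenever some metabolite produced by $u$ is consumed by $v$. The *naive*
distance gives every edge length 1 (the number of reactions between a pair,
plus one). The *weighted* distance assigns each metabolite
$w(m) = \max\!\big(1,\ 1 + \log_2(\deg(m)/2)\big)$, where $\deg(m)$ counts the
reactions producing plus consuming $m$ (a reversible reaction fills both
roles), and each edge the minimum $w(m)$ over its bridging metabolites — the
cheapest bridge defines adjacency. A degree-2 metabolite (one producer, one
consumer: strict linearity) recovers the naive distance exactly; hubs such as
pyruvate or ATP push their neighbors apart sub-linearly (degree 8 gives
length 3). No hardcoded side-metabolite list is needed: hub filtering
emerges from the degree weighting. The exact functional form of the degree
weight is this package's own calibration choice, fixed once; its two
anchor properties (degree 2 maps to length 1, sub-linear growth) are what
the tests rely on.

Distances are computed by Dijkstra per ROI direction. Because mass must both
reach and leave the ROI, the default orientation (`mode = "both"`) takes the
elementwise minimum of the downstream distance (following production) and
the upstream distance (following consumption), so the whole pathway passing
through the ROI is within reach. Each single-orientation metric satisfies
the triangle inequality; their minimum need not, which is immaterial here
since only distances from the ROI, never path compositions, are used.

Three decay families convert distance into a multiplier on the penalty:

* `power`: $(1+d)^{-n}$ — the original FPA decay; $n = 0$ disables decay.
* `hard_boundary`: 1 for $d \le b$, 0 beyond.
* `exponential`: 1 for $d \le b$, then $2^{-(d-b)}$ — full weight inside the
  boundary with a soft tail. With $b = 6$ on the weighted metric this is
  **standard eFPA**, the package default.

The boundary is measured on the weighted-distance scale;
`effective_boundary()` converts it to the naive length of the longest
integrated pathway for interpretation. Unreachable reactions always decay
to 0, including under $n = 0$.

## Baselines

*Reaction expression* scores an ROI by its own relative expression — the
reciprocal of its penalty — using no network information. *Compass-* follows
the two-stage resistance calculation of the Compass family without cell
pooling: first the unconstrained ROI optimum $v^\*$, then the minimal
penalty-weighted total flux sustaining $f \cdot v^\*$ (optimum fraction
$f = 0.95$, the published Compass default, which the source study does not
restate). For comparability the raw resistance is normalised as
$\text{super-cell resistance} / \text{cell resistance}$, clipped to $[0,1]$,
so for all methods higher means more predicted capacity; whether the
original normalisation applies a log transform first is ambiguous, and the
ratio form was chosen here. Compass- uses the eFPA penalties (the fair
benchmarking configuration) and no distance decay; `compass_with_decay()`
adds the power decay (order 2.5 by default) over naive distances.
*Original FPA* is the same LP as eFPA with the power decay and, by default,
the naive metric; `original_fpa(metric = "weighted")` gives the
weighted-distance FPA variant.

One deliberate reading: the ROI's own penalty is included in the weighted
sum at $d = 0$ by default; `run_efpa(exclude_roi = TRUE)` removes it (in the
condition and super-condition alike), scoring the ROI purely from its
neighborhood. That variant matters twice: it shows predictions are not
driven by the cognate enzyme alone, and it is the robust choice when the
ROI's own measurement is unreliable, as with single-cell dropout.

## Statistical layer

Predictions are evaluated by row-wise Pearson correlation against measured
flux across conditions, with two-tailed t-based p-values and
Benjamini–Hochberg adjustment over the family of reactions actually tested
(constant or under-observed rows are excluded from the family, which is an
explicit input, never inferred). A reaction counts as predicted at
$q \le 0.05$ and PCC $> 0$. Pathway coexpression strength is the median
pairwise PCC among member reactions; the pathway profile is the
per-condition median. The cross-informing rate bins connected reaction pairs
by bridging-metabolite degree (equal-count bins, default 8, since only the
grouping principle and not the bin edges is prescribed) and reports the
significant fraction per bin. The label-randomisation test shuffles reaction
labels of the relative-expression matrix and reports the empirical p-value
with the +1 pseudo-count, $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$,
so p is never 0. Tissue enrichment is $\Delta$rFP $=$ rFP minus the row
median with $\pm 0.2$ flags; cell-type enrichment combines a median fold
change ($> 1.2$) with a Wilcoxon rank-sum p ($< 10^{-10}$) against all other
cells excluding the top-ranked type (or the second-ranked when the tested
type is itself on top), which keeps one metabolically dominant type from
masking every other comparison.

The Wilcoxon p uses the tie-corrected normal approximation, appropriate
because single-cell zeros create heavy ties. Against exact enumeration it
agrees within 10% for $p \ge 0.05$ at group sizes up to 10; in the extreme
discrete tail of very small samples the exact law sits on atoms the normal
approximation cannot reproduce, which is irrelevant at the $10^{-10}$
threshold used with hundreds of cells.

## Synthetic data: what it emulates, and what it does not

`make_toy_network()` builds mass-balanced fixtures in which every reaction
can carry steady-state flux: a linear chain; a branched route into the ROI
with a proximal coexpressed pathway and a distal independently-expressed
segment; a hub metabolite of configurable degree; two branches whose entry
reactions share a GPR; and a lumped reaction with an obligatory co-product
drain. `simulate_expression()` draws a latent pathway-activity factor per
condition; member gene log2-levels are $\rho f_c + \sigma \epsilon$
(default $\sigma = 0.6 \approx \sqrt{1 - 0.8^2}$, so $\rho = 0.8$ gives
realistic pairwise coexpression), other genes independent unit noise, and
the ground-truth chain flux is $2^{\beta f_c + \sigma_f \epsilon}$ — flux
and pathway expression share the factor without either determining the
other. Expression is log-normal, matching the multiplicative noise of
proteomics; dropout is Bernoulli zeroing at a fixed rate, applied after
simulation, with no imputation anywhere.

The defaults mirror the study conditions the method was calibrated for:
25 conditions, $\rho = 0.8$, $\beta = 1$. The generators do not emulate
sequencing-depth effects, negative-binomial counts, or the empirical
distributions of any published dataset; passing tests show that the
method's mechanisms work as designed, not that they attain any particular
accuracy on real measurements.

Two simulation studies deserve comment. In the boundary-titration study the
flux–rFP correlation of a data-less ROI rises as the boundary grows to the
pathway length and falls beyond it, because the distal segment's expression
is noise with respect to the ROI's flux — the miniature of the calibration
that selects the boundary. In the single-cell study the fixture uses 4
isozymes per reaction and 6 cells per type at 40% dropout. The isozyme count
is not cosmetic: with one gene per reaction, any fully dropped-out reaction
in the integration neighborhood takes penalty $1/\varepsilon$ and crushes
that cell's FP, and neighborhood integration is then no more robust than the
cognate enzyme itself. Redundancy in the `or` rules — pervasive in animal
central metabolism — is what lets the aggregate survive dropout, and the
ROI's own unreliable single-gene measurement is excluded via
`exclude_roi = TRUE`. Under these conditions the neighborhood score
preserves the cell-type ordering more reliably than reaction expression,
whose median-based signal degrades; the baseline weakens rather than
collapses outright at this dropout rate and cell count.

## Numerical choices

* All LPs share one shape — nonnegative directed fluxes, steady state,
  upper bounds, one budget (or optimum-fraction) row — and are solved with
  the dense simplex implementation in the recommended `boot` package. The
  steady-state equalities are passed as paired inequalities
  ($Sv \le 0$, $-Sv \le 0$) so the origin is a feasible starting basis;
  metabolic LPs are highly degenerate and phase-I construction from
  equality rows fails on them far more often.
* Solver feasibility tolerance is the `boot::simplex` default
  ($10^{-10}$); results are compared at $10^{-6}$. Simplex tie-breaking is
  irrelevant because only optimal values, never optimal bases, are used.
* If every weight is zero the budget row is vacuous and the ROI flux is
  limited only by its bound; the result is flagged `clamped`. Infeasible
  or errored solves yield FP 0 with a status flag; a super-condition FP at
  or below tolerance makes rFP undefined (`NA`) rather than 0.
* Distances are computed once per ROI direction and reused across
  conditions; both directions of a base reaction are never connected by an
  edge, so a directed copy cannot be its own neighbor.
* Degenerate inputs: empty GPRs are missing data, not errors; unparseable
  GPR strings warn and degrade to missing; reactions with `lb > 0` are
  treated as irreversible forward (the minimum-flux requirement is not
  encoded); blocked reactions (`lb = ub = 0`) become directed copies with
  bound 0.

Problem sizes in the shipped tests were chosen so the whole suite runs in
well under a minute of LP time: fixtures of 7–20 directed reactions,
25 conditions, 30–50 simulation replicates, 200 permutations. The same
study designs scale to genome-scale models unchanged, at the cost of a
sparse-aware LP backend — the solver wrapper is the single place to swap.

## Known limitations

* The weighted-distance and decay parameterisations are heuristic
  calibrations; their exact published forms beyond the anchor properties
  are not reproduced here.
* `boot::simplex` is dense and suitable for the fixture scale; genome-scale
  work needs an external LP solver behind `solve_flux_lp()`.
* Condition-specific media tables, quantitative uptake constraints and
  tissue-network construction pipelines are out of scope; bound overrides
  (`bounds =`) are the supported mechanism for blocking nutrients.
* Reproducing the published chemostat-dataset numbers requires third-party
  supplementary tables that cannot be redistributed with the package; the
  acceptance test for that reproduction documents the expected file layout
  and remains unsatisfied until the data are supplied.
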