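---
title: "Shelf-life-constrained (r, Q) policies under stochastic lead time: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shelf-life-constrained (r, Q) policies under stochastic lead time: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharminv)
```

## The decision problem

A hospital pharmacy manages one perishable drug under continuous
review: when the inventory position reaches the reorder point $r$, a
lot of $Q$ packages is ordered. The model rests on six assumptions:

1. demand is deterministic at rate $D$ packages/year;
2. one order is outstanding at a time;
3. the lead time $L$ is random with density $g(t)$, independent across
   cycles;
4. demand unmet during a stockout is lost (no backorders) and charged
   $C$ per package;
5. stock rotates first-in-first-out;
6. a lot must be consumable within its shelf life $S$, counted from the
   moment of ordering.

Because the cycle consumes exactly $Q$ packages at rate $D$, the cycle
time is $T = Q/D$ years whatever the lead time — the lost-sales
accounting keeps the time base fixed and prices the lost demand instead.

## Cost functionals

Within one cycle two geometries can occur. If the lot arrives before
the shelf empties ($L < r/D$), the inventory trajectory has holding
area $(2r - DL)L/2$ during the lead time plus
$(Q + 2r - DL)(Q - DL)/(2D)$ from arrival to the next order, and no
shortage. If it arrives late ($L \ge r/D$), the holding areas are
$r^2/(2D)$ and $(Q^2 - r^2)/(2D)$ and the lost demand is the triangle
$(DL - r)^2/(2D)$. Taking expectations over $g$ and truncating at the
space horizon $M = W/(fD)$ years (the time-equivalent of the storage
capacity $W$ at $f$ m$^3$/package) gives the per-cycle expectations
implemented in `expected_holding_per_cycle()` and
`expected_shortage_per_cycle()`; ordering adds $A + KQ$. Dividing by
$T$ yields the annual rate

$$Z(Q,r) = \frac{DA + C\int_{r/D}^{M} \frac{(Dt-r)^2}{2} g\,dt}{Q}
 + KD + \frac{hQ}{2}\int_0^{M} g\,dt
 - hD\int_0^{r/D} t\,g\,dt + hr\int_0^{r/D} g\,dt .$$

Note the deliberate convention, kept throughout: integrals are
truncated at $M$ **without renormalising** $g$ — lead-time mass beyond
the space horizon contributes no cost. The Monte-Carlo comparator uses
the correspondingly conditioned law so both sides measure the same
thing (see below).

### Closed forms

For $L \sim U[a,b]$ with $0 \le a \le r/D \le b \le M$ the integrals
are polynomials and `uniform_annual_cost()` evaluates

$$Z = \frac{DA + \frac{C}{2(b-a)}\left(r^2 b - \frac{r^3}{3D} - rDb^2 +
\frac{b^3D^2}{3}\right)}{Q} + KD + \frac{hQ}{2} +
\frac{hr^2 + hD^2a^2 - 2Dahr}{2(b-a)D},$$

which agrees with the quadrature mode to $10^{-8}$ relative (a
property the test suite checks on 100 random instances per run).

For $L \sim \mathrm{Exp}(\lambda)$ the package ships two forms.
`exponential_annual_cost(mode = "exact")` uses the exact
antiderivatives of the truncated integrals. `mode = "paper"` evaluates
the closed form in circulation for this model, which groups the
shortage terms as

$$\frac{c_0 - c_1 r + c_2 r^2}{Q}\left(e^{-\lambda r/D} -
e^{-\lambda M}\right), \qquad
c_0 = C^2\!\left(\tfrac{DW}{\lambda f} + \tfrac{D^2}{\lambda^2} +
\tfrac{W^2}{2f^2}\right),\;
c_1 = C^2\!\left(\tfrac{2D}{\lambda} + \tfrac{W}{f}\right),\;
c_2 = C^2 .$$

Two caveats, both documented because they matter for reproduction:

* **The grouping is not the exact integral.** The exact antiderivative
  weights the two exponential endpoints with *different* polynomials
  ($D^2/\lambda^2$ at $r/D$; $\frac{(DM-r)^2}{2} + \frac{D(DM-r)}{\lambda}
  + \frac{D^2}{\lambda^2}$ at $M$), so no algebra reduces it to a common
  factor $(e^{-\lambda r/D} - e^{-\lambda M})$. The two modes therefore
  disagree materially, and the package refuses to guess which one a
  user means: `"paper"` reproduces the published numeric results,
  `"exact"` is the form the simulator validates. The simulation check
  (`compare_analytic_vs_simulated()`) passes `"exact"` at 3 sigma and
  rejects the `"paper"` shortage component decisively — the test suite
  asserts both.
* **Coefficient precision.** The worked exponential instance carries
  $c_0, c_1, c_2$ at three significant figures, and its reported
  objective values (the optimum and the whole shelf-life table) are
  only reproduced at that precision. `exponential_coefficients()`
  therefore rounds to 3 significant figures by default
  (`signif_digits = NULL` gives the unrounded symbolic values). For the
  bundled `table2_exponential` fixture the rounded coefficients are
  $1.66\times10^{10}$, $1.97\times10^{8}$, $10^{6}$.

A related reporting convention: published tables evaluate costs at
policies printed to two decimals. Where the package's results are
compared against printed table values (in the acceptance machinery),
the cost is evaluated at the 2-decimal policy; the optimiser and sweep
themselves carry full precision.

## Constraints and optimisation

The feasible region of the nonlinear program is

* $G(r/D) \ge \alpha_{lo}$ (type-1 service level, default 0.98), and
  optionally $G(r/D) \le \alpha_{hi}$; inverted through the lead-time
  quantile these give $r \in [D G^{-1}(\alpha_{lo}), D
  G^{-1}(\alpha_{hi})]$;
* $P(L + Q/D \le S) \ge c$ (shelf life at confidence $c$, default
  0.99), i.e. $Q \le D\,(S - G^{-1}(c))$; with a bounded lead time and
  $c = 1$ this is the hard bound $b + Q/D \le S$;
* $Q \ge r \ge 0$.

Space enters only through the integration cap $M$; no separate
$Qf \le W$ constraint is imposed, matching the cost model's own
treatment of space.

For fixed $r$, $Z$ is strictly convex in $Q$ (shape $\alpha/Q + \beta Q
+ \gamma$ with $\alpha, \beta > 0$), with minimiser
$Q^*(r) = \sqrt{2(DA + \text{shortage numerator})/(h\,G(M))}$ —
the EOQ $\sqrt{2DA/h}$ when $C = 0$ and the lead-time mass lies inside
$M$. `optimize_policy()` exploits this: a deterministic grid over $r$
(step 0.01 packages, chosen well below the 2-decimal reporting
precision of the quantities involved) with the clamped closed form
$Q^*(r) \mapsto [r, Q_{max}]$ at each point, ties broken toward
smaller $r$. A grid is preferred to a general nonlinear solver because
at this problem size (about $10^3$ grid points per instance) it is
exact to the grid, tolerance-free and trivially reproducible. A
constraint is reported as *binding* only when relaxing it would lower
the cost (a directional probe of the objective), not merely when the
optimum sits on its boundary — with a free lower service bound the
relaxed optimum is flat in $r$, and reporting `service_lo` there would
be misleading.

One instance-specific note: for the uniform worked instance the 98%
service quantile gives $r_{min} = D(a + 0.98(b-a)) = 23.64$, while the
published instance uses $r = 23.58$ without derivation. The package
computes 23.64 from the constraint; the `r_fixed` override (set in the
bundled fixture) reproduces the published point exactly. Both values
are within 0.3% of each other in cost.

## Shelf-life sensitivity

`shelf_life_sweep()` re-solves the instance over a grid of shelf lives
(default step 0.02 years, mirroring the published tables). The reorder
point is held fixed across rows by default — shelf life does not enter
the service constraint, and the published tables hold $r$ constant —
with `reoptimize_r = TRUE` available. Expected regimes, which
`elasticity_report()` labels from the data:

* **constrained**: $Q(S) = D(S - G^{-1}(c))$ grows affinely with slope
  $D$; total cost falls as the cap relaxes;
* **plateau**: once $Q^*(r)$ fits under the cap, $Q$ and cost freeze at
  the unconstrained optimum.

When the cap falls below the reorder point the row is clamped to
$Q = r = Q_{max}$ (the $Q \ge r$ constraint); when no positive lot is
admissible the row is flagged infeasible rather than aborting the
sweep. Total cost is nonincreasing in $S$ throughout (relaxing a
constraint cannot raise the optimum), a property the tests check on
both bundled instances.

## The Monte-Carlo simulator

`simulate_policy()` draws independent cycles, applies the exact
two-case geometry above to each draw, and annualises by the fixed
cycle time $T = Q/D$. Design choices:

* **Truncated lead-time law.** Draws are from $L$ conditioned on
  $L \le M$, generated by inverse-CDF (uniform variates on
  $[0, G(M)]$ mapped through the quantile function) — identical in law
  to rejection sampling but with a deterministic draw count per seed.
  The analytic comparator in `compare_analytic_vs_simulated()`
  integrates the same conditioned (renormalised) law, so simulated and
  analytic components estimate the same quantity; for the uniform
  family with $b \le M$ the conditioning is vacuous.
* **Reproducibility.** Mersenne-Twister seeded explicitly; the seed is
  recorded in the summary, and a fixed seed reproduces the summary
  bit-for-bit.
* **Shelf violations.** The shelf constraint assigns no outdating cost
  in this model, so the simulator reports the *fraction* of cycles
  whose span $L + Q/D$ exceeds $S$; under a lot size at the shelf cap
  this fraction stays within $1 - c$ (up to Monte-Carlo error), which
  validates the constraint's probabilistic meaning without inventing a
  disposal cost the model does not define.

What the simulation does and does not show: it validates the cost
*functionals* under the model's own assumptions (deterministic demand,
one outstanding order, lost sales, independent cycles). Agreement there
says nothing about features real pharmacy data would add — demand
surges, order crossover, batch-level expiry — which are out of scope by
design.

## Numerical choices

* Quadrature: `stats::integrate` with `rel.tol = 1e-11`,
  `abs.tol = 1e-10`; every integrand kink at $t = r/D$ is a domain
  endpoint, never interior to an integration call.
* Time is in years internally; days appear only in printed summaries at
  365 days/year. Costs are rounded to 2 decimals at serialisation only.
* $Q$ and $r$ are continuous packages; no integer rounding anywhere in
  the core.
* Degenerate inputs: $Q = r = 0$ gives zero holding; $r \ge D b$ gives
  zero shortage; $r/D > M$ raises a structured infeasibility error, as
  does a shelf life at or below the confidence quantile.
* Test problem sizes: 100 random instances per closed-form/quadrature
  property check, 1,000 random policies for optimality dominance,
  30,000–100,000 cycles for simulation checks — sizes at which the
  Monte-Carlo standard errors are small enough for 3-sigma checks to
  be meaningful while the whole suite runs in seconds.

## Limitations

Single drug, deterministic demand, at most one outstanding order, no
order crossover, no partial-outdating cost, and a space cap that acts
through the integration horizon rather than as a hard per-order volume
constraint. The exponential `"paper"` mode is a faithful reproduction
of the circulating closed form, not a recommendation: for any new
analysis use `mode = "exact"`, and treat `"paper"` as the bridge to the
published numbers.
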