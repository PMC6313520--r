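# pharminv

Continuous-review (r, Q) inventory policies for perishable drugs with
stochastic replenishment lead time.

Hospital pharmacies that stock short-shelf-life preparations (liquid
formulations, vaccines, biologics) face a two-sided risk: ordering too
little causes stockouts of medicines that often carry near-mandatory
service levels, while ordering too much means stock expires on the
shelf. `pharminv` is a small decision-support toolkit for this
trade-off. It targets analysts and operations researchers in healthcare
logistics who need a transparent, reproducible model rather than a
black-box solver.

## The model

A single drug is managed under continuous review: whenever the
inventory position falls to the reorder point *r*, a lot of *Q*
packages is ordered. Demand is deterministic at rate *D* packages/year;
the lead time *L* is random with density *g(t)* (uniform or exponential
families are built in, or any density via the quadrature mode). Unmet
demand during the lead time is lost and charged at *C* per package.
Storage space caps the planning horizon at *M = W/(fD)* years. The
expected annual cost of a policy is

    Z(Q, r) = [ D·A + C·∫_{r/D}^{M} (Dt − r)²/2 · g(t) dt ] / Q
            + K·D + (h·Q/2)·∫_0^M g(t) dt
            − h·D·∫_0^{r/D} t·g(t) dt + h·r·∫_0^{r/D} g(t) dt

with fixed order cost *A*, unit cost *K* and holding cost *h*. It is
minimised subject to three constraints:

* **service level** — the no-stockout probability G(r/D) must reach a
  target (default 98%), optionally capped from above;
* **shelf life** — stock ordered now must be consumed within the shelf
  life *S*, giving the lot-size cap Q ≤ D·(S − G⁻¹(c)) at confidence
  *c*;
* **consistency** — Q ≥ r ≥ 0.

For fixed *r* the objective is strictly convex in *Q* with a
closed-form minimiser (an EOQ with a shortage-augmented numerator), so
the optimiser combines the closed form with a deterministic grid over
*r*. A seedable Monte-Carlo simulator replays the cycle geometry
exactly and serves as an independent check on every analytic
expectation.

## Worked example

Two worked instances ship as YAML fixtures. The uniform-lead-time
instance (`table1_uniform`: D = 600 packages/year, h = 4, A = 20,
K = 500, C = 1000 yuan, lead time uniform on [0.01, 0.04] years,
shelf life 3 months):

```r
library(pharminv)
cfg <- load_config("table1_uniform")
optimize_policy(cfg$params, cfg$dist, mode = "paper",
                r_fixed = cfg$options$r_fixed)
#> Optimal (r, Q) policy [paper mode]
#>   Q = 77.46 packages, r = 23.58 packages
#>   annual cost 300344.19 yuan/year; cycle 47.12 days
#>   binding constraints: none
#>   (r fixed at 23.58)
```

Order about 77 packages every 47 days; the expected annual cost of
300,344 yuan is dominated by the 300,000 yuan of product cost (K·D),
with roughly 190 yuan of holding and a fraction of a yuan of expected
shortage. Shrinking the shelf life tightens the lot-size cap and raises
cost:

```r
shelf_life_sweep(cfg$params, cfg$dist, s_values = seq(0.08, 0.18, 0.02),
                 r_fixed = 23.58)
#>      S        Q     r       TC feasible
#> 1 0.08 24.00000 23.58 300582.4     TRUE
#> 2 0.10 36.00000 23.58 300439.7     TRUE
#> 3 0.12 48.00000 23.58 300380.4     TRUE
#> 4 0.14 60.00000 23.58 300354.4     TRUE
#> 5 0.16 72.00000 23.58 300345.0     TRUE
#> 6 0.18 77.46188 23.58 300344.2     TRUE
```

While the cap binds, the optimal lot grows at exactly 600 packages per
year of extra shelf life (the demand rate); from S = 0.18 on, the
unconstrained optimum fits and both Q and cost plateau. The simulator
confirms the analytic cost:

```r
simulate_policy(rq_policy(77.46, 23.58), cfg$params, cfg$dist,
                n_cycles = 100000, seed = 2024)
#> Simulated (r, Q) policy: 100000 cycles, seed 2024
#>   annual cost 300344.19 +/- 0.07 yuan/yr (holding 189.27, shortage 0.01, ordering 300154.92)
#>   achieved service level 0.9768; cycle 47.12 days; shelf violations 0.0000
```

A thin command-line wrapper is installed at
`system.file("cli", "pharminv.R", package = "pharminv")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pharminv.R",package="pharminv"))')" \
  --config table2_exponential --command sweep --out results/
```

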