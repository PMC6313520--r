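Package: pharminv
Title: Continuous-Review (r,Q) Inventory Policies for Perishable Drugs
    with Stochastic Lead Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expected-cost analysis and constrained optimisation of
    continuous-review (r,Q) inventory policies for drugs with a fixed
    shelf life and stochastic replenishment lead time. Provides exact
    quadrature cost functionals for an arbitrary lead-time density and
    closed forms for uniform and exponential lead times, a feasibility
    region builder (type-1 service level, shelf-life and storage-space
    constraints), a deterministic constrained optimiser, shelf-life
    sensitivity sweeps, and a seedable Monte-Carlo policy simulator that
    serves as an independent check on the analytic expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
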