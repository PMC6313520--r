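# Worked instance: exponential lead time, rate 40/year (mean ~9 days).
fixture: table2_exponential
parameters:
  demand_rate: 600          # packages/year
  holding_cost: 4           # yuan/package/year
  fixed_order_cost: 20      # yuan/order
  unit_order_cost: 500      # yuan/package
  unit_shortage_cost: 1000  # yuan/package
  unit_space: 0.3           # m3/package
  total_space: 50           # m3
  shelf_life: 0.3333333333333333   # 1/3 year
  expiration_date: 0.5      # years
  service_level_lo: 0.98
  service_level_hi: 0.99
  shelf_confidence: 0.99
distribution:
  kind: exponential
  rate: 40
mode: paper
options:
  # published reorder point (99% service quantile, printed precision)
  r_fixed: 69.08
  s_from: 0.22
  s_to: 0.48
  s_by: 0.02
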