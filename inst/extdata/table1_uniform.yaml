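# Worked instance: uniform lead time on [0.01, 0.04] years.
# Hard shelf constraint (confidence 1): b + Q/D <= S.
fixture: table1_uniform
parameters:
  demand_rate: 600          # packages/year
  holding_cost: 4           # yuan/package/year
  fixed_order_cost: 20      # yuan/order
  unit_order_cost: 500      # yuan/package
  unit_shortage_cost: 1000  # yuan/package
  unit_space: 0.3           # m3/package
  total_space: 50           # m3
  shelf_life: 0.25          # years
  expiration_date: 0.5      # years
  service_level_lo: 0.98
  shelf_confidence: 1.0
distribution:
  kind: uniform
  min: 0.01
  max: 0.04
mode: paper
options:
  # published reorder point for this instance (the service quantile
  # gives 23.64; the source prints 23.58 -- kept as an override)
  r_fixed: 23.58
  s_from: 0.08
  s_to: 0.32
  s_by: 0.02
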