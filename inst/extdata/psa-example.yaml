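# Example probabilistic sensitivity-analysis specification.
# Beta distributions on branch probabilities (means at the base-case
# 0.20 / 0.10 values), gamma distributions on the most influential unit
# costs (means at the base-case USD values, coefficient of variation 0.2).
parameters:
- target:
    kind: param
    name: p_bloodfed
  kind: distribution
  distribution:
    family: beta
    shape1: 20
    shape2: 80
- target:
    kind: param
    name: p_unsat
  kind: distribution
  distribution:
    family: beta
    shape1: 10
    shape2: 90
- target:
    kind: payoff
    assay_id: sanger_sequencing
    field: materials_cost_per_sample
  kind: distribution
  distribution:
    family: gamma
    shape: 25
    scale: 0.9292
- target:
    kind: payoff
    assay_id: maldi_head_thorax
    field: materials_cost_per_sample
  kind: distribution
  distribution:
    family: gamma
    shape: 25
    scale: 0.0236
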