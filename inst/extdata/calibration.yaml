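# Committed calibration configuration: the structural settings under which the
# built-in base case reproduces the package's reference results (per-strategy
# discounted costs and QALYs, MRI dominance, and the probabilistic
# acceptability shares at a willingness-to-pay of $100,000). See the methods
# vignette ("Calibration of open structural choices") for the rationale behind
# each setting.
parameters: builtin
lifetable: builtin
horizon: 13
settings:
  p_detect: 1.0
  fp_pathway: confirmatory
  fp_workup_cost: 964.0
  undiagnosed_cost: crlm
  recurrence_input: cumulative_5y
  recurrence_pathway: salvage
  dispersion_frac: 0.125
psa:
  n: 50000
  seed: 20230724
  wtp: 100000
tornado:
  range: 0.25
ceac:
  from: 0
  to: 200000
  by: 5000
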