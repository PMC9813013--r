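# Example configuration: override a handful of model parameters and carry
# run options. Every key must exist in the default parameter schema; see
# ?load_config. Monetary values are million VND.
settings:
  horizon_months: 672
  discount_annual: 0.015
costs:
  detection_rate: 0.0006
run:
  seed: 1
  perspective: public_payer
  psa_iterations: 2000
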