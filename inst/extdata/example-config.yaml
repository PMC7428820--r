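# Example configuration for the cloneforecast CLI.
# Defaults follow the standard parameter set; anything omitted is filled
# in (K = 512, m = 10, r_init = 1, normal rate 0.9, death multiplier
# 100, resistance rate = mu/10).
params:
  K: 512
  mu: 1.0e-5
  s: 0.1
  endpoint_size: 30000
cohort:
  n_tumours: 10
  mu: random            # per-tumour mu = 10^-X, X ~ U(4, 6)
  schemes: [whole, edge]
  treatment: true
calibration:
  seed: 101
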