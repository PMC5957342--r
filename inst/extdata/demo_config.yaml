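# Demonstration pipeline run: water vs fluoride at the 3-donor pocket.
# Scaled for a quick desk run; double n_steps / replicas for tighter errors.
seed: 42
site: f_site
bulk: bulk
ion: fluoride
water: water
temperature: 300

stability:
  n_replicas: 6
  n_steps: 50000      # 100 ps per replica at dt = 0.002 ps
  dt: 0.002
  sample_stride: 10
  persistence: 5      # ps outside the escape radius before an escape counts

ti:
  n_steps: 20000      # per lambda window
  dt: 0.002
  burn_in_steps: 2500 # first 5 ps of each window discarded
  sample_stride: 10
  n_windows_relative: 11

restraint_k: 200
v_standard: 0.02992
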