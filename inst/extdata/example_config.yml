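# Example simulator configuration: midinfrared drive at the carbonyl
# fingerprint frequency under a 4e-equivalent membrane voltage.
dt_fs: 10
n_steps: 50000
sample_stride: 100
temperature: 300
friction: 5
membrane_voltage: 100
charge_imbalance_dq: 4
seed: 556
discard_time_ns: 0.05
field:
  E0: 0.4
  f: 51.87
  phi: 0
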