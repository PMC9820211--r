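# Smoke-scale comparative plan: no-field reference vs off-resonant and
# resonant drives.  Scale n_steps up (e.g. 1e6) for production runs.
config:
  dt_fs: 10
  n_steps: 20000
  sample_stride: 100
  membrane_voltage: 100
  seed: 556
  discard_time_ns: 0.02
landscape:
  depth: 3
  barrier: 1.5
  kappa: 0.5
n_replicates: 1
n_ions: 3
n_waters: 3
reference: no-field
conditions:
  - label: no-field
    E0: 0
    f: 0
  - label: 50THz
    E0: 0.4
    f: 50
  - label: resonant
    E0: 0.4
    f: 51.87
  - label: 53THz
    E0: 0.4
    f: 53
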