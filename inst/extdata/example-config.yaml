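# Example ehgsim run configuration.  Every omitted key keeps its default
# (the study's standard parameter set); unknown keys are rejected.
band:
  c: 30            # band speed, mm/s
  Ros: 400         # initial axial position, mm
  theta: 10        # cone half-angle, degrees
  delta: 6         # band width, mm
abdomen:
  fat:
    thickness: 15  # mm (admissible range 0-30)
  muscle:
    thickness: 8   # mm (admissible range 0-16)
solver:
  grid_spacing: 5  # mm
electrodes:
  - kind: monopolar
    r: 5
  - kind: bipolar
    r: 5
  - kind: tripolar
    r: 7.5
noise:
  enabled: true
  n_dipoles: 6
seed: 1
outdir: ehgsim-output
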