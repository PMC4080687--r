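# Dental (skull-analogue) experiment: nine tilts about the vertical axis,
# evaluated on an air-filled box in the mouth cavity between the metal
# restorations (c = -1000 HU).
version: 1
phantom:
  type: dental
  n: 256
  spacing: 0.13
angles: [0, 22.5, -22.5, 45, -45, 67.5, -67.5, 90, -90]
dose:
  mode: full
mAs: 200
seed: 1
combine: [median, mean]
roi:
  type: box
  center: [0, -3, 0]
  extents: [3.0, 1.1, 1.0]
  c: -1000
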