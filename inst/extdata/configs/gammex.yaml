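# Standard tilted-scan experiment on the Gammex-like phantom: six distinct
# tilts about the vertical axis, full dose per scan, median/mean fusion,
# evaluated on a ring of Solid Water around the 3 cm titanium insert.
version: 1
phantom:
  type: gammex
  n: 256
  spacing: 0.13
angles: [0, 30, 60, 90, 120, 150]
dose:
  mode: full
mAs: 200
seed: 1
combine: [median, mean]
roi:
  type: ring
  center: [10, 0, 0]
  rInner: 2.0
  rOuter: 2.8
  slab: 0.7
  c: 11
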