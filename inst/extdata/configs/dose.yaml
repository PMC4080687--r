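# Constant-total-dose experiment: eight tilted scans, each at 1/8 of the
# full tube current-time product, median-fused and compared against a
# single full-dose scan (run separately with angles: [0], dose full).
version: 1
phantom:
  type: gammex
  n: 256
  spacing: 0.13
angles: [0, 22.5, -22.5, 45, -45, 67.5, -67.5, 90]
dose:
  mode: split
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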