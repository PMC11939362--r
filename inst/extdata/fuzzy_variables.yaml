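# Default fuzzy variables of the spawning-habitat model.
#
# Each set is a piecewise-linear membership function given as [x, mu]
# breakpoints in the factor's units; membership extends flat beyond the
# terminal breakpoints (shoulder semantics). Crossovers between adjacent
# grades sit at mu = 0.5 on the published suitability thresholds:
#   temperature 18 / 20 / 25 / 27 degC (optimal 20-25)
#   velocity    0.1 / 0.2 / 1.3 / 1.5 m/s (optimal 0.2-1.3, >1.5 unsuitable)
#   depth       0.6 / 1.2 / 11.5 / 15 m (optimal 1.2-11.5, >15 unsuitable)
#   substrate   0.002 / 0.02 / 0.25 / 0.40 m (gravel/cobble suitable,
#               boulders >0.40 m unsuitable, sand <0.002 m unsuitable)
substrate:
  units: m
  universe: [0.0001, 2.0]
  sets:
    VL: [[0.001, 1], [0.003, 0]]
    L:  [[0.001, 0], [0.003, 1], [0.01, 1], [0.03, 0]]
    M:  [[0.01, 0], [0.03, 1], [0.2, 1], [0.3, 0]]
    H:  [[0.2, 0], [0.3, 1], [0.35, 1], [0.45, 0]]
    VH: [[0.35, 0], [0.45, 1]]
temperature:
  units: degC
  universe: [0.0, 40.0]
  sets:
    VL: [[17, 1], [19, 0]]
    L:  [[17, 0], [19, 1], [21, 0]]
    M:  [[19, 0], [21, 1], [24, 1], [26, 0]]
    H:  [[24, 0], [26, 1], [28, 0]]
    VH: [[26, 0], [28, 1]]
velocity:
  units: m/s
  universe: [0.0, 8.0]
  sets:
    VL: [[0.05, 1], [0.15, 0]]
    L:  [[0.05, 0], [0.15, 1], [0.25, 0]]
    M:  [[0.15, 0], [0.25, 1], [1.2, 1], [1.4, 0]]
    H:  [[1.2, 0], [1.4, 1], [1.6, 0]]
    VH: [[1.4, 0], [1.6, 1]]
depth:
  units: m
  universe: [0.0, 60.0]
  sets:
    VL: [[0.4, 1], [0.8, 0]]
    L:  [[0.4, 0], [0.8, 1], [1.0, 1], [1.4, 0]]
    M:  [[1.0, 0], [1.4, 1], [10.5, 1], [12.5, 0]]
    H:  [[10.5, 0], [12.5, 1], [14, 1], [16, 0]]
    VH: [[14, 0], [16, 1]]
# Output variable: the five suitability grades as triangles on [0, 1].
# The L centroid (0.2) sits below the 0.3 low-suitability cutoff so fully
# blocked cells land in the LSP class.
hsi:
  units: dimensionless
  universe: [0.0, 1.0]
  sets:
    VL: [[0, 1], [0.2, 0]]
    L:  [[0, 0], [0.2, 1], [0.4, 0]]
    M:  [[0.3, 0], [0.5, 1], [0.7, 0]]
    H:  [[0.6, 0], [0.8, 1], [1, 0]]
    VH: [[0.8, 0], [1, 1]]
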