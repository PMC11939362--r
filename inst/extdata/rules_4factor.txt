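# Fuzzy rule base of the four-factor spawning-habitat model.
# Columns: substrate temperature velocity depth -> hsi
# Tokens: VL L M H VH, AC = any grade, "/" separates alternatives.
L/M/H M L/H L/H M
L/M/H L/H M L/H M
M L/H L/H M M
L/H L/H L/H M L
L/M/H M M L/H H
L/M/H M L/H M H
M L/H M M H
L/H L/H M M M
L/M/H M M M VH
VL AC AC AC L
L/M/H VL/VH AC AC L
L/M/H L/M/H VL/VH AC L
L/M/H L/M/H L/M/H VL/VH L
# Completion rows (not part of the published table):
# boulder beds block spawning, mirroring the sand-blocking row above
VH AC AC AC L
# all hydraulic factors merely marginal -> low suitability
L/M/H L/H L/H L/H L
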