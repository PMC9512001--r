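# Nominal geometry of the reverse-geometry ortho-k lens used in the
# worked examples (data-sheet means).
total_diameter_mm = 10.89
D0 = 6.79   # back optic zone diameter
D1 = 0.60   # reverse-curve annulus width
D2 = 0.85   # alignment annulus width
D3 = 0.60   # edge-lift annulus width
R0 = 8.40
R1 = 7.19
R2 = 8.08
R3 = 12.19
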