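MapSolver Restriction Map Export
Map Name: example_synthetic_map
Enzyme: AflII
Orientation: circular
Fragment	Size (Kb)	Position (Kb)
1	23.400	0.000
2	9.850	23.400
3	2.120	33.250
4	15.730	35.370
5	41.005	51.100
6	7.640	92.105
7	12.310	99.745
8	30.220	112.055
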