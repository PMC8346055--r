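# Approximate domain segmentation of the sheep Cx46 reference (440 aa),
# keyed to the cryo-EM gap-junction structure numbering. Boundaries are
# editable data: replace with structure-derived values as needed.
# structured = NT,M1,E1,M2,M3,E2,M4; unstructured = CL,CT;
# pore = NT,M1,E1,M2; nonpore = M3,E2,M4.
label	start	end
NT	1	22
M1	23	48
E1	49	82
M2	83	108
CL	109	146
M3	147	173
E2	174	208
M4	209	235
CT	236	440
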