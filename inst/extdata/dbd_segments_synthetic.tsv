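# Synthetic reconstruction of the per-segment dissection of the scDBD design
# target (LacI DNA-binding domain, DFT variant).  The original supplementary
# segment table is not redistributed here; these boundaries are the unique
# 5-7-residue contiguous partition of residues 1-29 (segments A-E) consistent
# with the published combination counts (128 for B, 3072 for E, both extremes),
# plus the forced six-by-five partition of residues 60-89 (segments F-K).
# Coordinates are 1-based inclusive residue positions on the 89-residue domain.
label	start	end
A	1	6
B	7	11
C	12	16
D	17	22
E	23	29
F	60	64
G	65	69
H	70	74
I	75	79
J	80	84
K	85	89
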