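# Assembly-PCR primer set for the single-chain tandem-repeat LacI DNA-binding
# domain repressor (scDBD), as published for the DFT/IAN operator-specificity
# variants.  Printed thermodynamic columns are the original predictions:
# t_ff / t_rr: self-dimer Tm of the primer / of its reverse complement (degC);
# t_fr: Tm of the primer against its exact reverse complement (degC);
# dg_f72 / dg_r72: hairpin folding dG at 72 degC (kcal/mol) for the primer /
# its reverse complement.  The published table prints duplicated column
# headers; the column order used here follows the accompanying text.
# class: "assembly" primers tile the redesigned template (alternating strands,
# in fragment order); "flanking" primers lie outside the redesign space.
# "dCT.R" is the C-terminal-truncation reverse primer (46 nt, printed beyond
# the 44-nt assembly-primer limit, which applied to assembly primers only).
name	sequence	class	fragment	variant	t_ff	t_rr	t_fr	dg_f72	dg_r72
pDBD.F	CCAGTAGTAGGTTGAGGC	flanking	NA	common	-29.0	-20.9	71.2	2.62	2.89
pDBD.R	CAGGCTTCATTTTTTTCCTCCTTCTAGTTTAAACAAAATTATTTG	flanking	NA	common	40.3	38.0	79.1	1.48	1.63
N.1	CTAGAAGGAGGAAAAAAATGAAGCCTGTTACCCTG	assembly	N1	common	-5.0	-15.2	81.2	1.68	1.48
N.2	CTCTGCCACGTCATACAGGGTAACAGGCTTCATTTTTTTC	assembly	N1	common	26.7	30.1	84.7	2.03	1.93
N.3	CCTGTATGACGTGGCAGAGTATGCAGGAGTGAGC	assembly	N1	common	40.7	11.2	86.5	0.84	1.43
DFT.N.4	CTACCGTGCTAACCGTAAAATCGCTCACTCCTGCATACTCTG	assembly	N1	DFT	-1.2	-0.1	86.7	2.54	1.02
IAN.N.4	CTACATTAGAGACCGTGGCAATGCTCACTCCTGCATACTCTG	assembly	N1	IAN	36.6	37.3	86.7	0.94	0.93
DFT.N.5	GATTTTACGGTTAGCACGGTAGTAAACCAAGCCTCCCATG	assembly	N1	DFT	28.6	36.6	85.5	1.27	1.26
IAN.N.5	CATTGCCACGGTCTCTAATGTAGTAAACCAAGCCTCCCATG	assembly	N1	IAN	-20.5	-3.1	86.5	1.97	1.24
N.6	CATGGGAGGCTTGGTTTACTAC	assembly	N1	common	-3.1	-1.6	75.2	2.29	2.61
LacI.N.F	GTAGTAAACCAAGCCTCCCATGTTTCTGCGAAAACGC	flanking	NA	common	26.2	27.6	85.7	1.82	0.22
LacI.N.R	GACTCCAATGAGCAGGGATTGTTTGCCCGCCAGTTG	flanking	NA	common	25.4	29.5	88.8	1.64	1.24
N.7	CAATCCCTGCTCATTGGAGTCGCTACATCGTC	assembly	N2	common	10.6	14.0	84.4	1.52	1.57
N.8	GCGTGTAAGGCAAGGGACGATGTAGCGACTCCAATG	assembly	N2	common	26.3	10.6	87.8	1.57	1.72
N.9	GTCCCTTGCCTTACACGCCCCCTCTCAAATC	assembly	N2	common	-17.0	-4.3	86.7	1.72	2.26
N.10	CCTTGACTTTATGGCAGCTACGATTTGAGAGGGGGCGTG	assembly	N2	common	-1.6	18.8	88.3	1.24	1.65
N.11	CGTAGCTGCCATAAAGTCAAGGGCTGACCAAATG	assembly	N2	common	18.8	23.4	84.8	1.34	1.09
N.12	CATACAAAGTGACGGGTTTCATTTGGTCAGCCCTTGAC	assembly	N2	common	5.7	-0.6	85.3	1.44	1.39
C.1	CAAATGAAACCCGTCACTTTGTATGATGTAG	assembly	C1	common	-4.3	-2.6	77.6	2.04	1.66
C.2	GCATATTCGGCTACATCATACAAAGTGACGGGTTTC	assembly	C1	common	-2.6	-12.4	82.7	1.66	2.04
C.3	CTTTGTATGATGTAGCCGAATATGCAGGCGTAAG	assembly	C1	common	29.8	32.3	81.5	1.49	1.94
DFT.C.4	CTACAGTAGAGACGGTGAAGTCACTTACGCCTGCATATTCGG	assembly	C1	DFT	33.4	35.1	86.3	1.62	0.72
IAN.C.4	CTACATTGCTCACTGTAGCGATACTTACGCCTGCATATTCGG	assembly	C1	IAN	34.4	46.3	85.7	1.38	1.10
DFT.C.5	CTTCACCGTCTCTACTGTAGTCAATCAGGCGAGTCATG	assembly	C1	DFT	40.2	37.1	84.8	1.89	1.58
IAN.C.5	CGCTACAGTGAGCAATGTAGTCAATCAGGCGAGTCATG	assembly	C1	IAN	47.6	39.6	85.7	1.98	1.84
C.6	CATGACTCGCCTGATTGACTAC	assembly	C1	common	-0.4	-6.4	74.9	2.12	2.10
LacI.C.F	GTAGTCAATCAGGCGAGTCATGTTTCTGCGAAAACGCG	flanking	NA	common	30.1	31.4	86.4	1.60	0.22
LacI.C.R	GCTCTGTTTGCCCGCCAGTTG	flanking	NA	common	-3.2	19.0	81.5	2.35	1.79
C.7	CTGGCGGGCAAACAGAGCCTTTTGATAGGGGTAGCAACG	assembly	C2	common	25.1	26.8	90.0	0.93	1.57
C.8	GAACTCGTTGCTACCCCTATCAAAAGG	assembly	C2	common	8.7	1.2	78.9	1.96	1.79
C.9	GATAGGGGTAGCAACGAGTTCATTGGCACTC	assembly	C2	common	1.2	29.8	83.2	1.79	1.68
C.10	CTATCTGGGAAGGTGCATGGAGTGCCAATGAACTCGTTG	assembly	C2	common	30.1	22.1	87.1	1.03	0.78
C.11	CCATGCACCTTCCCAGATAGTGGCAGCAATCAAATCGAG	assembly	C2	common	15.0	17.8	87.4	1.27	1.03
C.12	CCTATCATTACTGGTCCGCTCTCGATTTGATTGCTGCCAC	assembly	C2	common	17.8	15.0	86.7	1.39	0.41
T7T.F	GAGCGGACCAGTAATGATAGGGATCC	flanking	NA	common	29.3	25.6	80.0	0.41	2.00
T7T.R	GCAGCCGGATCCCTATCATTACTGGTCCG	flanking	NA	common	34.3	30.3	85.1	1.62	0.41
dCT.R	GCAGCCGGATCCCTATCATTAACTCGTTGCTACCCCTATCAAAAGG	flanking	NA	common	34.3	30.3	88.3	2.00	1.96
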