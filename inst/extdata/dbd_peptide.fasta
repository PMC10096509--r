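>scDBD_domain_DFT LacI DNA-binding domain residues 1-89, DFT operator-specificity variant (D17/F18/T22)
MKPVTLYDVAEYAGVSDFTVSTVVNQASHVSAKTREKVEAAMAELNYIPNRVAQQLAGKQ
SLLIGVATSSLALHAPSQIVAAIKSRADQ
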