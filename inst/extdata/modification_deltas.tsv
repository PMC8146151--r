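modification	target	monoisotopic	average
carbamidomethyl	C	57.021464	57.051402
oxidation	M	15.994915	15.999405
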