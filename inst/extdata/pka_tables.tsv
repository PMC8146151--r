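set	group	pka
bjellqvist	nterm	7.50
bjellqvist	cterm	3.55
bjellqvist	C	9.00
bjellqvist	D	4.05
bjellqvist	E	4.45
bjellqvist	H	5.98
bjellqvist	K	10.00
bjellqvist	R	12.00
bjellqvist	Y	10.00
emboss	nterm	8.60
emboss	cterm	3.60
emboss	C	8.50
emboss	D	3.90
emboss	E	4.10
emboss	H	6.50
emboss	K	10.80
emboss	R	12.50
emboss	Y	10.10
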