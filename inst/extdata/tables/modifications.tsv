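name	targets	mono_delta	avg_delta	mode	all_or_none	max_per_peptide
propionamide	C	71.03711	71.0779	VARIABLE	TRUE	10
oxidation	M	15.99491	15.9994	VARIABLE	FALSE	2
carbamidomethyl	C	57.02146	57.0513	FIXED	FALSE	10
phospho	S,T,Y	79.96633	79.9799	VARIABLE	FALSE	2
hexnac	S,T	203.07937	203.1925	VARIABLE	FALSE	2
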