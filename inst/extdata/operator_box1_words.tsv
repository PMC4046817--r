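locus	word
lrpB_operator_Box1	TTGTAATTTTTACAA
Sso0049_Box1	TTGTAATTTTTTCAA
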