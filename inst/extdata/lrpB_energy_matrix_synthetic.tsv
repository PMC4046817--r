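# Synthetic example binding-energy matrix (kT penalties relative to the
# consensus TTGCAAAATTTGCAA). The values are illustrative stand-ins, NOT a
# measured saturation-mutagenesis matrix; supply your own matrix for real
# analyses.
# kd_consensus=6.3e-08
A	C	G	T
1.2	0.8	1.5	0.0
1.0	0.6	1.8	0.0
2.2	1.4	0.0	2.0
1.9	0.0	2.4	1.6
0.0	1.1	0.9	0.4
0.0	1.3	1.7	0.7
0.0	2.6	2.1	1.1
0.0	0.9	1.2	0.25
1.5	1.0	2.0	0.0
0.9	1.6	1.3	0.0
0.5	2.3	1.9	0.0
2.8	1.2	0.0	2.5
2.1	0.0	2.7	1.8
0.0	1.4	1.0	0.6
0.0	0.8	1.5	0.3
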