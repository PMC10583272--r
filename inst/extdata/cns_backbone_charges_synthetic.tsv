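atom	type	charge
N	NH1	-0.570
HN	H	0.370
CA	CT1	0.070
HA	HB	0.090
CB	CT2	-0.180
O	O	-0.510
C	CC	0.510
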