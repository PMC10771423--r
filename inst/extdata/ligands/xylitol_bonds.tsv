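atom1	atom2
O1	C1
C1	C2
C2	O2
C2	C3
C3	O3
C3	C4
C4	O4
C4	C5
C5	O5
O1	HO1
C1	H11
C1	H12
C2	H21
O2	HO2
C3	H31
O3	HO3
C4	H41
O4	HO4
C5	H51
C5	H52
O5	HO5
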