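HETATM    1  O1  XUL A   1       2.998   0.511  -1.252  1.00  0.00           O
HETATM    2  C1  XUL A   1       1.654   0.664  -0.805  1.00  0.00           C
HETATM    3  C2  XUL A   1       1.204  -0.578  -0.047  1.00  0.00           C
HETATM    4  O2  XUL A   1       1.786  -1.657  -0.212  1.00  0.00           O
HETATM    5  C3  XUL A   1       0.022  -0.466   0.921  1.00  0.00           C
HETATM    6  O3  XUL A   1       0.057   0.700   1.741  1.00  0.00           O
HETATM    7  C4  XUL A   1      -1.347  -0.581   0.226  1.00  0.00           C
HETATM    8  O4  XUL A   1      -1.525  -1.846  -0.410  1.00  0.00           O
HETATM    9  C5  XUL A   1      -1.666   0.530  -0.787  1.00  0.00           C
HETATM   10  O5  XUL A   1      -1.238   1.822  -0.379  1.00  0.00           O
HETATM   11  HO1 XUL A   1       3.090  -0.424  -1.525  1.00  0.00           H
HETATM   12  H11 XUL A   1       1.620   1.541  -0.155  1.00  0.00           H
HETATM   13  H12 XUL A   1       1.021   0.816  -1.679  1.00  0.00           H
HETATM   14  H31 XUL A   1       0.120  -1.321   1.604  1.00  0.00           H
HETATM   15  HO3 XUL A   1       0.844   0.627   2.315  1.00  0.00           H
HETATM   16  H41 XUL A   1      -2.110  -0.509   1.013  1.00  0.00           H
HETATM   17  HO4 XUL A   1      -1.354  -2.551   0.241  1.00  0.00           H
HETATM   18  H51 XUL A   1      -1.217   0.309  -1.761  1.00  0.00           H
HETATM   19  H52 XUL A   1      -2.748   0.567  -0.960  1.00  0.00           H
HETATM   20  HO5 XUL A   1      -1.210   1.845   0.598  1.00  0.00           H
END
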