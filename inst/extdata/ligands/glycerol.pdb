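HETATM    1  O1  GOL A   1       1.879  -0.415  -1.242  1.00  0.00           O
HETATM    2  C1  GOL A   1       1.230   0.671  -0.592  1.00  0.00           C
HETATM    3  C2  GOL A   1       0.133   0.175   0.347  1.00  0.00           C
HETATM    4  O2  GOL A   1      -0.494   1.296   0.983  1.00  0.00           O
HETATM    5  C3  GOL A   1      -0.935  -0.638  -0.388  1.00  0.00           C
HETATM    6  O3  GOL A   1      -1.970  -0.971   0.545  1.00  0.00           O
HETATM    7  HO1 GOL A   1       2.616  -0.034  -1.751  1.00  0.00           H
HETATM    8  H11 GOL A   1       1.975   1.242  -0.026  1.00  0.00           H
HETATM    9  H12 GOL A   1       0.816   1.343  -1.352  1.00  0.00           H
HETATM   10  H21 GOL A   1       0.568  -0.445   1.140  1.00  0.00           H
HETATM   11  HO2 GOL A   1      -1.297   0.918   1.398  1.00  0.00           H
HETATM   12  H31 GOL A   1      -0.523  -1.562  -0.804  1.00  0.00           H
HETATM   13  H32 GOL A   1      -1.395  -0.047  -1.187  1.00  0.00           H
HETATM   14  HO3 GOL A   1      -2.603  -1.533   0.064  1.00  0.00           H
END
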