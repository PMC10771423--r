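HETATM    1  O1  XLT A   1       3.061   0.338  -1.542  1.00  0.00           O
HETATM    2  C1  XLT A   1       1.756   0.561  -0.996  1.00  0.00           C
HETATM    3  C2  XLT A   1       1.438  -0.555   0.008  1.00  0.00           C
HETATM    4  O2  XLT A   1       1.505  -1.828  -0.645  1.00  0.00           O
HETATM    5  C3  XLT A   1       0.091  -0.390   0.748  1.00  0.00           C
HETATM    6  O3  XLT A   1       0.276   0.498   1.863  1.00  0.00           O
HETATM    7  C4  XLT A   1      -1.077   0.145  -0.105  1.00  0.00           C
HETATM    8  O4  XLT A   1      -1.257  -0.616  -1.301  1.00  0.00           O
HETATM    9  C5  XLT A   1      -2.396   0.131   0.683  1.00  0.00           C
HETATM   10  O5  XLT A   1      -3.444   0.619  -0.162  1.00  0.00           O
HETATM   11  HO1 XLT A   1       3.706   0.499  -0.831  1.00  0.00           H
HETATM   12  H11 XLT A   1       1.735   1.550  -0.529  1.00  0.00           H
HETATM   13  H12 XLT A   1       1.066   0.547  -1.844  1.00  0.00           H
HETATM   14  H21 XLT A   1       2.246  -0.574   0.750  1.00  0.00           H
HETATM   15  HO2 XLT A   1       2.098  -1.710  -1.413  1.00  0.00           H
HETATM   16  H31 XLT A   1      -0.198  -1.369   1.152  1.00  0.00           H
HETATM   17  HO3 XLT A   1       0.819   0.019   2.516  1.00  0.00           H
HETATM   18  H41 XLT A   1      -0.883   1.180  -0.411  1.00  0.00           H
HETATM   19  HO4 XLT A   1      -2.190  -0.486  -1.566  1.00  0.00           H
HETATM   20  H51 XLT A   1      -2.353   0.748   1.585  1.00  0.00           H
HETATM   21  H52 XLT A   1      -2.667  -0.892   0.964  1.00  0.00           H
HETATM   22  HO5 XLT A   1      -3.333   1.585  -0.224  1.00  0.00           H
END
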