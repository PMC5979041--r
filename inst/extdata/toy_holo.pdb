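REMARK   1 SYNTHETIC TOY HOLO COMPLEX (BENZENE IN A MINIMAL POCKET)
ATOM      1 N    ALA A   1       4.000   0.000   0.000  1.00  0.00           N
ATOM      2 CA   ALA A   1       5.500   0.000   0.000  1.00  0.00           C
ATOM      3 CB   ALA A   1       9.000   0.000   0.000  1.00  0.00           C
ATOM      4 N    VAL A   2       0.000   6.000   0.000  1.00  0.00           N
ATOM      5 CA   VAL A   2       0.000   8.000   0.000  1.00  0.00           C
ATOM      6 CB   VAL A   2       0.000  -6.200   0.000  1.00  0.00           C
ATOM      7 N    LEU A   3       0.000   0.000   3.000  1.00  0.00           N
ATOM      8 CA   LEU A   3       0.000   0.000   5.500  1.00  0.00           C
ATOM      9 CB   LEU A   3       2.000   2.000   2.000  1.00  0.00           C
ATOM     10 N    PHE A   4      12.000   0.000   0.000  1.00  0.00           N
ATOM     11 CA   PHE A   4       0.000  12.000   0.000  1.00  0.00           C
ATOM     12 CB   PHE A   4       0.000   0.000  12.000  1.00  0.00           C
ATOM     13 HB   ALA A   1       4.500   0.000   0.000  1.00  0.00           H
HETATM   14 C1   BNZ A   9       1.390   0.000   0.000  1.00  0.00           C
HETATM   15 C2   BNZ A   9       0.695   1.204   0.000  1.00  0.00           C
HETATM   16 C3   BNZ A   9      -0.695   1.204   0.000  1.00  0.00           C
HETATM   17 C4   BNZ A   9      -1.390   0.000   0.000  1.00  0.00           C
HETATM   18 C5   BNZ A   9      -0.695  -1.204   0.000  1.00  0.00           C
HETATM   19 C6   BNZ A   9       0.695  -1.204   0.000  1.00  0.00           C
END
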