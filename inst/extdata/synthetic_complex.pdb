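ATOM      1 N    ARG A 224       0.000   0.000   0.000  1.00  0.00           N
ATOM      2 HN   ARG A 224       1.000   0.000   0.000  1.00  0.00           H
ATOM      3 CA   ARG A 224      -0.800   1.200   0.000  1.00  0.00           C
ATOM      4 CB   ARG A 224       0.000   3.000   0.000  1.00  0.00           C
ATOM      5 O    ARG A 224      -2.200   1.000   0.800  1.00  0.00           O
HETATM    6 C1   LIG B   1       4.000   3.000   0.000  1.00  0.00           C
HETATM    7 O1   LIG B   1       2.900   0.000   0.000  1.00  0.00           O
HETATM    8 C2   LIG B   1       5.200   3.800   0.500  1.00  0.00           C
END
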