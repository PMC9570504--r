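ATOM      1 CB   ALA A  10       0.000   0.000   0.000  1.00  0.00           C
ATOM      2 CB   ALA A  11       0.000   3.000   0.000  1.00  0.00           C
ATOM      3 CB   ALA A  12       0.000   6.000   0.000  1.00  0.00           C
ATOM      4 CB   ALA A  13       0.000   9.000   0.000  1.00  0.00           C
ATOM      5 CB   ALA A  14       0.000  12.000   0.000  1.00  0.00           C
ATOM      6 CB   ALA A  15       0.000  15.000   0.000  1.00  0.00           C
ATOM      7 CB   ALA A  16       0.000  18.000   0.000  1.00  0.00           C
ATOM      8 CB   ALA A  17       0.000  21.000   0.000  1.00  0.00           C
ATOM      9 CB   LEU A  85      30.000   0.000   0.000  1.00  0.00           C
ATOM     10 CB   LEU A  86      30.000   3.000   0.000  1.00  0.00           C
ATOM     11 CB   LEU A  87      30.000   6.000   0.000  1.00  0.00           C
ATOM     12 CB   LEU A  88      30.000   9.000   0.000  1.00  0.00           C
ATOM     13 CB   LEU A  89       2.600  12.000   0.000  1.00  0.00           C
ATOM     14 CB   LEU A  90      30.000  15.000   0.000  1.00  0.00           C
ATOM     15 CB   LEU A  91      30.000  18.000   0.000  1.00  0.00           C
ATOM     16 CB   LEU A  92      30.000  21.000   0.000  1.00  0.00           C
ATOM     17 CB   LEU A  93      30.000  24.000   0.000  1.00  0.00           C
ATOM     18 CB   LEU A  94      30.000  27.000   0.000  1.00  0.00           C
ATOM     19 CB   LEU A  95      30.000  30.000   0.000  1.00  0.00           C
ATOM     20 CB   ALA B  10       0.000   0.000  15.000  1.00  0.00           C
ATOM     21 CB   ALA B  11       0.000   3.000  15.000  1.00  0.00           C
ATOM     22 CB   ALA B  12       0.000   6.000  15.000  1.00  0.00           C
ATOM     23 CB   ALA B  13       0.000   9.000  15.000  1.00  0.00           C
ATOM     24 CB   ALA B  14       0.000  12.000  15.000  1.00  0.00           C
ATOM     25 CB   ALA B  15       0.000  15.000  15.000  1.00  0.00           C
ATOM     26 CB   ALA B  16       0.000  18.000  15.000  1.00  0.00           C
ATOM     27 CB   ALA B  17       0.000  21.000  15.000  1.00  0.00           C
ATOM     28 CB   LEU B  85      30.000   0.000  15.000  1.00  0.00           C
ATOM     29 CB   LEU B  86      30.000   3.000  15.000  1.00  0.00           C
ATOM     30 CB   LEU B  87      30.000   6.000  15.000  1.00  0.00           C
ATOM     31 CB   LEU B  88      30.000   9.000  15.000  1.00  0.00           C
ATOM     32 CB   LEU B  89       3.600  12.000  15.000  1.00  0.00           C
ATOM     33 CB   LEU B  90      30.000  15.000  15.000  1.00  0.00           C
ATOM     34 CB   LEU B  91      30.000  18.000  15.000  1.00  0.00           C
ATOM     35 CB   LEU B  92      30.000  21.000  15.000  1.00  0.00           C
ATOM     36 CB   LEU B  93      30.000  24.000  15.000  1.00  0.00           C
ATOM     37 CB   LEU B  94      30.000  27.000  15.000  1.00  0.00           C
ATOM     38 CB   LEU B  95      30.000  30.000  15.000  1.00  0.00           C
END
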