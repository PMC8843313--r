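ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 20.00           N
ATOM      2  CA  ALA A   1       1.460   0.000   0.400  1.00 20.00           C
ATOM      3  C   ALA A   1       2.400   1.000   0.000  1.00 20.00           C
ATOM      4  O   ALA A   1       2.800   2.150   0.000  1.00 20.00           O
ATOM      5  N   ALA A   2       3.800   0.000   0.000  1.00 20.00           N
ATOM      6  CA  ALA A   2       5.260   0.000   0.400  1.00 20.00           C
ATOM      7  C   ALA A   2       6.200   1.000   0.000  1.00 20.00           C
ATOM      8  O   ALA A   2       6.600   2.150   0.000  1.00 20.00           O
ATOM      9  N   ALA A   3       7.600   0.000   0.000  1.00 20.00           N
ATOM     10  CA  ALA A   3       9.060   0.000   0.400  1.00 20.00           C
ATOM     11  C   ALA A   3      10.000   1.000   0.000  1.00 20.00           C
ATOM     12  O   ALA A   3      10.400   2.150   0.000  1.00 20.00           O
ATOM     13  CB AALA A   3       9.060  -1.200   1.300  0.60 20.00           C
ATOM     14  CB BALA A   3       9.860  -1.200   1.300  0.40 20.00           C
ATOM     15  N   ALA A   4      11.400   0.000   0.000  1.00 20.00           N
ATOM     16  CA  ALA A   4      12.860   0.000   0.400  1.00 20.00           C
ATOM     17  C   ALA A   4      13.800   1.000   0.000  1.00 20.00           C
ATOM     18  O   ALA A   4      14.200   2.150   0.000  1.00 20.00           O
ATOM     19  CB  ALA A   4      12.860  -1.200   1.300  1.00 20.00           C
ATOM     20  N   ALA A   5      15.200   0.000   0.000  1.00 20.00           N
ATOM     21  CA  ALA A   5      16.660   0.000   0.400  1.00 20.00           C
ATOM     22  C   ALA A   5      17.600   1.000   0.000  1.00 20.00           C
ATOM     23  O   ALA A   5      18.000   2.150   0.000  1.00 20.00           O
ATOM     24  N   ALA A   6      19.000   0.000   0.000  1.00 20.00           N
ATOM     25  CA  ALA A   6      20.460   0.000   0.400  1.00 20.00           C
ATOM     26  C   ALA A   6      21.400   1.000   0.000  1.00 20.00           C
ATOM     27  O   ALA A   6      21.800   2.150   0.000  1.00 20.00           O
ATOM     28  N   ALA A   7      22.800   0.000   0.000  1.00 20.00           N
ATOM     29  CA  ALA A   7      24.260   0.000   0.400  1.00 20.00           C
ATOM     30  C   ALA A   7      25.200   1.000   0.000  1.00 20.00           C
ATOM     31  O   ALA A   7      25.600   2.150   0.000  1.00 20.00           O
ATOM     32  N   ALA A   8      26.600   0.000   0.000  1.00 20.00           N
ATOM     33  CA  ALA A   8      28.060   0.000   0.400  1.00 20.00           C
ATOM     34  C   ALA A   8      29.000   1.000   0.000  1.00 20.00           C
ATOM     35  O   ALA A   8      29.400   2.150   0.000  1.00 20.00           O
HETATM   36  C1  LIG L   1      10.000  -3.000   4.000  1.00 20.00           C
HETATM   37  C2  LIG L   1      11.500  -3.400   3.300  1.00 22.00           C
HETATM   38  N1  LIG L   1      11.900  -1.900   2.400  1.00 25.00           N
HETATM   39  C3  LIG L   1      13.200  -1.900   2.200  1.00 24.00           C
HETATM   40  O1  LIG L   1      13.600  -0.800   1.900  1.00 26.00           O
HETATM   41  C4  LIG L   1      14.200  -3.000   2.000  1.00 48.00           C
END
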