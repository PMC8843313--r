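ATOM      1  N   ALA A   1       5.000   3.000  -2.000  1.00 25.00           N
ATOM      2  CA  ALA A   1       6.264   2.270  -1.600  1.00 25.00           C
ATOM      3  C   ALA A   1       7.578   2.666  -2.000  1.00 25.00           C
ATOM      4  O   ALA A   1       8.500   3.462  -2.000  1.00 25.00           O
ATOM      5  N   ALA A   2       8.291   1.100  -2.000  1.00 25.00           N
ATOM      6  CA  ALA A   2       9.555   0.370  -1.600  1.00 25.00           C
ATOM      7  C   ALA A   2      10.869   0.766  -2.000  1.00 25.00           C
ATOM      8  O   ALA A   2      11.791   1.562  -2.000  1.00 25.00           O
ATOM      9  N   ALA A   3      11.582  -0.800  -2.000  1.00 25.00           N
ATOM     10  CA  ALA A   3      12.846  -1.530  -1.600  1.00 25.00           C
ATOM     11  C   ALA A   3      14.160  -1.134  -2.000  1.00 25.00           C
ATOM     12  O   ALA A   3      15.082  -0.338  -2.000  1.00 25.00           O
ATOM     13  CB  ALA A   3      12.246  -2.569  -0.700  1.00 25.00           C
ATOM     14  N   ALA A   4      14.873  -2.700  -2.000  1.00 25.00           N
ATOM     15  CA  ALA A   4      16.137  -3.430  -1.600  1.00 25.00           C
ATOM     16  C   ALA A   4      17.451  -3.034  -2.000  1.00 25.00           C
ATOM     17  O   ALA A   4      18.373  -2.238  -2.000  1.00 25.00           O
ATOM     18  CB  ALA A   4      15.537  -4.469  -0.700  1.00 25.00           C
ATOM     19  N   ALA A   5      18.164  -4.600  -2.000  1.00 25.00           N
ATOM     20  CA  ALA A   5      19.428  -5.330  -1.600  1.00 25.00           C
ATOM     21  C   ALA A   5      20.742  -4.934  -2.000  1.00 25.00           C
ATOM     22  O   ALA A   5      21.663  -4.138  -2.000  1.00 25.00           O
ATOM     23  N   ALA A   6      21.454  -6.500  -2.000  1.00 25.00           N
ATOM     24  CA  ALA A   6      22.719  -7.230  -1.600  1.00 25.00           C
ATOM     25  C   ALA A   6      24.033  -6.834  -2.000  1.00 25.00           C
ATOM     26  O   ALA A   6      24.954  -6.038  -2.000  1.00 25.00           O
ATOM     27  N   ALA A   7      24.745  -8.400  -2.000  1.00 25.00           N
ATOM     28  CA  ALA A   7      26.010  -9.130  -1.600  1.00 25.00           C
ATOM     29  C   ALA A   7      27.324  -8.734  -2.000  1.00 25.00           C
ATOM     30  O   ALA A   7      28.245  -7.938  -2.000  1.00 25.00           O
ATOM     31  N   ALA A   8      28.036 -10.300  -2.000  1.00 25.00           N
ATOM     32  CA  ALA A   8      29.301 -11.030  -1.600  1.00 25.00           C
ATOM     33  C   ALA A   8      30.615 -10.634  -2.000  1.00 25.00           C
ATOM     34  O   ALA A   8      31.536  -9.838  -2.000  1.00 25.00           O
HETATM   35  C1  LIG L   1      13.026  -5.098   2.000  1.00 25.00           C
HETATM   36  C2  LIG L   1      14.125  -6.194   1.300  1.00 27.00           C
HETATM   37  N1  LIG L   1      15.222  -5.095   0.400  1.00 30.00           N
HETATM   38  C3  LIG L   1      16.348  -5.745   0.200  1.00 29.00           C
HETATM   39  O1  LIG L   1      17.244  -4.993  -0.100  1.00 31.00           O
HETATM   40  C4  LIG L   1      16.664  -7.198   0.000  1.00 53.00           C
END
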