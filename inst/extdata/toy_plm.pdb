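REMARK   3 synthetic toy fixture: one alanine residue, a palmitate-like
REMARK   3 3-carbon HETATM fragment and one water
ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N
ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C
ATOM      3  C   ALA A   1      12.697   7.139  -4.943  1.00  0.00           C
ATOM      4  O   ALA A   1      13.560   7.312  -5.806  1.00  0.00           O
ATOM      5  CB  ALA A   1      10.521   6.251  -4.120  1.00  0.00           C
TER       6      ALA A   1
HETATM    7  C1  PLM A 101       2.000   1.000   0.500  1.00  0.00           C
HETATM    8  C2  PLM A 101       3.250   1.700   0.900  1.00  0.00           C
HETATM    9  C3  PLM A 101       4.500   1.000   1.300  1.00  0.00           C
HETATM   10  O   HOH A 201       8.000   8.000   8.000  1.00  0.00           O
END
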