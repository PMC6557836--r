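ATOM      1  CA  HIS A  59      -1.500  -2.000  -1.000  1.00  0.00           C
ATOM      2  ND1 HIS A  59       2.200   0.000   0.000  1.00  0.00           N
ATOM      3  NE2 HIS A  59       0.000   0.000   0.000  1.00  0.00           N
ATOM      4  CA  CYS A 113      -1.000   1.500   4.500  1.00  0.00           C
ATOM      5  SG  CYS A 113       0.000   0.000   3.300  1.00  0.00           S
ATOM      6  CA  THR A 152       6.000   4.000   3.900  1.00  0.00           C
ATOM      7  OG1 THR A 152       4.400   2.900   2.700  1.00  0.00           O
ATOM      8  CA  HIS A 157       3.300   4.600  -1.200  1.00  0.00           C
ATOM      9  ND1 HIS A 157       2.200   2.900   0.000  1.00  0.00           N
ATOM     10  NE2 HIS A 157       4.400   2.900   0.000  1.00  0.00           N
END
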