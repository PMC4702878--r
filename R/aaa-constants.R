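# Amino-acid code tables used across modules; this file loads first.

# 3-letter -> 1-letter amino-acid codes (20 standard residues). Anything
# else renders as "X" in chain sequences.
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_123 <- setNames(names(AA_321), unname(AA_321))

STANDARD_AA <- sort(unname(AA_321))
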