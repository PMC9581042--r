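# Shared amino-acid tables and atom-set constants (loaded before the
# module files that use them at top level).

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA20 <- sort(unname(AA3_TO_1))
AA1_TO_3 <- c(stats::setNames(names(AA3_TO_1), unname(AA3_TO_1)), X = "UNK")
BACKBONE_ATOMS <- c("N", "CA", "C", "O")
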