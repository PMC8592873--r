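# Internal lookup tables shared across modules.

# Atomic masses (u), standard atomic weights.
.ELEMENT_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  `NA` = 22.990, K = 39.098, CL = 35.45, BR = 79.904, I = 126.904,
  CA = 40.078, MN = 54.938, CU = 63.546, F = 18.998
)

# Van der Waals radii (Angstrom), Chothia-style values used for SASA.
.VDW_RADIUS <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
  FE = 1.47, ZN = 1.39, MG = 1.73, `NA` = 2.27, K = 2.75, CL = 1.75,
  BR = 1.85, I = 1.98, CA = 2.31, MN = 1.61, CU = 1.40, F = 1.47
)

# Theoretical maximum residue SASA (Angstrom^2), Tien et al. style reference
# values, used to turn absolute residue SASA into relative accessibility.
.MAX_SASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# Formal side-chain charge at pH 7; histidine treated as neutral.
.AA_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0, K = 1,
  L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
  W = 0, Y = 0
)

.AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# Side-chain nitrogen atoms carrying positive charge (salt-bridge donors)
# and side-chain carboxylate oxygens (salt-bridge acceptors).
.SB_DONOR_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2")
)
.SB_ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

.WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD")
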