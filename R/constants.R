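# Published physicochemical constant tables used by the protein descriptor
# block. Sources: Kyte & Doolittle (1982) hydropathy; Guruprasad et al. (1990)
# dipeptide instability weights (DIWV); Bjellqvist et al. (1993) pKa set as
# deployed on the Expasy ProtParam server; Edelhoch/Pace molar extinction
# increments (5500 Trp, 1490 Tyr, 125 cystine); Expasy N-end-rule half-life
# table (Bachmair/Varshavsky).

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# DIWV[x, y] is the instability weight of the dipeptide x-y (x N-terminal).
# Rows/columns in the order A C D E F G H I K L M N P Q R S T V W Y.
.DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(.AA, .AA))

# Bjellqvist pKa values (Expasy ProtParam flavour). N-terminal pKa depends on
# the first residue for a handful of amino acids; all others use 7.5.
.PKA_SIDE_POS <- c(K = 10.0, R = 12.0, H = 5.98)
.PKA_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
.PKA_CTERM <- 3.55
.PKA_NTERM_DEFAULT <- 7.5
.PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
                E = 7.7)

# Expasy N-end-rule estimated half-lives in hours (mammalian reticulocytes
# in vitro, yeast in vivo, E. coli in vivo). Open-ended entries (">20 h",
# ">10 h") are encoded as their numeric bound; minutes converted to hours.
# E. coli half-life of N-terminal Pro is not listed on the server and is
# encoded as the table's modal bound (10 h).
.HALF_LIFE <- matrix(c(
  4.4,  20,     10,       # A
  1.2,  20,     10,       # C
  1.1,  0.05,   10,       # D
  1.0,  0.5,    10,       # E
  1.1,  0.05,   2 / 60,   # F
  30,   20,     10,       # G
  3.5,  10 / 60, 10,      # H
  20,   0.5,    10,       # I
  1.3,  3 / 60, 2 / 60,   # K
  5.5,  3 / 60, 2 / 60,   # L
  30,   20,     10,       # M
  1.4,  3 / 60, 10,       # N
  20,   20,     10,       # P
  0.8,  10 / 60, 10,      # Q
  1.0,  2 / 60, 2 / 60,   # R
  1.9,  20,     10,       # S
  7.2,  20,     10,       # T
  100,  20,     10,       # V
  2.8,  3 / 60, 2 / 60,   # W
  2.8,  10 / 60, 2 / 60   # Y
), nrow = 20, byrow = TRUE,
   dimnames = list(.AA, c("mammalian", "yeast", "ecoli")))

.EXT_TRP <- 5500
.EXT_TYR <- 1490
.EXT_CYSTINE <- 125
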