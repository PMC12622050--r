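# Shared amino-acid tables and geometric conventions.

#' Canonical amino-acid alphabet
#'
#' The twenty canonical one-letter amino-acid codes. Non-canonical letters
#' (including X) are rejected throughout the package.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Three-letter <-> one-letter residue codes for PDB I/O.
AA3 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
         HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
         PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
         TRP = "W", TYR = "Y")
AA1TO3 <- setNames(names(AA3), unname(AA3))

# Kyte-Doolittle hydropathy; > 0 defines "hydrophobic" for the surrogates.
KYTE_DOOLITTLE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                    H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                    P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7,
                    V = 4.2, W = -0.9, Y = -1.3)

# Theoretical maximum per-residue accessible surface area (A^2) in an
# extended Gly-X-Gly context (Tien et al. 2013, theoretical column). Used
# as the conformation-independent linear-chain reference for all-atom
# structures.
MAX_ASA_TIEN <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
                  E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
                  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
                  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Element-keyed van der Waals radii (A) for all-atom SASA; hydrogens are
# ignored at parse time.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Conventions for the C-alpha-only surrogate representation: pseudo-atom
# radius, virtual bond length, and water-probe radius.
CA_PSEUDO_RADIUS <- 3.0
CA_BOND <- 3.8
PROBE_RADIUS <- 1.4

is_hydrophobic <- function(residues) {
  KYTE_DOOLITTLE[strsplit(residues, "", fixed = TRUE)[[1]]] > 0
}

check_residues <- function(residues, id = "sequence") {
  letters <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(letters), AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-canonical residue letter(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
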