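# average residue masses (Da) and water, as used by the Expasy-style
# Compute pI/Mw calculation
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# EMBOSS pKa set; side chains plus termini
PKA_POS <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEG <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

net_charge <- function(counts, pH) {
  pos <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(pos) <- c("Nterm", "K", "R", "H")
  neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(neg) <- c("Cterm", "D", "E", "C", "Y")
  sum(pos / (1 + 10^(pH - PKA_POS[names(pos)]))) -
    sum(neg / (1 + 10^(PKA_NEG[names(neg)] - pH)))
}

#' Molecular weight and isoelectric point of a protein
#'
#' Molecular weight is the sum of average residue masses plus one water.
#' The pI is the pH at which the Henderson-Hasselbalch net charge (EMBOSS pKa
#' set, free termini included) vanishes, found by bisection on \[0, 14\] to
#' `|charge| < 1e-4`. Both are composition-only quantities.
#'
#' @param seq Protein sequence without ambiguous residues (no X).
#' @return List with `mw` (Da) and `pI` (pH units).
#' @export
compute_physchem <- function(seq) {
  seq <- unname(seq[[1]])
  chars <- strsplit(seq, "")[[1]]
  if (any(!chars %in% AA20))
    stopf("compute_physchem: ambiguous/invalid residue(s): %s",
          paste(unique(chars[!chars %in% AA20]), collapse = ", "))
  counts <- table(factor(chars, levels = AA20))
  counts <- setNames(as.numeric(counts), AA20)
  mw <- sum(counts * AA_MASS[AA20]) + WATER_MASS
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, mid)
    if (abs(q) < 1e-4 || hi - lo < 1e-12) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(mw = mw, pI = mid)
}
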