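# Pinned physicochemical tables. Average masses (Da) of the free amino
# acids; peptide mass = sum - (n - 1) waters. Kyte-Doolittle hydropathy.
# pKa values are the Lehninger set (termini from glycine).
AA_MASS <- c(A = 89.0935, R = 174.2017, N = 132.1184, D = 133.1032,
             C = 121.1590, E = 147.1293, Q = 146.1451, G = 75.0669,
             H = 155.1552, I = 131.1736, L = 131.1736, K = 146.1882,
             M = 149.2124, F = 165.1900, P = 115.1310, S = 105.0930,
             T = 119.1197, W = 204.2262, Y = 181.1894, V = 117.1469)
WATER_MASS <- 18.01528

KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

PKA <- list(positive = c(Nterm = 9.69, K = 10.53, R = 12.48, H = 6.00),
            negative = c(Cterm = 2.34, D = 3.65, E = 4.25, C = 8.18,
                         Y = 10.07))

net_charge_at_ph <- function(counts, ph) {
  npos <- c(Nterm = 1, counts[c("K", "R", "H")])
  nneg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  pos <- sum(npos / (1 + 10^(ph - PKA$positive[names(npos)])))
  neg <- sum(nneg / (1 + 10^(PKA$negative[names(nneg)] - ph)))
  pos - neg
}

#' Physicochemical feature vector of a peptide
#'
#' Deterministic, fully pinned feature set for AMP probability prediction:
#' length, the 20 amino-acid composition fractions, net charge at pH 7
#' (Henderson--Hasselbalch over the Lehninger pKa set, termini included),
#' isoelectric point (bisection on the same charge function), mean
#' Kyte--Doolittle hydropathy, cysteine fraction, and average molecular
#' weight in Da.
#'
#' @param record a [peptide_record()] or bare sequence of standard residues.
#' @return named numeric vector of 26 features.
#' @export
extract_features <- function(record) {
  seq <- if (is.character(record)) toupper(record) else record$sequence
  assert_standard_aa(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  counts <- table(factor(chars, levels = AA20))
  counts <- setNames(as.numeric(counts), AA20)
  comp <- counts / n
  # pI: net charge is strictly decreasing in pH, bisect on [0, 14]
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(counts, mid) > 0) lo <- mid else hi <- mid
  }
  c(length = n,
    setNames(comp, paste0("comp_", AA20)),
    net_charge_pH7 = net_charge_at_ph(counts, 7),
    isoelectric_point = (lo + hi) / 2,
    mean_hydrophobicity = sum(KYTE_DOOLITTLE[AA20] * counts) / n,
    cysteine_fraction = unname(comp["C"]),
    molecular_weight = sum(AA_MASS[AA20] * counts) - (n - 1) * WATER_MASS)
}

#' Feature matrix for a set of peptides
#'
#' @param records list of [peptide_record()]s or character vector.
#' @return matrix, one row per peptide.
#' @export
feature_matrix <- function(records) {
  if (is.character(records)) records <- as.list(records)
  t(vapply(records, extract_features, extract_features("ACDE")))
}
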