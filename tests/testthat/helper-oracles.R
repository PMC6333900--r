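# Independent oracles used across the suite. These re-derive results by
# different routes than the package (hard-coded codon table, regex scans,
# fixed-point root finding) so agreement is informative.

# standard genetic code, hard-coded in the classic TCAG ordering
ORACLE_AA64 <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
oracle_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  setNames(strsplit(ORACLE_AA64, "")[[1]], codons)
})

# translate one DNA string in a given frame (0-based); N codons -> X
oracle_translate <- function(dna, frame = 0) {
  n <- nchar(dna)
  if (frame + 3 > n) return("")
  starts <- seq(frame + 1, n - 2, by = 3)
  cods <- substring(dna, starts, starts + 2)
  aa <- oracle_code[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# brute-force regex extraction over all three frame translations of a set
# of reads: first AEGEF, then nearest DPAKAA, 9-mer insert, no stop/X
oracle_extract_multiset <- function(reads) {
  out <- character()
  for (f in 0:2) {
    prot <- vapply(reads, oracle_translate, character(1), frame = f,
                   USE.NAMES = FALSE)
    m <- regmatches(prot, regexec("AEGEF(.*?)DPAKAA", prot))
    ins <- vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_,
                  character(1))
    keep <- !is.na(ins) & nchar(ins) == 9 & !grepl("[*X]", ins)
    out <- c(out, ins[keep])
  }
  sort(out)
}

# fixed-point solution of the one-site mass-action equilibrium
oracle_complex <- function(M, X, K_D, N = 1) {
  b <- N * M + X + K_D
  cc <- 0
  for (k in 1:2000) {
    cn <- N * M * X / (b - cc)
    if (abs(cn - cc) < 1e-18 + 1e-14 * cn) return(cn)
    cc <- cn
  }
  cc
}

# discrete stepwise-dilution concentrations ((1 - v/V0) per step)
oracle_stepwise_conc <- function(V0, M0, Xs, vols) {
  M <- M0; X <- 0
  out <- matrix(NA_real_, length(vols), 2, dimnames = list(NULL, c("M", "X")))
  for (i in seq_along(vols)) {
    f <- 1 - vols[i] / V0
    M <- M * f
    X <- X * f + Xs * vols[i] / V0
    out[i, ] <- c(M, X)
  }
  out
}

# independent continuous-dilution heat model: separate arithmetic and a
# fixed-point root instead of the closed-form quadratic
oracle_heats <- function(protocol, N, K_D, dH, q_dil = 0) {
  V0 <- protocol$cell_volume
  dv <- cumsum(protocol$injection_volumes)
  M <- protocol$cell_conc * exp(-dv / V0)
  X <- protocol$syringe_conc * (1 - exp(-dv / V0))
  cplx <- mapply(oracle_complex, M, X, MoreArgs = list(K_D = K_D, N = N))
  Q <- V0 * dH * 1000 * cplx
  Qp <- c(0, Q[-length(Q)])
  dq <- Q - Qp + (protocol$injection_volumes / V0) * (Q + Qp) / 2
  dq / (protocol$syringe_conc * protocol$injection_volumes * 1000) + q_dil
}

# small helper: random peptide strings
random_peptides <- function(n, len = 9) {
  m <- matrix(sample(ngpd::AA_STANDARD, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
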