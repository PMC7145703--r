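# Goldman-Yang (GY94) codon substitution model over the 61 sense codons.
# Off-diagonal rates for single-nucleotide changes are pi_j multiplied by
# 1 / kappa / omega / omega*kappa for synonymous transversion / synonymous
# transition / nonsynonymous transversion / nonsynonymous transition;
# multi-step and stop-involving changes are 0.

# unscaled generator (used by the mixture machinery, which applies one
# shared scale factor across site classes)
gy94_unscaled <- function(kappa, omega, pi) {
  info <- codon_pair_info()
  n <- 61L
  fac <- matrix(0, n, n)
  fac[info$single] <- 1
  fac[info$single & info$transition] <- kappa
  nonsyn <- info$single & !info$synonymous
  fac[nonsyn] <- fac[nonsyn] * omega
  Q <- fac * rep(pi, each = n)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Build a scaled GY94 generator
#'
#' Assembles the 61x61 GY94 rate matrix for given kappa (transition/
#' transversion ratio), omega (dN/dS) and codon equilibrium frequencies,
#' scaled so the expected substitution rate at equilibrium is 1 (branch
#' lengths are then expected substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Codon frequencies (61-vector summing to 1); `NULL` uniform.
#' @return 61x61 generator matrix with row sums 0.
#' @export
build_gy94 <- function(kappa, omega, pi = NULL) {
  stopifnot(kappa > 0, omega >= 0)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  stopifnot(length(pi) == 61)
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1", call. = FALSE)
  Q <- gy94_unscaled(kappa, omega, pi)
  rate <- -sum(pi * diag(Q))
  Q / rate
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Empirical nucleotide frequencies at each codon position, multiplied
#' and renormalized over the 61 sense codons (CodeML's default codon
#' frequency model).
#'
#' @param aln A `codon_alignment`.
#' @return Numeric 61-vector summing to 1.
#' @export
codon_freqs_f3x4 <- function(aln) {
  m <- unclass(aln)
  keep <- m %in% sense_codons()
  codons <- m[keep]
  nt <- c("A", "C", "G", "T")
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, nt))
  for (p in 1:3) {
    tab <- table(factor(substring(codons, p, p), levels = nt))
    tot <- sum(tab)
    # guard against a degenerate position with a single observed base
    pos_freq[p, ] <- (as.numeric(tab) + 0.5) / (tot + 2)
  }
  sc <- sense_codons()
  pi <- pos_freq[1, substring(sc, 1, 1)] *
    pos_freq[2, substring(sc, 2, 2)] *
    pos_freq[3, substring(sc, 3, 3)]
  pi / sum(pi)
}
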