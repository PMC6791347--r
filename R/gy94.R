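#' Goldman-Yang codon substitution rate matrix
#'
#' Builds the 61x61 generator of the GY94 codon model. Codon pairs differing
#' at more than one position have rate 0; single-nucleotide changes have
#' rate pi_j multiplied by 1 (synonymous transversion), kappa (synonymous
#' transition), omega (nonsynonymous transversion) or omega*kappa
#' (nonsynonymous transition). The diagonal makes rows sum to zero.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS), >= 0.
#' @param pi equilibrium frequencies of the 61 sense codons (sum to 1).
#' @param scale if `TRUE` (default) the generator is rescaled so that the
#'   expected number of substitutions per codon per unit time is 1, i.e.
#'   -sum(pi_i q_ii) = 1, the convention under which branch lengths are in
#'   expected substitutions per codon.
#' @return a 61x61 numeric matrix with codon dimnames.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  stopifnot(length(kappa) == 1L, kappa > 0, length(omega) == 1L, omega >= 0,
            length(pi) == 61L, all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-8) stop("codon frequencies must sum to 1")
  mult <- c(1, kappa, omega, omega * kappa)
  Q <- matrix(0, 61L, 61L, dimnames = list(.codons, .codons))
  nz <- .codon_pair_class > 0L
  Q[nz] <- mult[.codon_pair_class[nz]]
  Q <- sweep(Q, 2L, pi, "*")
  diag(Q) <- -rowSums(Q)
  if (scale) {
    s <- -sum(pi * diag(Q))
    if (s > 0) Q <- Q / s
  }
  Q
}

# Spectral decomposition of a reversible generator. Because pi_i q_ij =
# pi_j q_ji, D^(1/2) Q D^(-1/2) is symmetric (D = diag(pi)) and
# P(t) = A exp(diag(lambda) t) B with A = D^(-1/2) U, B = U' D^(1/2).
# Returns A, B, lambda; P(t) = A %*% (exp(lambda * t) * B).
gy94_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / sq, B = t(e$vectors) * rep(sq, each = 61L),
       lambda = e$values)
}

#' Transition probability matrix of a codon model
#'
#' @param Q generator from [gy94_rate_matrix()].
#' @param t branch length (expected substitutions per codon).
#' @param pi the equilibrium frequencies used to build `Q`.
#' @return the 61x61 matrix expm(Q t), computed spectrally.
#' @export
gy94_transition_matrix <- function(Q, t, pi) {
  e <- gy94_eigen(Q, pi)
  P <- e$A %*% (exp(e$lambda * t) * e$B)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' F3x4 codon equilibrium frequencies
#'
#' Estimates codon frequencies from position-specific nucleotide
#' frequencies (the codeml `CodonFreq = 3` convention): the frequency of a
#' codon is the product of its three positional nucleotide frequencies,
#' with stop-codon mass removed and the remaining 61 frequencies
#' renormalized.
#'
#' @param aln a [codon_alignment()] (or a character matrix of codons).
#' @return numeric vector of 61 frequencies named by codon, summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  m <- if (inherits(aln, "CodonAlignment")) aln$codons else aln
  stopifnot(is.matrix(m), length(m) > 0L)
  counts <- matrix(0, 3L, 4L, dimnames = list(NULL, .nucs))
  for (p in 1:3) {
    ch <- substring(m, p, p)
    ch <- ch[ch %in% .nucs]
    if (length(ch) == 0L)
      stop("codon position ", p, " has no unambiguous observations")
    counts[p, ] <- tabulate(match(ch, .nucs), 4L)
  }
  fr <- counts / rowSums(counts)
  pi <- fr[1L, substring(.codons, 1L, 1L)] *
    fr[2L, substring(.codons, 2L, 2L)] *
    fr[3L, substring(.codons, 3L, 3L)]
  # guard against codons whose positional product is exactly zero: a zero
  # equilibrium frequency breaks reversibility-based diagonalization
  pi <- pmax(pi, 1e-10)
  pi <- pi / sum(pi)
  names(pi) <- .codons
  pi
}
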