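#' GY94-style codon rate matrices with branch-class omega
#'
#' The instantaneous rate from codon i to codon j is zero unless the
#' codons differ at exactly one nucleotide position and j is a sense
#' codon; otherwise it is `pi_j`, multiplied by `kappa` for transitions
#' and by the branch class omega for nonsynonymous changes.  The whole
#' matrix set is scaled so that the expected number of substitutions per
#' codon per unit branch length equals one under the background-class
#' omega, so input branch lengths read as expected substitutions per
#' codon on background branches.
#'
#' @name rate_matrix
NULL

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Structural skeleton of a codon model
#'
#' Precomputes, for a genetic code, the pairs of sense codons one
#' nucleotide apart together with transition/transversion and
#' synonymous/nonsynonymous indicators.
#'
#' @param code A `genetic_code`.
#' @return List: `codons` (sense codons, lexicographic), `pairs`
#'   (matrix of index pairs i < j), `ts` (transition flag), `ns`
#'   (nonsynonymous flag).
#' @export
codon_model_structure <- function(code = load_genetic_code()) {
  codons <- sense_codons(code)
  n <- length(codons)
  chars <- do.call(rbind, strsplit(codons, ""))
  ii <- integer(0); jj <- integer(0); ts <- logical(0); ns <- logical(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diffs <- which(chars[i, ] != chars[j, ])
      if (length(diffs) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, is_transition(chars[i, diffs], chars[j, diffs]))
      ns <- c(ns, code[[codons[i]]] != code[[codons[j]]])
    }
  }
  list(codons = codons, pairs = cbind(ii, jj), ts = ts, ns = ns)
}

codon_Q_unscaled <- function(kappa, omega, pi, struct) {
  n <- length(struct$codons)
  Q <- matrix(0, n, n, dimnames = list(struct$codons, struct$codons))
  rate <- ifelse(struct$ts, kappa, 1) * ifelse(struct$ns, omega, 1)
  i <- struct$pairs[, 1]; j <- struct$pairs[, 2]
  Q[cbind(i, j)] <- rate * pi[j]
  Q[cbind(j, i)] <- rate * pi[i]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Build scaled rate matrices for each branch class
#'
#' @param params List with `kappa`, `omega_by_class` (named, must include
#'   `background`), `codon_freqs` (pi over sense codons, summing to 1).
#' @param code A `genetic_code`.
#' @param struct Optional precomputed [codon_model_structure()].
#' @return List: `Q` (named list of rate matrices per class), `scale`
#'   (the divisor applied, from the background-class matrix).
#' @export
build_rate_matrix <- function(params, code = load_genetic_code(),
                              struct = codon_model_structure(code)) {
  pi <- params$codon_freqs
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("codon frequencies must be strictly positive and sum to 1")
  }
  if (!"background" %in% names(params$omega_by_class)) {
    stop("omega_by_class must include 'background'")
  }
  Qb <- codon_Q_unscaled(params$kappa, params$omega_by_class[["background"]],
                         pi, struct)
  mu <- -sum(pi * diag(Qb))
  if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
  Qs <- lapply(params$omega_by_class, function(w) {
    codon_Q_unscaled(params$kappa, w, pi, struct) / mu
  })
  list(Q = Qs, scale = mu)
}

#' F3x4 codon equilibrium frequencies
#'
#' Nucleotide frequencies are estimated separately at each codon
#' position from the alignment (missing codons ignored); the frequency
#' of a sense codon is the product of its three positional nucleotide
#' frequencies, renormalised over sense codons, with a small floor so
#' every frequency is strictly positive.
#'
#' @param aln A `codon_alignment`.
#' @param code A `genetic_code`.
#' @param floor Minimal frequency before renormalisation (default 1e-8).
#' @return Named numeric vector over sense codons.
#' @export
f3x4_frequencies <- function(aln, code = load_genetic_code(), floor = 1e-8) {
  codons <- aln$codons[!is.na(aln$codons)]
  chars <- do.call(rbind, strsplit(codons, ""))
  nt <- c("A", "C", "G", "T")
  fpos <- sapply(1:3, function(p) {
    tab <- table(factor(chars[, p], levels = nt))
    as.numeric(tab) / sum(tab)
  })
  sense <- sense_codons(code)
  sc <- do.call(rbind, strsplit(sense, ""))
  pi <- fpos[match(sc[, 1], nt), 1] *
    fpos[match(sc[, 2], nt), 2] *
    fpos[match(sc[, 3], nt), 3]
  pi <- pmax(pi, floor)
  stats::setNames(pi / sum(pi), sense)
}

#' Uniform codon frequencies over sense codons
#'
#' @param code A `genetic_code`.
#' @return Named numeric vector over sense codons.
#' @export
uniform_frequencies <- function(code = load_genetic_code()) {
  sense <- sense_codons(code)
  stats::setNames(rep(1 / length(sense), length(sense)), sense)
}
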