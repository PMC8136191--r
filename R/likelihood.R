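#' Codon model log-likelihood by Felsenstein pruning
#'
#' Site patterns are compressed, per-branch transition matrices are
#' obtained from the eigendecomposition of the (reversible, hence
#' symmetrizable) rate matrix of the branch's class, and the pruning
#' recursion runs in compiled code with per-pattern log-scaling.
#' Missing codons are summed over all sense states.
#'
#' @name likelihood
NULL

compress_patterns <- function(aln, tip_order, codons) {
  mat <- aln$codons[tip_order, , drop = FALSE]
  idx <- matrix(match(mat, codons), nrow = nrow(mat))
  idx[is.na(idx)] <- 0L
  key <- apply(idx, 2, paste0, collapse = ",")
  first <- !duplicated(key)
  list(tipstates = idx[, first, drop = FALSE],
       weights = as.numeric(table(key)[key[first]]),
       site_pattern = match(key, key[first]))
}

rate_eigen <- function(Q, pi) {
  # eigendecomposition of the symmetrized matrix S = D Q D^-1 with
  # D = diag(sqrt(pi)): S_ij = sqrt(pi_i) q_ij / sqrt(pi_j), symmetric
  # by reversibility
  ncod <- length(pi)
  sq <- sqrt(pi)
  A <- Q * rep(sq, times = ncod) / rep(sq, each = ncod)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values)
}

transition_matrix <- function(Q, pi, t) {
  # single P(t) = D^-1 U exp(lambda t) U' D; branch sets inside the
  # pruning call are built in C++
  e <- rate_eigen(Q, pi)
  sq <- sqrt(pi)
  M <- (e$U * rep(exp(e$lambda * t), each = length(pi))) %*% t(e$U)
  P <- pmax(M * rep(sq, each = length(pi)) / sq, 0)
  dimnames(P) <- dimnames(Q)
  P
}

#' Log-likelihood of a codon alignment under branch-class omegas
#'
#' @param aln A `codon_alignment`.
#' @param ltree A `labeled_tree`; `excluded` branches evolve under the
#'   background omega.
#' @param params List with `kappa`, `omega_by_class` (named vector with
#'   at least `background`; `foreground` where the tree has foreground
#'   branches), `codon_freqs` (over sense codons), and optional `scale`
#'   (global branch-length multiplier, default 1).
#' @param code A `genetic_code`.
#' @param struct Optional precomputed [codon_model_structure()].
#' @param patterns Optional precomputed pattern compression (internal
#'   reuse during optimisation).
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(aln, ltree, params, code = load_genetic_code(),
                           struct = codon_model_structure(code),
                           patterns = NULL) {
  phylo <- ltree$phylo
  if (is.null(phylo$edge.length)) stop("tree needs branch lengths")
  if (any(phylo$edge.length < 0)) stop("negative branch length")
  pi <- params$codon_freqs
  scale <- if (is.null(params$scale)) 1 else params$scale
  rates <- build_rate_matrix(params, code, struct)
  cls <- ltree$branch_class
  cls[cls == "excluded"] <- "background"
  if (!all(cls %in% names(rates$Q))) {
    stop("omega_by_class missing class(es): ",
         paste(setdiff(cls, names(rates$Q)), collapse = ", "))
  }
  if (is.null(patterns)) {
    patterns <- compress_patterns(aln, phylo$tip.label, struct$codons)
  }
  post <- ape::reorder.phylo(phylo, "postorder")
  # map postorder edge rows back to the original edge order used for classes
  orig <- match(paste(post$edge[, 1], post$edge[, 2]),
                paste(phylo$edge[, 1], phylo$edge[, 2]))
  # one eigendecomposition per distinct omega (classes can coincide, as in M0)
  omg <- vapply(names(rates$Q), function(cn) params$omega_by_class[[cn]],
                numeric(1))
  uniq <- !duplicated(omg)
  eig <- lapply(rates$Q[uniq], rate_eigen, pi = pi)
  class_idx <- match(omg[cls[orig]], omg[uniq])
  ncod <- length(pi)
  U <- array(0, c(ncod, ncod, length(eig)))
  lambda <- matrix(0, ncod, length(eig))
  for (k in seq_along(eig)) {
    U[, , k] <- eig[[k]]$U
    lambda[, k] <- eig[[k]]$lambda
  }
  lnL <- prune_lnL_cpp(post$edge, as.integer(class_idx),
                       post$edge.length * scale, U, lambda, pi,
                       patterns$tipstates, patterns$weights,
                       length(phylo$tip.label),
                       length(phylo$tip.label) + phylo$Nnode)
  if (!is.finite(lnL)) stop("non-finite log-likelihood")
  lnL
}
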