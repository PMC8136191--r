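# Shared fixtures: tiny trees, group tables and alignments built in code.

mito_code <- load_genetic_code("vertebrate_mitochondrial")

quartet_tree <- function(bl = 1) {
  ape::read.tree(text = sprintf(
    "((A:%g,B:%g):%g,(C:%g,D:%g):%g);", bl, bl, bl, bl, bl, bl))
}

quartet_groups <- function(fg = "A") {
  data.frame(taxon = c("A", "B", "C", "D"), group = "g",
             role = ifelse(c("A", "B", "C", "D") %in% fg,
                           "foreground", "background"),
             stringsAsFactors = FALSE)
}

quartet_alignment <- function(A, B, C, D, code = mito_code) {
  codon_alignment_from_strings(c(A = A, B = B, C = C, D = D), code)
}

# exhaustive small-parsimony oracle: minimum changes over all assignments
# of observed states to internal nodes (valid for unordered characters)
brute_force_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  obs <- unique(tip_states[!is.na(tip_states)])
  n_internal <- tree$Nnode
  grid <- expand.grid(rep(list(obs), n_internal), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(tip_states, unlist(grid[r, ]))
    changes <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- assign_all[tree$edge[e, 1]]
      ch <- assign_all[tree$edge[e, 2]]
      if (!is.na(p) && !is.na(ch) && p != ch) changes <- changes + 1L
    }
    best <- min(best, changes)
  }
  best
}

# full-enumeration two-sided Fisher oracle built directly from binomial
# coefficients (independent of dhyper)
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# choose a derived amino acid absent from the background terminal states
# at a site (the convergence criterion requires absence), preferring the
# amino acids given first
absent_derived_aa <- function(sim, site, prefer = c("P", "N", "V")) {
  lt <- sim$scenario$ltree
  phylo <- lt$phylo
  tip_edges <- phylo$edge[, 2] <= length(phylo$tip.label)
  bg_tips <- phylo$edge[tip_edges & lt$branch_class == "background", 2]
  bg_aa <- translate_codons(sim$node_states[bg_tips, site], mito_code)
  cands <- setdiff(c(prefer, selsig:::AA1), bg_aa)
  cands[1]
}

# a 17-region cytochrome-b style domain map tiling a 381-codon protein
cytb_style_domains <- function() {
  widths <- c(33, 10, 25, 12, 30, 11, 28, 10, 26, 12, 31, 11, 27, 10, 29, 12, 64)
  cls <- rep(c("membrane", "transmembrane"), length.out = 17)
  name <- paste0(ifelse(cls == "membrane", "Memb", "TM"),
                 ave(seq_len(17), cls, FUN = seq_along))
  start <- cumsum(c(1, widths[-17]))
  df <- data.frame(name = name, class = cls, start = start,
                   end = start + widths - 1L, stringsAsFactors = FALSE)
  selsig:::validate_domain_map(df, 381)
}
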