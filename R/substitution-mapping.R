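#' Parsimony mapping of codon substitutions onto branches
#'
#' Ancestral codon states are reconstructed per site by Fitch parsimony
#' over the sense-codon state space, and a substitution event is emitted
#' for every (branch, site) where the reconstructed parent and child
#' states differ.  Multi-nucleotide codon changes are decomposed into
#' synonymous and nonsynonymous single-nucleotide steps by stop-free
#' pathway averaging (Nei-Gojobori style).
#'
#' @name substitution_mapping
NULL

#' Fitch parsimony ancestral codon states
#'
#' Bottom-up pass: at each internal node the candidate set is the
#' intersection of the child sets when nonempty, else their union (one
#' change counted).  Missing leaves contribute the full sense-codon set
#' and impose no constraint.  Top-down resolution prefers the parent's
#' resolved state whenever it is in the node's candidate set (a
#' DELTRAN-like rule that pushes changes tipward), otherwise picks the
#' lexicographically smallest candidate; the result is deterministic.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `labeled_tree` (or `phylo`) whose leaves match the
#'   alignment taxa.
#' @param code A `genetic_code`.
#' @return List of class `ancestral_states`: `states` (node x site codon
#'   matrix, tips first in `tree$tip.label` order), `candidates` (per
#'   site, per internal node, the pre-resolution candidate set),
#'   `changes` (per-site Fitch change count), `all_missing` (logical per
#'   site).
#' @export
fitch_states <- function(aln, tree, code = load_genetic_code()) {
  phylo <- if (inherits(tree, "labeled_tree")) tree$phylo else tree
  stopifnot(inherits(phylo, "phylo"))
  if (!setequal(phylo$tip.label, aln$taxa)) {
    stop("tree leaves and alignment taxa differ")
  }
  if (length(phylo$tip.label) < 3L) stop("need at least 3 taxa")
  if (!ape::is.binary(phylo)) stop("fitch_states requires a binary tree")
  ntip <- length(phylo$tip.label)
  nnode <- ntip + phylo$Nnode
  obs <- aln$codons[phylo$tip.label, , drop = FALSE]
  sense <- sense_codons(code)
  kids <- child_list(phylo)
  post <- postorder_nodes(phylo)           # children before parents
  post_internal <- post[post > ntip]
  states <- matrix(NA_character_, nnode, aln$sites)
  states[seq_len(ntip), ] <- obs           # tip rows in tip.label order
  candidates <- vector("list", aln$sites)
  changes <- integer(aln$sites)
  all_missing <- logical(aln$sites)
  root <- ntip + 1L
  pre_internal <- rev(post_internal)       # parents before children
  parent_of <- integer(nnode)
  parent_of[phylo$edge[, 2]] <- phylo$edge[, 1]
  for (s in seq_len(aln$sites)) {
    tip_codons <- obs[, s]
    if (all(is.na(tip_codons))) {
      all_missing[s] <- TRUE
      candidates[[s]] <- list()
      next
    }
    sets <- vector("list", nnode)
    for (i in seq_len(ntip)) {
      sets[[i]] <- if (is.na(tip_codons[i])) sense else tip_codons[i]
    }
    nch <- 0L
    for (nd in post_internal) {
      ch <- kids[[nd]]
      acc <- sets[[ch[1]]]
      for (c2 in ch[-1]) {
        inter <- intersect(acc, sets[[c2]])
        if (length(inter)) {
          acc <- inter
        } else {
          acc <- union(acc, sets[[c2]])
          nch <- nch + 1L
        }
      }
      sets[[nd]] <- acc
    }
    changes[s] <- nch
    for (nd in pre_internal) {
      cand <- sets[[nd]]
      if (nd == root) {
        states[nd, s] <- min(cand)
      } else {
        p_state <- states[parent_of[nd], s]
        states[nd, s] <- if (p_state %in% cand) p_state else min(cand)
      }
    }
    candidates[[s]] <- sets[(ntip + 1L):nnode]
  }
  structure(list(states = states, candidates = candidates, changes = changes,
                 all_missing = all_missing, ntip = ntip,
                 tip_order = phylo$tip.label),
            class = "ancestral_states")
}

#' Decompose a codon change into synonymous/nonsynonymous steps
#'
#' All orderings of the single-nucleotide steps from `from_codon` to
#' `to_codon` are enumerated; pathways passing through a stop codon are
#' discarded; each surviving step is scored synonymous or nonsynonymous
#' under `code` and counts are averaged over surviving pathways.  If every
#' pathway is blocked by stops the decomposition falls back to direct
#' endpoint comparison (all steps synonymous when the amino acid is
#' conserved, otherwise one nonsynonymous plus synonymous remainder) and
#' the result is flagged.
#'
#' @param from_codon,to_codon Distinct sense codons.
#' @param code A `genetic_code`.
#' @return Named list: `n_syn`, `n_nonsyn` (summing to the nucleotide
#'   Hamming distance), `blocked` flag.
#' @export
classify_codon_change <- function(from_codon, to_codon,
                                  code = load_genetic_code()) {
  if (from_codon == to_codon) stop("codons are identical")
  if (code[[from_codon]] == "*" || code[[to_codon]] == "*") {
    stop("stop codon passed to classify_codon_change")
  }
  f <- strsplit(from_codon, "")[[1]]
  t_ <- strsplit(to_codon, "")[[1]]
  diff_pos <- which(f != t_)
  h <- length(diff_pos)
  orderings <- switch(h,
    list(diff_pos),
    list(diff_pos, rev(diff_pos)),
    {
      p <- diff_pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  syn_tot <- 0
  nonsyn_tot <- 0
  n_ok <- 0L
  for (ord in orderings) {
    cur <- f
    ns <- 0L
    nn <- 0L
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- t_[p]
      aa_cur <- code[[paste0(cur, collapse = "")]]
      aa_nxt <- code[[paste0(nxt, collapse = "")]]
      if (aa_nxt == "*") { ok <- FALSE; break }
      if (aa_cur == aa_nxt) ns <- ns + 1L else nn <- nn + 1L
      cur <- nxt
    }
    if (ok) {
      syn_tot <- syn_tot + ns
      nonsyn_tot <- nonsyn_tot + nn
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) {
    aa_same <- code[[from_codon]] == code[[to_codon]]
    return(list(n_syn = if (aa_same) h else h - 1,
                n_nonsyn = if (aa_same) 0 else 1, blocked = TRUE))
  }
  list(n_syn = syn_tot / n_ok, n_nonsyn = nonsyn_tot / n_ok, blocked = FALSE)
}

#' Enumerate substitution events on branches
#'
#' One event per (branch, site) where the reconstructed parent and child
#' codon states differ; each event carries the branch class and the
#' syn/nonsyn decomposition from [classify_codon_change()].
#'
#' @param states An `ancestral_states` from [fitch_states()].
#' @param ltree The `labeled_tree` the states were computed on.
#' @param code A `genetic_code`.
#' @return `data.frame` with columns `branch`, `parent_node`,
#'   `child_node`, `branch_class`, `site`, `from_codon`, `to_codon`,
#'   `n_syn`, `n_nonsyn`, `from_aa`, `to_aa`.
#' @export
map_events <- function(states, ltree, code = load_genetic_code()) {
  stopifnot(inherits(states, "ancestral_states"),
            inherits(ltree, "labeled_tree"))
  edge <- ltree$phylo$edge
  out <- vector("list", 256)
  n_out <- 0L
  for (i in seq_len(nrow(edge))) {
    p_states <- states$states[edge[i, 1], ]
    c_states <- states$states[edge[i, 2], ]
    hit <- which(!is.na(p_states) & !is.na(c_states) & p_states != c_states)
    for (s in hit) {
      dec <- classify_codon_change(p_states[s], c_states[s], code)
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- data.frame(
        branch = i, parent_node = edge[i, 1], child_node = edge[i, 2],
        branch_class = ltree$branch_class[i], site = s,
        from_codon = p_states[s], to_codon = c_states[s],
        n_syn = dec$n_syn, n_nonsyn = dec$n_nonsyn,
        from_aa = code[[p_states[s]]], to_aa = code[[c_states[s]]],
        stringsAsFactors = FALSE)
    }
  }
  if (n_out == 0L) {
    return(data.frame(branch = integer(), parent_node = integer(),
                      child_node = integer(), branch_class = character(),
                      site = integer(), from_codon = character(),
                      to_codon = character(), n_syn = numeric(),
                      n_nonsyn = numeric(), from_aa = character(),
                      to_aa = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(n_out)])
  res <- res[order(res$branch, res$site), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write mapped events to TSV
#'
#' @param events Event table from [map_events()].
#' @param path Output TSV.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
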