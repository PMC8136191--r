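#' Convergent substitutions across independent foreground lineages
#'
#' A site shows convergence when the same derived amino acid arises on
#' several phylogenetically independent foreground lineages (foreground
#' branches that do not share a foreground ancestor), and that amino acid
#' is absent from every background terminal sequence at the site --
#' the criterion behind replacements typical of several unrelated
#' subterranean lineages.
#'
#' @param events Event table from [map_events()].
#' @param ltree The `labeled_tree` the events were mapped on.
#' @param aln The `codon_alignment` (for background terminal states).
#' @param code A `genetic_code`.
#' @param min_lineages Minimal number of independent foreground lineages
#'   carrying the derived amino acid (default 3).
#' @param require_radical If `TRUE`, keep only sites where at least one
#'   of the contributing events is flagged radical.
#' @param radical Logical vector along `events` rows (from
#'   [radical_events()]); required when `require_radical = TRUE`.
#' @details Lineages are witnessed either by a mapped foreground event
#'   ending in the derived amino acid or by a foreground leaf carrying
#'   it: because the amino acid must be absent from every background
#'   leaf, a foreground leaf state is itself evidence of a derived
#'   replacement on that terminal lineage even when parsimony, facing an
#'   ambiguous tie, placed the compensating event elsewhere.
#' @return `data.frame`: `site`, `derived_aa`, `n_lineages`, `lineages`
#'   (comma-separated lineage ids), `radical`.
#' @export
find_convergent <- function(events, ltree, aln, code = load_genetic_code(),
                            min_lineages = 3L, require_radical = FALSE,
                            radical = NULL) {
  if (require_radical && is.null(radical)) {
    stop("require_radical = TRUE needs the 'radical' flag vector")
  }
  lin <- foreground_lineages(ltree)
  fg_ev <- which(events$branch_class == "foreground" &
                   events$from_aa != events$to_aa)
  empty <- data.frame(site = integer(), derived_aa = character(),
                      n_lineages = integer(), lineages = character(),
                      radical = logical(), stringsAsFactors = FALSE)
  phylo <- ltree$phylo
  ntip <- length(phylo$tip.label)
  tip_edges <- which(phylo$edge[, 2] <= ntip)
  bg_edges <- tip_edges[ltree$branch_class[tip_edges] == "background"]
  fg_tip_edges <- tip_edges[ltree$branch_class[tip_edges] == "foreground"]
  bg_taxa <- phylo$tip.label[phylo$edge[bg_edges, 2]]
  bg_aa <- matrix(translate_codons(aln$codons[bg_taxa, , drop = FALSE], code),
                  nrow = length(bg_taxa))
  fg_taxa <- phylo$tip.label[phylo$edge[fg_tip_edges, 2]]
  fg_leaf_aa <- matrix(
    translate_codons(aln$codons[fg_taxa, , drop = FALSE], code),
    nrow = length(fg_taxa))
  # candidate (site, derived aa) pairs from mapped foreground events and
  # from foreground leaf states
  cand <- unique(rbind(
    data.frame(site = events$site[fg_ev], aa = events$to_aa[fg_ev],
               stringsAsFactors = FALSE),
    data.frame(site = rep(seq_len(aln$sites), each = length(fg_taxa)),
               aa = as.vector(fg_leaf_aa),
               stringsAsFactors = FALSE)))
  cand <- cand[!is.na(cand$aa), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ev_key <- paste(events$site[fg_ev], events$to_aa[fg_ev])
  out <- lapply(seq_len(nrow(cand)), function(r) {
    site <- cand$site[r]
    aa <- cand$aa[r]
    if (any(!is.na(bg_aa[, site]) & bg_aa[, site] == aa)) return(NULL)
    idx <- fg_ev[ev_key == paste(site, aa)]
    branches <- events$branch[idx]
    # foreground leaves carrying the amino acid witness their terminal
    # branch even when the mapped event was placed elsewhere by a tie
    carrier <- !is.na(fg_leaf_aa[, site]) & fg_leaf_aa[, site] == aa
    branches <- unique(c(branches, fg_tip_edges[carrier]))
    if (length(branches) == 0L) return(NULL)
    lineages <- sort(unique(lin[branches]))
    if (length(lineages) < min_lineages) return(NULL)
    rad <- if (is.null(radical)) FALSE else any(radical[idx])
    if (require_radical && !rad) return(NULL)
    data.frame(site = site, derived_aa = aa,
               n_lineages = length(lineages),
               lineages = paste(lineages, collapse = ","),
               radical = rad, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$site, out$derived_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
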