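#' Group assignments and branch labeling
#'
#' Contrasts and branch models need every branch of the input phylogeny
#' assigned to one of three classes: `foreground` (the focal lineages,
#' e.g. subterranean species), `background` (everything else retained in
#' the contrast) or `excluded` (outgroup branches, dropped from counting
#' contrasts).  A `labeled_tree` couples an `ape::phylo` with one class
#' per edge.
#'
#' @name tree_labeling
NULL

#' Read a taxon -> group table
#'
#' @param path TSV with columns `taxon`, `group`, `role`; `role` must be
#'   one of `foreground`, `background`, `outgroup`.
#' @return A `data.frame` with those three columns.
#' @export
read_group_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_group_table(df)
}

validate_group_table <- function(df) {
  need <- c("taxon", "group", "role")
  if (!all(need %in% names(df))) {
    stop("group table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$role), c("foreground", "background", "outgroup"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$taxon)) stop("duplicate taxon in group table")
  df[need]
}

#' Label tree branches as foreground / background / excluded
#'
#' In `terminal` mode only the pendant branches of foreground taxa are
#' labeled foreground.  In `clade` mode the stem and all internal branches
#' of every maximal all-foreground clade are labeled foreground as well,
#' so a monophyletic group of foreground species (an *Ellobius*-like
#' clade) is treated as a single colonisation event.  Branches leading
#' only to outgroup taxa are labeled `excluded` in both modes; everything
#' else is `background`.
#'
#' @param tree A rooted `ape::phylo` with branch lengths, or a Newick
#'   file path.
#' @param groups Group table as from [read_group_table()].
#' @param mode `"terminal"` or `"clade"`.
#' @return A `labeled_tree`: list with `phylo` and `branch_class`
#'   (character vector along `phylo$edge` rows).
#' @export
label_branches <- function(tree, groups, mode = c("clade", "terminal")) {
  mode <- match.arg(mode)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  groups <- validate_group_table(groups)
  unassigned <- setdiff(tree$tip.label, groups$taxon)
  if (length(unassigned)) {
    stop("leaves missing from group table: ", paste(unassigned, collapse = ", "))
  }
  role <- stats::setNames(groups$role, groups$taxon)[tree$tip.label]
  if (!any(role == "foreground")) {
    warning("no foreground taxa on this tree; contrasts will refuse")
  }
  ntip <- length(tree$tip.label)
  # role of each node: tips from the table, internal nodes by unanimity of
  # their descendant leaves ("mixed" otherwise)
  node_role <- character(ntip + tree$Nnode)
  node_role[seq_len(ntip)] <- role
  post <- postorder_nodes(tree)
  kids <- child_list(tree)
  for (nd in post) {
    if (nd <= ntip) next
    rr <- unique(node_role[kids[[nd]]])
    node_role[nd] <- if (length(rr) == 1L) rr else "mixed"
  }
  root <- ntip + 1L
  if (mode == "clade" && node_role[root] == "foreground") {
    stop("all leaves are foreground: clade-mode labeling spans the root")
  }
  child <- tree$edge[, 2]
  cls <- rep("background", nrow(tree$edge))
  if (mode == "terminal") {
    cls[child <= ntip & node_role[child] == "foreground"] <- "foreground"
  } else {
    cls[node_role[child] == "foreground"] <- "foreground"
  }
  cls[node_role[child] == "outgroup"] <- "excluded"
  structure(list(phylo = tree, branch_class = cls), class = "labeled_tree")
}

postorder_nodes <- function(tree) {
  # children strictly before parents: reverse of a preorder walk
  ord <- ape::reorder.phylo(tree, "cladewise")
  root <- length(tree$tip.label) + 1L
  rev(c(root, ord$edge[, 2]))
}

child_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("Labeled tree:", length(x$phylo$tip.label), "leaves;",
      sum(x$branch_class == "foreground"), "foreground /",
      sum(x$branch_class == "background"), "background /",
      sum(x$branch_class == "excluded"), "excluded branches\n")
  invisible(x)
}

#' Count branches in each class
#'
#' @param ltree A `labeled_tree`.
#' @return Named integer vector over the three classes.
#' @export
branch_class_counts <- function(ltree) {
  out <- table(factor(ltree$branch_class,
                      levels = c("foreground", "background", "excluded")))
  stats::setNames(as.integer(out), names(out))
}

#' Independent foreground lineages
#'
#' Foreground branches that are connected to each other through foreground
#' ancestors form a single lineage (one colonisation event); branches in
#' different connected components are phylogenetically independent.
#'
#' @param ltree A `labeled_tree`.
#' @return Integer vector along edges: lineage id for foreground branches,
#'   `NA` elsewhere.
#' @export
foreground_lineages <- function(ltree) {
  tree <- ltree$phylo
  fg <- ltree$branch_class == "foreground"
  lin <- rep(NA_integer_, nrow(tree$edge))
  # edge index by child node for parent lookup
  edge_of_child <- integer(length(tree$tip.label) + tree$Nnode)
  edge_of_child[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  nxt <- 0L
  ord <- ape::reorder.phylo(tree, "postorder")
  # preorder over original edge indices: parents before children
  pre <- rev(seq_len(nrow(ord$edge)))
  for (k in pre) {
    i <- edge_of_child[ord$edge[k, 2]]
    if (!fg[i]) next
    parent_edge <- edge_of_child[tree$edge[i, 1]]
    if (parent_edge > 0L && fg[parent_edge] && !is.na(lin[parent_edge])) {
      lin[i] <- lin[parent_edge]
    } else {
      nxt <- nxt + 1L
      lin[i] <- nxt
    }
  }
  lin
}
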