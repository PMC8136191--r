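#' Gillespie simulation of codon sequences along a labeled tree
#'
#' Sequences evolve site-independently under the branch-class GY94-style
#' rate matrices of [build_rate_matrix()]: the root codon of each site
#' is drawn from pi, then along every branch substitutions are realised
#' by exact (Gillespie) simulation under that branch's class omega, so
#' the full substitution history exists as ground truth.  Replaying the
#' history along the tree reproduces the emitted leaf sequences exactly.
#'
#' @name synthetic_data
NULL

#' Define a simulation scenario
#'
#' @param ltree A `labeled_tree` with branch lengths in expected
#'   substitutions per codon (under the background omega).
#' @param n_sites Number of codon sites (default 381, a cytochrome-b
#'   sized protein).
#' @param code A `genetic_code`.
#' @param kappa Transition/transversion rate ratio.
#' @param omega Named vector of omega per branch class (needs
#'   `background`; `foreground` where present on the tree).
#' @param codon_freqs `"uniform"` or a named vector over sense codons.
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return A `sim_scenario` list.
#' @export
simulation_scenario <- function(ltree, n_sites = 381L,
                                code = load_genetic_code(), kappa = 4,
                                omega = c(foreground = 0.08, background = 0.03),
                                codon_freqs = "uniform", seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (identical(codon_freqs, "uniform")) codon_freqs <- uniform_frequencies(code)
  structure(list(ltree = ltree, n_sites = as.integer(n_sites), code = code,
                 kappa = kappa, omega = omega, codon_freqs = codon_freqs,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a codon alignment and its true substitution history
#'
#' @param scenario A `sim_scenario` from [simulation_scenario()].
#' @return List of class `sim_result`: `aln` (a `codon_alignment`),
#'   `history` (`data.frame`: `branch`, `site`, `from_codon`,
#'   `to_codon`, `time` along the branch), `node_states` (node x site
#'   codon matrix), `scenario`.
#' @export
simulate_codon_alignment <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(scenario$seed)
  ltree <- scenario$ltree
  phylo <- ltree$phylo
  code <- scenario$code
  struct <- codon_model_structure(code)
  params <- list(kappa = scenario$kappa, omega_by_class = scenario$omega,
                 codon_freqs = scenario$codon_freqs)
  cls <- ltree$branch_class
  cls[cls == "excluded"] <- "background"
  rates <- build_rate_matrix(params, code, struct)
  sense <- struct$codons
  # per class: total exit rate per codon and transition distribution rows
  machinery <- lapply(rates$Q, function(Q) {
    exit <- -diag(Q)
    probs <- Q
    diag(probs) <- 0
    probs <- probs / ifelse(exit > 0, exit, 1)
    list(exit = exit, probs = probs)
  })
  ntip <- length(phylo$tip.label)
  nnode <- ntip + phylo$Nnode
  node_states <- matrix(NA_integer_, nnode, scenario$n_sites)
  root <- ntip + 1L
  node_states[root, ] <- sample.int(length(sense), scenario$n_sites,
                                    replace = TRUE,
                                    prob = scenario$codon_freqs)
  post <- ape::reorder.phylo(phylo, "postorder")
  orig <- match(paste(post$edge[, 1], post$edge[, 2]),
                paste(phylo$edge[, 1], phylo$edge[, 2]))
  pre <- rev(seq_len(nrow(post$edge)))   # parents before children
  hist_rows <- list()
  for (k in pre) {
    i <- orig[k]                         # original edge index
    p <- phylo$edge[i, 1]; ch <- phylo$edge[i, 2]
    t_total <- phylo$edge.length[i]
    mach <- machinery[[cls[i]]]
    state <- node_states[p, ]
    for (s in seq_len(scenario$n_sites)) {
      t_now <- 0
      repeat {
        rate <- mach$exit[state[s]]
        if (rate <= 0) break
        t_now <- t_now + stats::rexp(1, rate)
        if (t_now >= t_total) break
        nxt <- sample.int(length(sense), 1L, prob = mach$probs[state[s], ])
        hist_rows[[length(hist_rows) + 1L]] <- c(i, s, state[s], nxt, t_now)
        state[s] <- nxt
      }
    }
    node_states[ch, ] <- state
  }
  history <- if (length(hist_rows)) {
    h <- do.call(rbind, hist_rows)
    data.frame(branch = as.integer(h[, 1]), site = as.integer(h[, 2]),
               from_codon = sense[h[, 3]], to_codon = sense[h[, 4]],
               time = h[, 5], stringsAsFactors = FALSE)
  } else {
    data.frame(branch = integer(), site = integer(),
               from_codon = character(), to_codon = character(),
               time = numeric(), stringsAsFactors = FALSE)
  }
  codons <- matrix(sense[node_states[seq_len(ntip), ]], ntip,
                   dimnames = list(phylo$tip.label, NULL))
  aln <- new_codon_alignment(codons, code)
  state_mat <- matrix(sense[node_states], nnode)
  structure(list(aln = aln, history = history, node_states = state_mat,
                 scenario = scenario),
            class = "sim_result")
}

#' Replay a substitution history along the tree
#'
#' Starting from the recorded root states, applies the history's events
#' branch by branch; used to verify that the emitted alignment and the
#' event log agree exactly.
#'
#' @param sim A `sim_result`.
#' @return Leaf codon matrix in `tip.label` order.
#' @export
replay_history <- function(sim) {
  phylo <- sim$scenario$ltree$phylo
  ntip <- length(phylo$tip.label)
  nnode <- ntip + phylo$Nnode
  states <- matrix(NA_character_, nnode, sim$scenario$n_sites)
  states[ntip + 1L, ] <- sim$node_states[ntip + 1L, ]
  post <- ape::reorder.phylo(phylo, "postorder")
  orig <- match(paste(post$edge[, 1], post$edge[, 2]),
                paste(phylo$edge[, 1], phylo$edge[, 2]))
  for (k in rev(seq_len(nrow(post$edge)))) {
    i <- orig[k]
    p <- phylo$edge[i, 1]; ch <- phylo$edge[i, 2]
    state <- states[p, ]
    ev <- sim$history[sim$history$branch == i, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    for (r in seq_len(nrow(ev))) state[ev$site[r]] <- ev$to_codon[r]
    states[ch, ] <- state
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- phylo$tip.label
  out
}

#' A study-like simulation scenario
#'
#' A fixed 31-leaf tree with five phylogenetically independent
#' foreground lineages -- one early-diverging singleton, one four-leaf
#' foreground clade and three singletons scattered among the background
#' clades -- mimicking the phylogenetic layout of subterranean lineages
#' within a vole radiation.  Branch lengths are in expected
#' substitutions per codon.  Defaults: 381 codons, kappa 4, background
#' omega 0.03, foreground omega 0.08, vertebrate mitochondrial code,
#' uniform codon frequencies.
#'
#' @param seed Integer seed for any simulation run from the scenario.
#' @param omega_fg,omega_bg Foreground and background omega.
#' @param n_sites Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @return A `sim_scenario`; its `ltree` has 11 foreground branches in
#'   clade mode (4 tips + 2 internal + 1 stem + 4 singleton tips).
#' @export
study_like_scenario <- function(seed, omega_fg = 0.08, omega_bg = 0.03,
                                n_sites = 381L, kappa = 4) {
  nwk <- paste0(
    "(Fg_early:0.45,((((Fg_cl1:0.05,Fg_cl2:0.06):0.04,",
    "(Fg_cl3:0.05,Fg_cl4:0.04):0.05):0.10,((B01:0.09,B02:0.10):0.05,",
    "(B03:0.08,(B04:0.06,B05:0.07):0.04):0.05):0.06):0.08,",
    "((((Fg_sc1:0.12,(B06:0.07,B07:0.06):0.04):0.05,((B08:0.08,B09:0.07):0.04,",
    "B10:0.09):0.04):0.05,((Fg_sc2:0.11,(B11:0.06,B12:0.05):0.05):0.06,",
    "(B13:0.07,(B14:0.05,B15:0.06):0.03):0.05):0.04):0.06,",
    "(((Fg_sc3:0.10,(B16:0.06,B17:0.07):0.04):0.05,(B18:0.08,B19:0.07):0.05):0.04,",
    "((B20:0.07,B21:0.08):0.04,(B22:0.06,B23:0.05):0.05):0.05):0.05):0.07):0.10);")
  tree <- ape::read.tree(text = nwk)
  groups <- data.frame(
    taxon = tree$tip.label,
    group = ifelse(grepl("^Fg_cl", tree$tip.label), "fg_clade",
                   ifelse(grepl("^Fg", tree$tip.label), "fg_single",
                          "surface")),
    role = ifelse(grepl("^Fg", tree$tip.label), "foreground", "background"),
    stringsAsFactors = FALSE)
  ltree <- label_branches(tree, groups, mode = "clade")
  simulation_scenario(ltree, n_sites = n_sites, kappa = kappa,
                      omega = c(foreground = omega_fg, background = omega_bg),
                      seed = seed)
}

#' Spike convergent replacements into a simulated data set
#'
#' Forces the chosen derived amino acid at one site onto whole
#' foreground lineages: for each targeted lineage the event is placed on
#' the lineage's stem branch (the foreground branch without a foreground
#' parent), any downstream events at that site inside the lineage are
#' removed, and all leaves of the lineage inherit the closest codon (by
#' nucleotide distance, ties broken lexicographically) encoding the
#' derived amino acid.
#'
#' @param sim A `sim_result`.
#' @param site Codon site to spike.
#' @param derived_aa One-letter amino acid.
#' @param lineages Integer ids of target lineages, as numbered by
#'   [foreground_lineages()] on the scenario's tree.
#' @return The modified `sim_result`.
#' @export
spike_convergence <- function(sim, site, derived_aa, lineages) {
  scen <- sim$scenario
  ltree <- scen$ltree
  phylo <- ltree$phylo
  code <- scen$code
  if (site < 1L || site > scen$n_sites) stop("spike site outside alignment")
  lin <- foreground_lineages(ltree)
  ntip <- length(phylo$tip.label)
  tip_edges <- phylo$edge[, 2] <= ntip
  bg_tips <- phylo$edge[tip_edges & ltree$branch_class == "background", 2]
  bg_aa <- translate_codons(sim$node_states[bg_tips, site], code)
  if (any(!is.na(bg_aa) & bg_aa == derived_aa)) {
    warning("derived amino acid already present in background at site ", site,
            "; convergence detection will not report this site")
  }
  sense <- sense_codons(code)
  targets <- sense[code[sense] == derived_aa]
  if (length(targets) == 0L) stop("amino acid not encodable: ", derived_aa)
  edge_of_child <- integer(ntip + phylo$Nnode)
  edge_of_child[phylo$edge[, 2]] <- seq_len(nrow(phylo$edge))
  kids <- child_list(phylo)
  for (lg in lineages) {
    edges <- which(!is.na(lin) & lin == lg)
    if (length(edges) == 0L) stop("no such foreground lineage: ", lg)
    parents_fg <- edge_of_child[phylo$edge[edges, 1]]
    stem <- edges[!(parents_fg %in% edges)]
    stopifnot(length(stem) == 1L)
    from <- sim$node_states[phylo$edge[stem, 1], site]
    hd <- vapply(targets, function(tc) {
      sum(strsplit(tc, "")[[1]] != strsplit(from, "")[[1]])
    }, integer(1))
    target <- targets[order(hd, targets)][1]
    # nodes below (and including) the stem's child
    below <- phylo$edge[stem, 2]
    queue <- below
    while (length(queue)) {
      nd <- queue[1]; queue <- queue[-1]
      queue <- c(queue, kids[[nd]])
      below <- c(below, kids[[nd]])
    }
    below <- unique(below)
    sub_edges <- c(stem, edge_of_child[setdiff(below, phylo$edge[stem, 2])])
    drop <- sim$history$site == site & sim$history$branch %in% sub_edges
    sim$history <- sim$history[!drop, , drop = FALSE]
    if (target != from) {
      sim$history <- rbind(sim$history, data.frame(
        branch = stem, site = site, from_codon = from, to_codon = target,
        time = phylo$edge.length[stem] / 2, stringsAsFactors = FALSE))
    }
    sim$node_states[below, site] <- target
    leaf_below <- below[below <= ntip]
    sim$aln$codons[phylo$tip.label[leaf_below], site] <- target
  }
  sim$history <- sim$history[order(sim$history$branch, sim$history$site,
                                   sim$history$time), , drop = FALSE]
  rownames(sim$history) <- NULL
  sim
}
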