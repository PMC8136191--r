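test_that("fisher_exact matches hand-enumerated tables", {
  # margins (4,4,4,4): five tables, two-sided mass 34/70
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70)
  # two extreme tables each with probability 1/C(10,5)
  expect_equal(fisher_exact(c(5, 0, 0, 5)), 2 / 252)
  # any zero margin leaves a single attainable table
  expect_equal(fisher_exact(c(0, 0, 3, 7)), 1)
  expect_equal(fisher_exact(c(0, 4, 0, 6)), 1)
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("fisher_exact is invariant under row and column swaps", {
  set.seed(7)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(tab[2:1, ]), p)
    expect_equal(fisher_exact(tab[, 2:1]), p)
    expect_equal(fisher_exact(t(tab)), p)
  }
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(11)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})

test_that("holm_adjust reproduces step-down arithmetic and edge cases", {
  expect_equal(holm_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.03, 1), 0.03)
  # equals Bonferroni for a single test against a larger family
  expect_equal(holm_adjust(0.002, 10), 0.02)
  expect_error(holm_adjust(c(0.1, 0.2), 1), "family_size")
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  # monotone nondecreasing in sorted order, >= raw, <= capped Bonferroni
  set.seed(3)
  p <- runif(20)
  adj <- holm_adjust(p, 34)
  expect_true(all(adj >= p))
  expect_true(all(adj <= pmin(1, 34 * p) + 1e-12))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("domain contrasts build the documented 2x2 tables", {
  # domain of 10 codons: 9 fg NS events over 20 fg branches, 2 bg NS
  # events over 40 bg branches -> [[9,191],[2,398]]
  fake_events <- function(n_fg, n_bg, sites_fg, sites_bg) {
    data.frame(branch = seq_len(n_fg + n_bg),
               parent_node = 1L, child_node = 2L,
               branch_class = c(rep("foreground", n_fg), rep("background", n_bg)),
               site = c(sites_fg, sites_bg),
               from_codon = "ATT", to_codon = "GTT",
               n_syn = 0, n_nonsyn = 1,
               from_aa = "I", to_aa = "V", stringsAsFactors = FALSE)
  }
  # build a labeled tree with exactly 20 fg and 40 bg branches
  tr <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:31, ":1", collapse = ","), ");"))
  tr <- ape::compute.brlen(ape::multi2di(tr), 1)
  grp <- data.frame(taxon = paste0("t", 1:31), group = "g",
                    role = c(rep("foreground", 20), rep("background", 11)))
  lt <- label_branches(tr, grp, "terminal")
  # force exact class counts (20 fg / 40 bg) by overriding labels; a
  # rooted binary 31-leaf tree has exactly 60 edges
  expect_equal(nrow(tr$edge), 60)
  lt$branch_class <- c(rep("foreground", 20), rep("background", 40))
  dom <- data.frame(name = "D1", class = "membrane", start = 1, end = 10)
  dom <- selsig:::validate_domain_map(dom)
  ev <- fake_events(9, 2, rep(3, 9), rep(4, 2))
  res <- domain_contrast(ev, lt, dom, "nonsynonymous")
  expect_equal(res$a, 9)
  expect_equal(res$b, 191)
  expect_equal(res$c, 2)
  expect_equal(res$d, 398)
  expect_equal(res$freq_fg, 0.045)
  expect_equal(res$freq_bg, 0.005)
  expect_equal(res$p_raw, fisher_exact(c(9, 191, 2, 398)))
})

test_that("domain contrasts use the joint Holm family and conserve events", {
  scen <- study_like_scenario(21)
  sim <- simulate_codon_alignment(scen)
  lt <- scen$ltree
  st <- fitch_states(sim$aln, lt, mito_code)
  ev <- map_events(st, lt, mito_code)
  dom <- cytb_style_domains()
  ns <- domain_contrast(ev, lt, dom, "nonsynonymous")
  s <- domain_contrast(ev, lt, dom, "synonymous")
  expect_equal(nrow(ns), 17)
  # family of 34: single smallest raw p adjusts by factor 34
  all_p <- c(ns$p_raw, s$p_raw)
  i_min <- which.min(all_p)
  expect_equal(c(ns$p_holm, s$p_holm)[i_min],
               min(1, 34 * all_p[i_min]))
  # domains tile 1..381, so per-class foreground events are conserved
  fg_ns <- sum(ev$n_nonsyn > 0 & ev$branch_class == "foreground")
  expect_equal(sum(ns$a), fg_ns)
  # no events -> all p_raw = 1
  empty <- ev[0, , drop = FALSE]
  res0 <- domain_contrast(empty, lt, dom, "synonymous")
  expect_true(all(res0$p_raw == 1))
})

test_that("site contrasts flag spiked sites and refuse degenerate classes", {
  scen <- study_like_scenario(23, n_sites = 50)
  sim <- simulate_codon_alignment(scen)
  lt <- scen$ltree
  st <- fitch_states(sim$aln, lt, mito_code)
  ev <- map_events(st, lt, mito_code)
  # spike: 5 fg nonsynonymous events at one site, none elsewhere
  spike <- data.frame(branch = which(lt$branch_class == "foreground")[1:5],
                      parent_node = 1L, child_node = 2L,
                      branch_class = "foreground", site = 17L,
                      from_codon = "ATT", to_codon = "GTT",
                      n_syn = 0, n_nonsyn = 1, from_aa = "I", to_aa = "V",
                      stringsAsFactors = FALSE)
  ev_ns <- ev[ev$n_nonsyn > 0, , drop = FALSE]
  res <- site_contrast(rbind(ev_ns[ev_ns$site != 17, ], spike), lt, 50,
                       "nonsynonymous")
  expect_equal(which.min(res$p_raw), 17)

  lt_nofg <- lt
  lt_nofg$branch_class[lt_nofg$branch_class == "foreground"] <- "background"
  expect_error(site_contrast(ev, lt_nofg, 50), "foreground")
})

test_that("null site contrasts are calibrated at or below the nominal level", {
  # occupy each (branch, site) slot independently with the same rate in
  # both classes; the exact test is valid (conservative), so the
  # fraction of sites reaching p_raw < 0.05 must stay at or below 5%
  # while remaining clearly positive for a dense event field
  set.seed(101)
  tr <- ape::rtree(31)
  grp <- data.frame(taxon = tr$tip.label, group = "g",
                    role = c(rep("foreground", 20), rep("background", 11)))
  lt <- label_branches(tr, grp, "terminal")
  lt$branch_class <- c(rep("foreground", 20), rep("background", 40))
  n_sites <- 100
  frac <- replicate(200, {
    slots <- expand.grid(branch = seq_len(60), site = seq_len(n_sites))
    keep <- runif(nrow(slots)) < 1 / 3
    ev <- data.frame(branch = slots$branch[keep],
                     parent_node = 1L, child_node = 2L,
                     branch_class = lt$branch_class[slots$branch[keep]],
                     site = slots$site[keep],
                     from_codon = "ATT", to_codon = "GTT",
                     n_syn = 0, n_nonsyn = 1, from_aa = "I", to_aa = "V",
                     stringsAsFactors = FALSE)
    res <- site_contrast(ev, lt, n_sites, "nonsynonymous")
    mean(res$p_raw < 0.05)
  })
  expect_lte(mean(frac), 0.05 + 0.005)
  expect_gt(mean(frac), 0.005)
})

test_that("amino-acid usage patterns find fixed differences only", {
  # site 1: fg all P vs bg all S -> p = 1/C(110,10); site 2 identical
  fg <- cbind(rep("P", 10), rep("A", 10))
  bg <- cbind(rep("S", 100), rep("A", 100))
  res <- aa_site_patterns(fg, bg)
  p1 <- res$p_raw[res$site == 1 & res$aa == "P"]
  expect_equal(p1, 1 / choose(110, 10))
  expect_true(all(res$p_raw[res$site == 2] == 1))

  # three spiked pattern sites among many are exactly the survivors
  set.seed(5)
  L <- 120
  fg <- matrix(sample(c("A", "G"), 30 * L, TRUE), 30, L)
  bg <- matrix(sample(c("A", "G"), 300 * L, TRUE), 300, L)
  for (s in c(10, 60, 110)) {
    fg[, s] <- "P"
    bg[, s] <- "S"
  }
  res <- aa_site_patterns(fg, bg)
  expect_equal(significant_pattern_sites(res), c(10, 60, 110))
  expect_error(aa_site_patterns(fg, bg[, 1:10]), "mismatch")
})
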