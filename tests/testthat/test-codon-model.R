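test_that("rate matrices have GY94 structure, zero rows and detailed balance", {
  struct <- selsig:::codon_model_structure(mito_code)
  pi <- uniform_frequencies(mito_code)
  params <- list(kappa = 2.5,
                 omega_by_class = c(foreground = 0.5, background = 0.05),
                 codon_freqs = pi)
  rates <- build_rate_matrix(params, mito_code, struct)
  for (Q in rates$Q) {
    expect_equal(dim(Q), c(60, 60))
    expect_true(all(abs(rowSums(Q)) < 1e-12))
  }
  # background matrix is scaled to one expected substitution per unit time
  expect_equal(-sum(pi * diag(rates$Q$background)), 1)

  # detailed balance pi_i q_ij = pi_j q_ji on random frequencies
  set.seed(4)
  pi2 <- rgamma(60, 2)
  pi2 <- stats::setNames(pi2 / sum(pi2), sense_codons(mito_code))
  params2 <- list(kappa = 7, omega_by_class = c(background = 0.3),
                  codon_freqs = pi2)
  Q <- build_rate_matrix(params2, mito_code, struct)$Q$background
  flux <- pi2 * Q
  expect_equal(flux, t(flux), tolerance = 1e-12)

  # omega = 0 kills every nonsynonymous rate
  params0 <- list(kappa = 2, omega_by_class = c(background = 0),
                  codon_freqs = pi)
  Q0 <- build_rate_matrix(params0, mito_code, struct)$Q$background
  ij <- struct$pairs[struct$ns, , drop = FALSE]
  expect_true(all(Q0[ij] == 0))
  expect_true(all(Q0[ij[, 2:1]] == 0))
})

test_that("F3x4 frequencies are positive, normalized and match counts", {
  aln <- quartet_alignment("ATTGGACTA", "ATCGGTCTA", "ATTGGCCTC", "ATAGGACTT")
  pi <- f3x4_frequencies(aln, mito_code)
  expect_equal(sum(pi), 1)
  expect_true(all(pi > 0))
  # first codon position is A in 3/4 of codons x taxa... verify one entry
  chars <- do.call(rbind, strsplit(as.vector(aln$codons), ""))
  f1 <- mean(chars[, 1] == "A")
  f2 <- mean(chars[, 2] == "T")
  f3 <- mean(chars[, 3] == "G")
  raw <- f1 * f2 * f3
  sense <- sense_codons(mito_code)
  sc <- do.call(rbind, strsplit(sense, ""))
  nt <- c("A", "C", "G", "T")
  fpos <- sapply(1:3, function(p) {
    sapply(nt, function(b) mean(chars[, p] == b))
  })
  norm <- sum(pmax(fpos[match(sc[, 1], nt), 1] * fpos[match(sc[, 2], nt), 2] *
                     fpos[match(sc[, 3], nt), 3], 1e-8))
  expect_equal(unname(pi["ATG"]), raw / norm)
})

test_that("pruning equals brute-force enumeration on small trees", {
  struct <- selsig:::codon_model_structure(mito_code)
  sense <- sense_codons(mito_code)
  pi <- uniform_frequencies(mito_code)
  params <- list(kappa = 3, omega_by_class = c(background = 0.2),
                 codon_freqs = pi, scale = 1)
  tr <- ape::read.tree(text = "((A:0.1,B:0.25):0.05,(C:0.3,D:0.15):0.2);")
  lt <- label_branches(tr, quartet_groups(character(0)), "terminal") |>
    suppressWarnings()
  aln <- quartet_alignment("ATTCTAGGA", "GTTCTAGGC", "ATCTTAGGA", "ATTCTGGGT")
  lnl <- log_likelihood(aln, lt, params, mito_code, struct)
  # brute force: sum over all internal-state assignments per site
  Qs <- build_rate_matrix(params, mito_code, struct)$Q$background
  P <- lapply(seq_len(nrow(tr$edge)),
              function(e) selsig:::transition_matrix(Qs, pi,
                                                     tr$edge.length[e]))
  # explicit joint-probability sum for the quartet topology
  # ((A,B)u,(C,D)v)r: sum_r pi_r [sum_u P(r,u)P(u,a)P(u,b)]
  #                          x [sum_v P(r,v)P(v,c)P(v,d)]
  e_to <- function(child) which(tr$edge[, 2] == child)
  u_node <- tr$edge[e_to(1), 1]     # parent of A
  v_node <- tr$edge[e_to(3), 1]     # parent of C
  brute_site <- function(codons) {
    idx <- match(codons, sense)
    left <- P[[e_to(u_node)]] %*%
      (P[[e_to(1)]][, idx[1]] * P[[e_to(2)]][, idx[2]])
    right <- P[[e_to(v_node)]] %*%
      (P[[e_to(3)]][, idx[3]] * P[[e_to(4)]][, idx[4]])
    log(sum(pi * left * right))
  }
  brute <- sum(sapply(seq_len(aln$sites),
                      function(s) brute_site(aln$codons[, s])))
  expect_equal(lnl, brute, tolerance = 1e-8)

  # and a genuinely exhaustive enumeration on a 3-leaf tree, 1 site
  tr3 <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,C:0.3);")
  grp3 <- data.frame(taxon = c("A", "B", "C"), group = "g",
                     role = "background")
  lt3 <- suppressWarnings(label_branches(tr3, grp3, "terminal"))
  aln3 <- codon_alignment_from_strings(c(A = "ATT", B = "GTT", C = "ATC"),
                                       mito_code)
  l3 <- log_likelihood(aln3, lt3, params, mito_code, struct)
  P3 <- lapply(seq_len(nrow(tr3$edge)),
               function(e) selsig:::transition_matrix(Qs, pi,
                                                      tr3$edge.length[e]))
  idx3 <- match(aln3$codons[tr3$tip.label, 1], sense)
  tot <- 0
  for (r in seq_along(sense)) {
    for (w in seq_along(sense)) {
      assign_all <- c(idx3, r, w)
      pr <- unname(pi[r])
      for (e in seq_len(nrow(tr3$edge))) {
        pr <- pr * P3[[e]][assign_all[tr3$edge[e, 1]],
                           assign_all[tr3$edge[e, 2]]]
      }
      tot <- tot + pr
    }
  }
  expect_equal(l3, log(tot), tolerance = 1e-8)
})

test_that("two-taxon likelihood matches the matrix-exponential closed form", {
  struct <- selsig:::codon_model_structure(mito_code)
  pi <- uniform_frequencies(mito_code)
  sense <- sense_codons(mito_code)
  params <- list(kappa = 5, omega_by_class = c(background = 0.08),
                 codon_freqs = pi, scale = 1)
  tr <- ape::read.tree(text = "(A:0.17,B:0.33);")
  grp <- data.frame(taxon = c("A", "B"), group = "g", role = "background")
  lt <- suppressWarnings(label_branches(tr, grp, "terminal"))
  aln <- codon_alignment_from_strings(c(A = "ATGCTATTC", B = "ATATTATTC"),
                                      mito_code)
  lnl <- log_likelihood(aln, lt, params, mito_code, struct)
  Q <- build_rate_matrix(params, mito_code, struct)$Q$background
  P <- as.matrix(Matrix::expm(Q * 0.5))   # total path length
  closed <- sum(sapply(seq_len(aln$sites), function(s) {
    i <- match(aln$codons["A", s], sense)
    j <- match(aln$codons["B", s], sense)
    log(pi[i] * P[i, j])
  }))
  expect_equal(lnl, closed, tolerance = 1e-8)

  # zero-length star: likelihood of identical sequences is log pi
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  lt0 <- suppressWarnings(label_branches(tr0, grp, "terminal"))
  aln0 <- codon_alignment_from_strings(c(A = "ATG", B = "ATG"), mito_code)
  expect_equal(log_likelihood(aln0, lt0, params, mito_code, struct),
               log(unname(pi["ATG"])), tolerance = 1e-10)
})

test_that("likelihood is invariant to leaf order and missing data sums out", {
  struct <- selsig:::codon_model_structure(mito_code)
  scen <- study_like_scenario(13, n_sites = 40)
  sim <- simulate_codon_alignment(scen)
  pi <- f3x4_frequencies(sim$aln, mito_code)
  params <- list(kappa = 4,
                 omega_by_class = c(foreground = 0.1, background = 0.03),
                 codon_freqs = pi, scale = 1)
  l1 <- log_likelihood(sim$aln, scen$ltree, params, mito_code, struct)
  perm <- rev(seq_len(nrow(sim$aln$codons)))
  aln2 <- sim$aln
  aln2$codons <- aln2$codons[perm, , drop = FALSE]
  aln2$taxa <- aln2$taxa[perm]
  expect_equal(log_likelihood(aln2, scen$ltree, params, mito_code, struct),
               l1)
  # masking a whole taxon's site never increases information: lnL changes
  # but stays finite, and a fully missing column contributes nothing
  aln3 <- sim$aln
  aln3$codons[, 1] <- NA_character_
  l3 <- log_likelihood(aln3, scen$ltree, params, mito_code, struct)
  aln4 <- sim$aln
  aln4$codons <- aln4$codons[, -1, drop = FALSE]
  aln4$sites <- aln4$sites - 1L
  l4 <- log_likelihood(aln4, scen$ltree, params, mito_code, struct)
  expect_equal(l3, l4, tolerance = 1e-10)
})

test_that("likelihood is invariant to rerooting under the reversible model", {
  struct <- selsig:::codon_model_structure(mito_code)
  pi <- uniform_frequencies(mito_code)
  params <- list(kappa = 2, omega_by_class = c(background = 0.15),
                 codon_freqs = pi, scale = 1)
  grp <- data.frame(taxon = c("A", "B", "C", "D"), group = "g",
                    role = "background")
  # same unrooted tree, rooted on the internal edge vs on A's pendant edge
  t1 <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:4):0.5);")
  t2 <- ape::read.tree(text = "(A:0.25,(B:2,(C:3,D:4):1):0.75);")
  aln <- quartet_alignment("ATTCTA", "GTTCTG", "ATCTTA", "CTTCTA")
  l1 <- log_likelihood(aln, suppressWarnings(label_branches(t1, grp)),
                       params, mito_code, struct)
  l2 <- log_likelihood(aln, suppressWarnings(label_branches(t2, grp)),
                       params, mito_code, struct)
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("LRT arithmetic follows the chi-squared reference", {
  f_alt <- structure(list(lnL = -100, n_free_params = 4), class = "model_fit")
  f_null <- structure(list(lnL = -100 - 3.841459 / 2, n_free_params = 3),
                      class = "model_fit")
  res <- lrt(f_alt, f_null)
  expect_equal(res$statistic, 3.841459, tolerance = 1e-6)
  expect_equal(res$df, 1)
  expect_equal(res$p, 0.05, tolerance = 1e-6)
  # identical fits: statistic clamped at zero, p = 1
  res0 <- lrt(f_alt, f_alt, df = 1)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  res2 <- lrt(structure(list(lnL = -100 + 10.83 / 2, n_free_params = 4),
                        class = "model_fit"), f_alt, df = 1)
  expect_equal(res2$p, 0.001, tolerance = 1e-2)
  expect_error(lrt(f_alt, f_null, df = 0), "df")
})

test_that("fits recover simulated parameters and flag degenerate data", {
  scen <- study_like_scenario(3, omega_fg = 0.1325, omega_bg = 0.0269)
  sim <- simulate_codon_alignment(scen)
  bf <- fit_model(sim$aln, scen$ltree, "b_free", mito_code)
  expect_equal(bf$omega_fg, 0.1325, tolerance = 0.30)
  expect_equal(bf$omega_bg, 0.0269, tolerance = 0.30)
  expect_equal(bf$kappa, 4, tolerance = 0.4)
  expect_equal(bf$scale, 1, tolerance = 0.15)
  m0 <- fit_model(sim$aln, scen$ltree, "M0", mito_code)
  bn <- fit_model(sim$aln, scen$ltree, "b_neut", mito_code)
  expect_equal(bn$omega_fg, 1)
  # both nulls are nested in b_free
  expect_gte(bf$lnL, m0$lnL - 1e-6)
  expect_gte(bf$lnL, bn$lnL - 1e-6)
  # strong purifying selection data reject neutrality of the foreground
  expect_lt(lrt(bf, bn, 1)$p, 1e-6)

  # identical sequences carry no information: the fit comes back flagged
  aln_flat <- codon_alignment_from_strings(
    stats::setNames(rep(paste(rep("ATT", 30), collapse = ""), 4),
                    c("A", "B", "C", "D")), mito_code)
  lt <- label_branches(quartet_tree(0.1), quartet_groups("A"), "terminal")
  flat <- fit_model(aln_flat, lt, "M0", mito_code)
  expect_true(flat$status %in% c("boundary", "no_convergence"))
})
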