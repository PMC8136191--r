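#' Exact-test contrasts of substitution density and amino-acid usage
#'
#' Foreground/background contrasts are built as 2x2 count tables
#' (events vs remaining opportunity, or sequences carrying an amino acid
#' vs not), tested with the two-sided Fisher exact test and corrected
#' across the whole family of tests with the Holm step-down procedure.
#'
#' @name contrast_stats
NULL

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (relative tolerance 1e-12 on the
#' comparison, so exact probability ties are included despite floating
#' point).
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major `a,b,c,d`) of
#'   nonnegative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be nonnegative integers")
  }
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[1, 2]   # row 1 total
  n <- tab[2, 1] + tab[2, 2]   # row 2 total
  k <- tab[1, 1] + tab[2, 1]   # column 1 total
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-12)]))
}

#' Holm step-down adjustment with an explicit family size
#'
#' Standard Holm correction, generalised so that a subset of p-values
#' known to be the smallest members of a larger family can be adjusted
#' against the full family size (as when only the significant rows of a
#' larger scan are available).  With `family_size = length(p_values)`
#' this is identical to `p.adjust(p, "holm")`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param family_size Total number of tests in the family
#'   (>= `length(p_values)`).
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (family_size < length(p_values)) {
    stop("family_size smaller than the number of p-values")
  }
  stats::p.adjust(p_values, method = "holm", n = family_size)
}

count_class_events <- function(events, subclass) {
  stopifnot(subclass %in% c("nonsynonymous", "synonymous"))
  if (subclass == "nonsynonymous") events$n_nonsyn > 0 else events$n_syn > 0
}

contrast_classes <- function(ltree) {
  n_fg <- sum(ltree$branch_class == "foreground")
  n_bg <- sum(ltree$branch_class == "background")
  if (n_fg == 0L) stop("no foreground branches: contrast refused")
  if (n_bg == 0L) stop("no background branches: contrast refused")
  list(n_fg = n_fg, n_bg = n_bg)
}

#' Contrast substitution density per protein domain
#'
#' For each domain the 2x2 table is (events of the requested class inside
#' the domain) versus (remaining opportunity), for foreground versus
#' background branches, where opportunity is domain width (codon sites)
#' times the number of branches of that class.  Holm correction is
#' applied across the full family: all domains times both substitution
#' classes (34 tests for the 17-region cytochrome-b map).  Events on
#' excluded (outgroup) branches are ignored.
#'
#' @param events Event table from [map_events()].
#' @param ltree The `labeled_tree`.
#' @param domains A `domain_map`.
#' @param subclass `"nonsynonymous"` or `"synonymous"`; results for the
#'   requested class are returned but the Holm family always spans both.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return `data.frame` with columns `unit`, `class`, `a`, `b`, `c`, `d`,
#'   `freq_fg`, `freq_bg`, `p_raw`, `p_holm`, `significant`.
#' @export
domain_contrast <- function(events, ltree, domains,
                            subclass = c("nonsynonymous", "synonymous"),
                            alpha = 0.05) {
  subclass <- match.arg(subclass)
  cl <- contrast_classes(ltree)
  widths <- domain_widths(domains)
  if (any(widths == 0L)) stop("empty domain")
  both <- lapply(c("nonsynonymous", "synonymous"), function(sc) {
    keep <- count_class_events(events, sc)
    ev <- events[keep & events$branch_class != "excluded", , drop = FALSE]
    res <- lapply(seq_len(nrow(domains)), function(i) {
      in_dom <- ev$site >= domains$start[i] & ev$site <= domains$end[i]
      a <- sum(in_dom & ev$branch_class == "foreground")
      c_ <- sum(in_dom & ev$branch_class == "background")
      opp_fg <- widths[i] * cl$n_fg
      opp_bg <- widths[i] * cl$n_bg
      data.frame(unit = domains$name[i], class = sc,
                 a = a, b = opp_fg - a, c = c_, d = opp_bg - c_,
                 freq_fg = a / opp_fg, freq_bg = c_ / opp_bg,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  fam <- do.call(rbind, both)
  fam$p_raw <- vapply(seq_len(nrow(fam)), function(i) {
    fisher_exact(c(fam$a[i], fam$b[i], fam$c[i], fam$d[i]))
  }, numeric(1))
  fam$p_holm <- holm_adjust(fam$p_raw)
  fam$significant <- fam$p_holm < alpha
  out <- fam[fam$class == subclass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast substitution density per codon site
#'
#' As [domain_contrast()] with single-site units; the Holm family is all
#' sites of the protein for the requested substitution class.
#'
#' @inheritParams domain_contrast
#' @param n_sites Protein length in codons (defines the site family).
#' @return `data.frame` as in [domain_contrast()], one row per site.
#' @export
site_contrast <- function(events, ltree, n_sites,
                          subclass = c("nonsynonymous", "synonymous"),
                          alpha = 0.05) {
  subclass <- match.arg(subclass)
  cl <- contrast_classes(ltree)
  keep <- count_class_events(events, subclass)
  ev <- events[keep & events$branch_class != "excluded", , drop = FALSE]
  a <- tabulate(ev$site[ev$branch_class == "foreground"], n_sites)
  c_ <- tabulate(ev$site[ev$branch_class == "background"], n_sites)
  res <- data.frame(unit = seq_len(n_sites), class = subclass,
                    a = a, b = cl$n_fg - a, c = c_, d = cl$n_bg - c_,
                    freq_fg = a / cl$n_fg, freq_bg = c_ / cl$n_bg,
                    stringsAsFactors = FALSE)
  res$p_raw <- vapply(seq_len(n_sites), function(i) {
    fisher_exact(c(res$a[i], res$b[i], res$c[i], res$d[i]))
  }, numeric(1))
  res$p_holm <- holm_adjust(res$p_raw)
  res$significant <- res$p_holm < alpha
  res
}

#' Per-site amino-acid usage contrasts
#'
#' For every site and every amino acid observed there, tests whether the
#' fraction of sequences carrying that amino acid differs between the
#' foreground and background sequence sets (sequences, not species, are
#' the sampling unit, so intraspecific variation counts).  Holm
#' correction spans all (site, amino acid) tests; a site is significant
#' if any of its per-amino-acid tests survives.
#'
#' @param fg_seqs,bg_seqs Character matrices (sequences x sites) of
#'   one-letter amino acids; unequal numbers of rows are expected.
#'   `NA`/`X`/`-` cells are ignored.
#' @param alpha Significance level on adjusted p-values.
#' @return `data.frame` with columns `site`, `aa`, `a`, `b`, `c`, `d`,
#'   `p_raw`, `p_holm`, `significant`.
#' @export
aa_site_patterns <- function(fg_seqs, bg_seqs, alpha = 0.05) {
  if (ncol(fg_seqs) != ncol(bg_seqs)) {
    stop("alignment length mismatch between groups")
  }
  rows <- vector("list", ncol(fg_seqs))
  for (s in seq_len(ncol(fg_seqs))) {
    fg <- fg_seqs[, s]
    bg <- bg_seqs[, s]
    fg <- fg[!is.na(fg) & !fg %in% c("X", "-", "*")]
    bg <- bg[!is.na(bg) & !bg %in% c("X", "-", "*")]
    aas <- sort(unique(c(fg, bg)))
    if (length(aas) < 2L && length(aas) > 0L) {
      # monomorphic site: a single degenerate test keeps families comparable
      rows[[s]] <- data.frame(site = s, aa = aas, a = sum(fg == aas),
                              b = 0L, c = sum(bg == aas), d = 0L,
                              stringsAsFactors = FALSE)
      next
    }
    if (length(aas) == 0L) next
    rows[[s]] <- do.call(rbind, lapply(aas, function(aa) {
      data.frame(site = s, aa = aa,
                 a = sum(fg == aa), b = sum(fg != aa),
                 c = sum(bg == aa), d = sum(bg != aa),
                 stringsAsFactors = FALSE)
    }))
  }
  res <- do.call(rbind, rows)
  res$p_raw <- vapply(seq_len(nrow(res)), function(i) {
    fisher_exact(c(res$a[i], res$b[i], res$c[i], res$d[i]))
  }, numeric(1))
  res$p_holm <- holm_adjust(res$p_raw)
  res$significant <- res$p_holm < alpha
  rownames(res) <- NULL
  res
}

#' Sites with significantly different amino-acid usage
#'
#' @param patterns Result of [aa_site_patterns()].
#' @return Sorted integer vector of significant sites.
#' @export
significant_pattern_sites <- function(patterns) {
  sort(unique(patterns$site[patterns$significant]))
}

#' Write a contrast report
#'
#' @param contrast A contrast `data.frame`.
#' @param path Output TSV.
#' @export
write_contrast <- function(contrast, path) {
  utils::write.table(contrast, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
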