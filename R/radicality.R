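#' Physicochemical radicality of amino-acid replacements
#'
#' Replacements are scored against a table of amino-acid property scales
#' (31 published indices by default, shipped in
#' `inst/extdata/aa_properties_31.tsv`).  For each property the absolute
#' property change of every replacement reachable by a single nucleotide
#' change under the genetic code is binned into 8 equal-width magnitude
#' categories; categories 6-8 are the radical ones.  Sliding-window
#' z-scores compare the observed category counts among mapped
#' nonsynonymous events with the neutral expectation derived from a
#' uniform distribution over all single-step nonsynonymous codon changes.
#'
#' @name radicality
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read an amino-acid property table
#'
#' @param path TSV with a `property` column and one column per amino
#'   acid (one-letter codes); `NULL` loads the packaged 31-property set
#'   drawn from the AAindex collection.
#' @return `data.frame` (class `property_table`), one row per property.
#' @export
read_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties_31.tsv", package = "selsig")
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"property" %in% names(df)) stop("property table needs a 'property' column")
  missing <- setdiff(AA1, names(df))
  if (length(missing)) {
    stop("property table missing amino acid column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$property)) stop("duplicate property name")
  class(df) <- c("property_table", "data.frame")
  df
}

single_step_aa_changes <- function(code) {
  # ordered pairs (from_aa, to_aa) over all single-nucleotide
  # nonsynonymous sense-codon changes, with multiplicity
  sense <- sense_codons(code)
  nt <- c("A", "C", "G", "T")
  from <- character(0)
  to <- character(0)
  for (cod in sense) {
    chars <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(nt, chars[pos])) {
        alt <- chars
        alt[pos] <- b
        alt_cod <- paste0(alt, collapse = "")
        if (code[[alt_cod]] == "*") next
        if (code[[alt_cod]] == code[[cod]]) next
        from <- c(from, code[[cod]])
        to <- c(to, code[[alt_cod]])
      }
    }
  }
  data.frame(from_aa = from, to_aa = to, stringsAsFactors = FALSE)
}

#' Bin replacement magnitudes into 8 radicality categories
#'
#' For each property, the bin width is one eighth of the maximal absolute
#' property difference over amino-acid pairs reachable by a single
#' nucleotide change under `code`; a difference exactly on a bin boundary
#' is assigned to the higher category.  Categories are also assigned to
#' pairs not reachable in a single step (multi-step replacements) with
#' the same bin width, capped at 8.
#'
#' @param props A `property_table`.
#' @param code A `genetic_code`.
#' @return `category_map`: list with `categories` (per property a 20x20
#'   integer matrix over amino acids), `neutral` (per property the
#'   expected category distribution `p_c`, an 8-vector), `width` per
#'   property.
#' @export
categorize_changes <- function(props, code = load_genetic_code()) {
  steps <- single_step_aa_changes(code)
  cats <- list()
  neutral <- list()
  widths <- numeric(0)
  for (i in seq_len(nrow(props))) {
    vals <- as.numeric(props[i, AA1])
    names(vals) <- AA1
    delta <- abs(outer(vals, vals, "-"))
    adj_delta <- delta[cbind(steps$from_aa, steps$to_aa)]
    dmax <- max(adj_delta)
    if (dmax == 0) {
      stop("constant property: ", props$property[i])
    }
    w <- dmax / 8
    cat_mat <- pmin(8L, as.integer(floor(delta / w + 1e-9)) + 1L)
    cat_mat[delta == 0] <- 1L
    dim(cat_mat) <- dim(delta)
    dimnames(cat_mat) <- dimnames(delta)
    step_cat <- cat_mat[cbind(steps$from_aa, steps$to_aa)]
    p_c <- tabulate(step_cat, 8) / length(step_cat)
    cats[[props$property[i]]] <- cat_mat
    neutral[[props$property[i]]] <- p_c
    widths[props$property[i]] <- w
  }
  structure(list(categories = cats, neutral = neutral, width = widths),
            class = "category_map")
}

#' Sliding-window z-scores for radicality categories
#'
#' For every property, category and window of `window` codons (step 1),
#' compares the observed number of nonsynonymous events in that category
#' against the binomial expectation `N * p_c` under the neutral category
#' distribution, with `z = (n_c - N p_c) / sqrt(N p_c (1 - p_c))` and a
#' one-tailed upper normal p-value.  Windows containing no nonsynonymous
#' event yield no record.
#'
#' @param events Event table from [map_events()].
#' @param cat_map A `category_map`.
#' @param window Window length in codons (default 20).
#' @param protein_length Protein length in codons.
#' @param categories Categories to report (default all 8).
#' @return `data.frame`: `property`, `category`, `start`, `length`,
#'   `observed`, `expected`, `z`, `p`.
#' @export
window_z_scores <- function(events, cat_map, window = 20L, protein_length,
                            categories = 1:8) {
  if (window > protein_length) stop("window longer than the protein")
  ev <- events[events$n_nonsyn > 0 & events$from_aa != events$to_aa, ,
               drop = FALSE]
  if (nrow(ev) == 0L) stop("no nonsynonymous events to scan")
  starts <- seq_len(protein_length - window + 1L)
  out <- vector("list", length(cat_map$categories))
  for (k in seq_along(cat_map$categories)) {
    prop <- names(cat_map$categories)[k]
    cat_of_ev <- cat_map$categories[[prop]][cbind(ev$from_aa, ev$to_aa)]
    # per-site counts per category, then windowed sums via cumsum
    site_tot <- tabulate(ev$site, protein_length)
    cum_tot <- c(0, cumsum(site_tot))
    N_w <- cum_tot[starts + window] - cum_tot[starts]
    keep_w <- N_w > 0
    if (!any(keep_w)) next
    rows <- vector("list", length(categories))
    for (ci in seq_along(categories)) {
      cc <- categories[ci]
      site_c <- tabulate(ev$site[cat_of_ev == cc], protein_length)
      cum_c <- c(0, cumsum(site_c))
      n_c <- cum_c[starts + window] - cum_c[starts]
      p_c <- cat_map$neutral[[prop]][cc]
      N <- N_w[keep_w]
      nc <- n_c[keep_w]
      expd <- N * p_c
      z <- ifelse(p_c > 0 & p_c < 1,
                  (nc - expd) / sqrt(N * p_c * (1 - p_c)), NA_real_)
      rows[[ci]] <- data.frame(
        property = prop, category = cc, start = starts[keep_w],
        length = window, observed = nc, expected = expd, z = z,
        p = stats::pnorm(z, lower.tail = FALSE), stringsAsFactors = FALSE)
    }
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag radical nonsynonymous events
#'
#' An event is radical when, for at least one property, its replacement
#' falls in category `category_min` or above and it lies inside at least
#' one window where that (property, category) has a significantly
#' positive z-score.
#'
#' @param events Event table from [map_events()].
#' @param zscores Result of [window_z_scores()].
#' @param cat_map The `category_map` used for the z-scores.
#' @param category_min Minimal radical category (default 6).
#' @param alpha One-tailed significance threshold (default 0.001).
#' @return Logical vector along the rows of `events`.
#' @export
radical_events <- function(events, zscores, cat_map, category_min = 6L,
                           alpha = 0.001) {
  sig <- zscores[!is.na(zscores$z) & zscores$z > 0 & zscores$p < alpha &
                   zscores$category >= category_min, , drop = FALSE]
  flag <- rep(FALSE, nrow(events))
  if (nrow(sig) == 0L || nrow(events) == 0L) return(flag)
  is_ns <- events$n_nonsyn > 0 & events$from_aa != events$to_aa
  keys <- paste(sig$property, sig$category)
  for (key in unique(keys)) {
    rows <- sig[keys == key, , drop = FALSE]
    prop <- rows$property[1]
    cc <- rows$category[1]
    covered <- rep(FALSE, max(events$site, rows$start + rows$length))
    for (r in seq_len(nrow(rows))) {
      covered[rows$start[r]:(rows$start[r] + rows$length[r] - 1L)] <- TRUE
    }
    ev_cat <- rep(NA_integer_, nrow(events))
    ev_cat[is_ns] <- cat_map$categories[[prop]][
      cbind(events$from_aa[is_ns], events$to_aa[is_ns])]
    flag <- flag | (is_ns & !is.na(ev_cat) & ev_cat == cc &
                      covered[events$site])
  }
  flag
}
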