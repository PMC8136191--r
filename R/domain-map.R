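#' Protein domain maps
#'
#' A domain map partitions (possibly partially) the protein into named
#' regions in 1-based inclusive amino-acid coordinates, each classed as
#' `membrane` or `transmembrane` -- the topology annotation style of
#' UniProt records for cytochrome b (regions Memb1..Memb9, TM1..TM8).
#'
#' @param path TSV with columns `name`, `class`, `start`, `end`.
#' @param protein_length Optional protein length for range validation.
#' @return A `data.frame` (class `domain_map`) with those columns,
#'   ordered by `start`.
#' @export
read_domain_map <- function(path, protein_length = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_domain_map(df, protein_length)
}

validate_domain_map <- function(df, protein_length = NULL) {
  need <- c("name", "class", "start", "end")
  if (!all(need %in% names(df))) {
    stop("domain map needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- setdiff(unique(df$class), c("membrane", "transmembrane"))
  if (length(bad)) stop("unknown region class(es): ", paste(bad, collapse = ", "))
  if (any(df$start < 1L) || any(df$end < df$start)) {
    stop("domain coordinates must satisfy 1 <= start <= end")
  }
  if (!is.null(protein_length) && any(df$end > protein_length)) {
    stop("domain end beyond protein length ", protein_length)
  }
  if (anyDuplicated(df$name)) stop("duplicate domain name")
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1] <= df$end[-nrow(df)])) {
    stop("overlapping domains in map")
  }
  rownames(df) <- NULL
  class(df) <- c("domain_map", "data.frame")
  df
}

#' Write a domain map
#'
#' @param domains A `domain_map`.
#' @param path Output TSV.
#' @export
write_domain_map <- function(domains, path) {
  utils::write.table(as.data.frame(domains), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Widths of domain regions (codon sites spanned)
#'
#' @param domains A `domain_map`.
#' @return Named integer vector of region widths.
#' @export
domain_widths <- function(domains) {
  stats::setNames(domains$end - domains$start + 1L, domains$name)
}
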