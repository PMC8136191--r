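#' Genetic code tables
#'
#' A `genetic_code` is a named character vector mapping all 64 codons
#' (upper-case DNA, e.g. `"ATG"`) to one-letter amino acids, with `"*"`
#' for stop codons.  The default throughout the package is the vertebrate
#' mitochondrial code (NCBI translation table 2): 60 sense codons, stops
#' TAA/TAG/AGA/AGG, ATA = Met and TGA = Trp.
#'
#' @param name_or_table Either the name of a built-in code
#'   (`"vertebrate_mitochondrial"` or `"standard"`) or the path to a
#'   two-column TSV (`codon`, `aa`) covering all 64 codons.
#' @return An object of class `genetic_code`: a named character vector of
#'   length 64 with a `name` attribute.
#' @examples
#' code <- load_genetic_code("vertebrate_mitochondrial")
#' sum(code != "*")  # 60 sense codons
#' @export
load_genetic_code <- function(name_or_table = "vertebrate_mitochondrial") {
  stopifnot(is.character(name_or_table), length(name_or_table) == 1L)
  builtin <- c(vertebrate_mitochondrial = "2", standard = "1")
  if (name_or_table %in% names(builtin)) {
    tab <- Biostrings::getGeneticCode(builtin[[name_or_table]])
    code <- as.character(tab)
    names(code) <- names(tab)
    name <- name_or_table
  } else {
    if (!file.exists(name_or_table)) {
      stop("unknown genetic code name and no such file: ", name_or_table)
    }
    df <- utils::read.delim(name_or_table, stringsAsFactors = FALSE)
    if (!all(c("codon", "aa") %in% names(df))) {
      stop("genetic code table needs columns 'codon' and 'aa'")
    }
    code <- stats::setNames(toupper(df$aa), toupper(df$codon))
    name <- basename(name_or_table)
  }
  validate_genetic_code(code)
  structure(code[sort(names(code))], name = name, class = "genetic_code")
}

all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  as.vector(outer(outer(nt, nt, paste0), nt, paste0))
}

validate_genetic_code <- function(code) {
  codons <- sort(all_codons())
  if (anyDuplicated(names(code))) stop("duplicate codon in genetic code table")
  missing <- setdiff(codons, names(code))
  if (length(missing)) {
    stop("incomplete genetic code table; missing codons: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  extra <- setdiff(names(code), codons)
  if (length(extra)) stop("invalid codons in table: ", paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", attr(x, "name"), "\n")
  cat(" sense codons:", sum(x != "*"),
      " stops:", paste(sense_stops(x), collapse = " "), "\n")
  invisible(x)
}

sense_stops <- function(code) names(code)[code == "*"]

#' Sense codons of a genetic code
#'
#' @param code A `genetic_code`.
#' @return Character vector of codons that translate to an amino acid,
#'   in lexicographic order.
#' @export
sense_codons <- function(code) sort(names(code)[code != "*"])

#' Translate codons
#'
#' @param codons Character vector of codons (may contain `NA`).
#' @param code A `genetic_code`.
#' @return One-letter amino acids (`"*"` for stop, `NA` propagated).
#' @export
translate_codons <- function(codons, code) {
  out <- unname(code[codons])
  out[is.na(codons)] <- NA_character_
  out
}
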