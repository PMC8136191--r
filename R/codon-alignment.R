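#' Codon alignments
#'
#' A `codon_alignment` stores an in-frame protein-coding alignment as a
#' taxa x codon-site character matrix of upper-case codons, with `NA`
#' marking missing data.  Any codon containing a non-ACGT character
#' (gaps, IUPAC ambiguity codes, `N`) is treated as missing: it is
#' excluded from substitution mapping and summed over in likelihood
#' computations.
#'
#' @name codon_alignment
NULL

new_codon_alignment <- function(codons, code) {
  stopifnot(is.matrix(codons), is.character(codons))
  if (is.null(rownames(codons))) stop("codon matrix needs taxon rownames")
  structure(
    list(taxa = rownames(codons), sites = ncol(codons), codons = codons,
         code_name = attr(code, "name")),
    class = "codon_alignment")
}

#' Read an in-frame codon alignment from FASTA
#'
#' Sequences must be aligned (equal length) and in frame (length divisible
#' by 3).  Codons containing any character outside A/C/G/T become missing
#' data.  A stop codon at an internal site is an error in strict mode and
#' masked to missing otherwise; a stop at the final column (a genuine
#' translation terminator carried in the alignment) is always masked.
#'
#' @param path FASTA file.
#' @param code A `genetic_code` (default vertebrate mitochondrial).
#' @param strict If `TRUE` (default), an internal stop codon aborts.
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, code = load_genetic_code(),
                                 strict = TRUE) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(widths), collapse = ", "))
  }
  if (widths[1] %% 3L != 0L) {
    stop("alignment length ", widths[1], " not divisible by 3")
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(rownames(mat))) stop("duplicate taxon names in FASTA")
  codon_matrix_from_chars(mat, code, strict = strict)
}

codon_matrix_from_chars <- function(mat, code, strict = TRUE) {
  n_sites <- ncol(mat) %/% 3L
  codons <- matrix(NA_character_, nrow(mat), n_sites,
                   dimnames = list(rownames(mat), NULL))
  for (s in seq_len(n_sites)) {
    trip <- mat[, (3L * s - 2L):(3L * s), drop = FALSE]
    cod <- paste0(trip[, 1], trip[, 2], trip[, 3])
    cod[!grepl("^[ACGT]{3}$", cod)] <- NA_character_
    codons[, s] <- cod
  }
  aa <- matrix(translate_codons(codons, code), nrow(mat))
  is_stop <- !is.na(aa) & aa == "*"
  if (any(is_stop[, n_sites])) codons[is_stop[, n_sites], n_sites] <- NA_character_
  internal <- is_stop
  internal[, n_sites] <- FALSE
  if (any(internal)) {
    w <- which(internal, arr.ind = TRUE)[1, ]
    if (strict) {
      stop("internal stop codon in taxon '", rownames(mat)[w[1]],
           "' at codon site ", w[2])
    }
    codons[internal] <- NA_character_
  }
  new_codon_alignment(codons, code)
}

#' Build a codon alignment from a named character vector of sequences
#'
#' Convenience constructor used by the simulator and in tests.
#'
#' @param sequences Named character vector of equal-length in-frame
#'   nucleotide strings.
#' @inheritParams read_codon_alignment
#' @return A `codon_alignment`.
#' @export
codon_alignment_from_strings <- function(sequences, code = load_genetic_code(),
                                         strict = TRUE) {
  stopifnot(!is.null(names(sequences)))
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(mat) <- names(sequences)
  if (length(unique(nchar(sequences))) != 1L) stop("ragged alignment")
  if (nchar(sequences[1]) %% 3L != 0L) stop("length not divisible by 3")
  codon_matrix_from_chars(mat, code, strict = strict)
}

#' Write a codon alignment to FASTA
#'
#' Missing codons are written as `NNN`, so write/read round-trips
#' preserve the in-memory representation.
#'
#' @param aln A `codon_alignment`.
#' @param path Output file.
#' @export
write_codon_alignment <- function(aln, path) {
  codons <- aln$codons
  codons[is.na(codons)] <- "NNN"
  seqs <- apply(codons, 1, paste0, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$taxa), "taxa x", x$sites, "codon sites (",
      3 * x$sites, "nt ), code:", x$code_name, "\n")
  invisible(x)
}

#' Translate a codon alignment to amino acids
#'
#' @param aln A `codon_alignment`.
#' @param code A `genetic_code` matching `aln`.
#' @return Character matrix (taxa x sites) of one-letter amino acids.
#' @export
translate_alignment <- function(aln, code = load_genetic_code()) {
  matrix(translate_codons(aln$codons, code), nrow = length(aln$taxa),
         dimnames = dimnames(aln$codons))
}
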