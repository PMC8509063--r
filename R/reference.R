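AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reference protein
#'
#' Holds the reference amino-acid sequence (1-based positions) against
#' which pooled reads and alignment rows are compared, optionally together
#' with the nucleotide open reading frame it was translated from.
#'
#' @param id Identifier.
#' @param aa_sequence Amino-acid string (uppercase, standard 20-letter
#'   alphabet). May be omitted when `orf_sequence` is given.
#' @param orf_sequence Optional nucleotide ORF; its translation (up to the
#'   first stop) must equal `aa_sequence`.
#' @return Object of class `"reference_protein"` with elements `id`,
#'   `aa_sequence`, `orf_sequence` and `length`.
#' @examples
#' ref <- hokc_reference()
#' ref$length
#' substr(ref$aa_sequence, 7, 7)  # M7
#' @export
reference_protein <- function(id, aa_sequence = NULL, orf_sequence = NULL) {
  if (is.null(aa_sequence)) {
    if (is.null(orf_sequence)) stop("provide aa_sequence and/or orf_sequence")
    aa_sequence <- translate_orf(orf_sequence)$aa
  }
  aa_sequence <- toupper(aa_sequence)
  if (nchar(aa_sequence) < 1L) stop("aa_sequence must be non-empty")
  res <- strsplit(aa_sequence, "")[[1]]
  if (!all(res %in% AA1))
    stop("aa_sequence contains non-standard residue(s): ",
         paste(unique(setdiff(res, AA1)), collapse = ", "))
  if (!is.null(orf_sequence)) {
    orf_sequence <- toupper(orf_sequence)
    tr <- translate_orf(orf_sequence)
    if (substr(tr$aa, 1, nchar(aa_sequence)) != aa_sequence)
      stop("orf_sequence does not translate to aa_sequence")
  }
  structure(list(id = id, aa_sequence = aa_sequence,
                 orf_sequence = orf_sequence, length = nchar(aa_sequence)),
            class = "reference_protein")
}

#' @export
print.reference_protein <- function(x, ...) {
  cat("Reference protein", x$id, "(", x$length, "aa )\n ", x$aa_sequence, "\n")
  invisible(x)
}

#' The short HokC reference used in the saturation-mutagenesis screen
#'
#' The toxin open reading frame starting at the second ATG; residue
#' numbering therefore puts the initiator methionine at position 1, the
#' transmembrane segment at roughly positions 1--24 and matches the
#' conventional substitution labels of the screen (M7, I12, C15, V24).
#' The nucleotide sequence is the wild-type codon sequence targeted by the
#' mutagenic oligonucleotides.
#'
#' @return A [reference_protein()] of 29 residues with its ORF.
#' @export
hokc_reference <- function() {
  orf <- paste0("ATGAAGCAGCATAAGGCG",          # M  K  Q  H  K  A
                "ATGATTGTCGCCCTGATC",          # M7 I  V  A  L  I12
                "GTCATCTGTATCACCGCC",          # V  I  C15 I  T  A18
                "GTAGTGGCGGCGCTGGTA",          # V19 V A21 A22 L V24
                "ACGAGAAAAGACCTC")             # T  R  K  D  L
  reference_protein("hokC", orf_sequence = orf)
}
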