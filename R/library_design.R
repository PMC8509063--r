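#' Degenerate codon schemes
#'
#' A degenerate codon scheme fixes, for each of the three codon positions,
#' the set of nucleotides that the mutagenic oligonucleotide may carry.
#' Saturation-mutagenesis libraries commonly use such schemes to reduce the
#' number of codons to screen while keeping amino-acid diversity; the SNS
#' scheme (first and third base S = G/C, second base N = any) encodes ten
#' amino acids and no stop codon.
#'
#' The scheme may be given either as a single IUPAC string such as
#' `"SNS"` or `"NNK"`, or as three explicit nucleotide sets.
#'
#' @param first IUPAC string for the whole codon (e.g. `"SNS"`), or the
#'   set of nucleotides allowed at the first position.
#' @param second,third Nucleotide sets for the second and third positions;
#'   ignored when `first` is a three-letter IUPAC string.
#' @param code Genetic code: a named character vector mapping codons to
#'   one-letter amino acids with `"*"` for stop. Defaults to the standard
#'   code (NCBI table 1) as shipped with Biostrings.
#' @return An object of class `"degenerate_scheme"`: a list with elements
#'   `alphabets` (list of three character vectors) and `code`.
#' @examples
#' sns <- degenerate_scheme("SNS")
#' encoded_amino_acids(sns)$amino_acids
#' @export
degenerate_scheme <- function(first, second = NULL, third = NULL,
                              code = Biostrings::GENETIC_CODE) {
  if (is.character(first) && length(first) == 1L && nchar(first) == 3L &&
      is.null(second) && is.null(third)) {
    letters3 <- strsplit(toupper(first), "")[[1]]
    map <- Biostrings::IUPAC_CODE_MAP
    if (!all(letters3 %in% names(map)))
      stop("unknown IUPAC nucleotide symbol in scheme '", first, "'")
    alphabets <- lapply(map[letters3], function(s) strsplit(s, "")[[1]])
  } else {
    alphabets <- list(first, second, third)
  }
  alphabets <- lapply(alphabets, function(a) sort(unique(toupper(as.character(a)))))
  for (a in alphabets) {
    if (length(a) < 1L) stop("each position alphabet must be non-empty")
    if (!all(a %in% c("A", "C", "G", "T")))
      stop("invalid nucleotide symbol(s): ",
           paste(setdiff(a, c("A", "C", "G", "T")), collapse = ", "),
           " (alphabets must be subsets of {A,C,G,T})")
  }
  stopifnot(is.character(code), !is.null(names(code)))
  structure(list(alphabets = unname(alphabets), code = code),
            class = "degenerate_scheme")
}

#' @export
print.degenerate_scheme <- function(x, ...) {
  alph <- vapply(x$alphabets, paste, "", collapse = "")
  cat("Degenerate codon scheme: [", alph[1], "][", alph[2], "][", alph[3], "]\n",
      sep = "")
  enc <- encoded_amino_acids(x)
  cat(" ", prod(lengths(x$alphabets)), "codons,", length(enc$amino_acids),
      "amino acids,", length(enc$stop_codons), "stop codon(s)\n")
  invisible(x)
}

#' Enumerate the concrete codons of a degenerate scheme
#'
#' Expands the cartesian product of the three position alphabets and
#' translates every codon with the scheme's genetic code.
#'
#' @param scheme A [degenerate_scheme()].
#' @return Named character vector: names are codons, values the encoded
#'   one-letter amino acid, with `"*"` for stop codons. Length equals the
#'   product of the three alphabet sizes.
#' @export
enumerate_degenerate_codons <- function(scheme) {
  stopifnot(inherits(scheme, "degenerate_scheme"))
  a <- scheme$alphabets
  grid <- expand.grid(third = a[[3]], second = a[[2]], first = a[[1]],
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$first, grid$second, grid$third)
  codons <- sort(codons)
  aa <- scheme$code[codons]
  if (anyNA(aa))
    stop("codon(s) missing from the genetic code table: ",
         paste(codons[is.na(aa)], collapse = ", "))
  setNames(unname(aa), codons)
}

#' Amino acids reachable by a degenerate scheme
#'
#' @param scheme A [degenerate_scheme()].
#' @return List with `amino_acids` (sorted distinct one-letter codes,
#'   stops excluded), `n` (its length), `stop_codons` (codons translating
#'   to stop) and `codons` (the full codon-to-amino-acid map).
#' @export
encoded_amino_acids <- function(scheme) {
  codons <- enumerate_degenerate_codons(scheme)
  stops <- names(codons)[codons == "*"]
  aas <- sort(unique(codons[codons != "*"]))
  list(amino_acids = unname(aas), n = length(aas),
       stop_codons = stops, codons = codons)
}

#' Expected variant counts for a mutagenised region
#'
#' For a region of `region_length` residues where each position can be
#' replaced by `aa_per_position` alternative amino acids, the library
#' contains `region_length * aa_per_position` single-point variants and
#' `aa_per_position ^ region_length` full combinations (e.g. a 3-residue
#' region at 10 amino acids per position gives 30 singles and 1000
#' combinations).
#'
#' @param region_length Number of residues in the region (>= 1).
#' @param aa_per_position Number of amino acids sampled per position (>= 1).
#' @return List with `single_variants` and `total_combinations`.
#' @export
expected_variant_counts <- function(region_length, aa_per_position) {
  if (length(region_length) != 1L || length(aa_per_position) != 1L ||
      !is.finite(region_length) || !is.finite(aa_per_position) ||
      region_length < 1 || aa_per_position < 1 ||
      region_length != round(region_length) ||
      aa_per_position != round(aa_per_position))
    stop("region_length and aa_per_position must be positive integers")
  list(single_variants = region_length * aa_per_position,
       total_combinations = aa_per_position^region_length)
}

#' Validate a mutagenesis region layout
#'
#' Regions are contiguous, non-overlapping 1-based residue intervals on
#' the reference protein, processed in order of their start positions.
#'
#' @param starts,ends Integer vectors of inclusive region bounds, or a
#'   two-column data frame / matrix passed as `starts`.
#' @param ref_length Optional reference protein length; when given, every
#'   region must lie within `[1, ref_length]`.
#' @return Data frame of class `"mutagenesis_regions"` with columns
#'   `index`, `start_pos`, `end_pos`, `length`.
#' @seealso [hokc_regions()] for the seven-region transmembrane tiling
#'   used in the HokC screen.
#' @export
region_layout <- function(starts, ends = NULL, ref_length = NULL) {
  if (is.null(ends)) {
    starts <- as.data.frame(starts)
    ends <- starts[[2]]
    starts <- starts[[1]]
  }
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("starts and ends must be non-empty vectors of equal length")
  if (any(starts < 1L)) stop("region layout error: positions must be >= 1")
  if (any(ends < starts)) stop("region layout error: end_pos < start_pos")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("region layout error: regions overlap")
  if (!is.null(ref_length) && any(ends > ref_length))
    stop("region layout error: region extends beyond the reference (length ",
         ref_length, ")")
  structure(data.frame(index = seq_along(starts), start_pos = starts,
                       end_pos = ends, length = ends - starts + 1L),
            class = c("mutagenesis_regions", "data.frame"))
}

#' Seven-region tiling of the HokC transmembrane segment
#'
#' The transmembrane region of the short HokC open reading frame (the form
#' starting at the second ATG) was mutagenised in seven tiles of neighbour
#' residues: residues 2--6 and then six three-residue windows up to
#' position 24, so region II spans residues 7--9 and region VI residues
#' 19--21.
#'
#' @return A [region_layout()] with seven regions covering residues 2--24.
#' @export
hokc_regions <- function() {
  region_layout(starts = c(2L, 7L, 10L, 13L, 16L, 19L, 22L),
                ends   = c(6L, 9L, 12L, 15L, 18L, 21L, 24L))
}

#' Report table for a degenerate scheme
#'
#' @param scheme A [degenerate_scheme()].
#' @return Data frame with columns `codon`, `amino_acid`, `is_stop`,
#'   suitable for writing as TSV.
#' @export
scheme_report <- function(scheme) {
  codons <- enumerate_degenerate_codons(scheme)
  data.frame(codon = names(codons), amino_acid = unname(codons),
             is_stop = unname(codons == "*"))
}
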