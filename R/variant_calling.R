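#' Translate an open reading frame
#'
#' Standard-code translation of an in-frame nucleotide sequence. Codons
#' containing `N` translate to `X`; translation stops at the first stop
#' codon, whose codon index is reported.
#'
#' @param dna Nucleotide string (bases `A`, `C`, `G`, `T`, `N`; length a
#'   multiple of three).
#' @param code Genetic code table (codon-named character vector).
#' @return List with `aa` (amino-acid string up to, excluding, the first
#'   stop) and `stop_at` (codon index of the first stop, or `NA` if none).
#' @examples
#' translate_orf("ATGGCG")       # "MA"
#' translate_orf("ATGTAAGCG")    # "M", stop at codon 2
#' @export
translate_orf <- function(dna, code = Biostrings::GENETIC_CODE) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0L) stop("empty input sequence")
  if (n %% 3L != 0L)
    stop("frame error: sequence length ", n, " is not a multiple of 3")
  chars <- strsplit(dna, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("invalid base(s): ",
         paste(unique(setdiff(chars, c("A", "C", "G", "T", "N"))), collapse = ", "))
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # any codon containing N
  stop_at <- which(aa == "*")[1]
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  list(aa = paste(aa, collapse = ""), stop_at = stop_at)
}

#' Call substitutions of a protein sequence against the reference
#'
#' Position-by-position comparison of an ungapped amino-acid sequence
#' (aligned to the reference start) with the reference protein. `X`
#' residues (from ambiguous bases) are never called as substitutions.
#'
#' @param aa_seq Amino-acid string.
#' @param reference A [reference_protein()].
#' @param min_length Minimum sequence length required for a call; reads
#'   shorter than this raise a coverage error. Defaults to the full
#'   reference length (full-ORF amplicons).
#' @return Canonical genotype string (see [parse_genotype()]); `"WT"` when
#'   the sequence matches the reference everywhere.
#' @export
call_substitutions <- function(aa_seq, reference,
                               min_length = reference$length) {
  stopifnot(inherits(reference, "reference_protein"))
  aa_seq <- toupper(aa_seq)
  if (nchar(aa_seq) < min_length)
    stop("coverage error: sequence length ", nchar(aa_seq),
         " is below the required span of ", min_length, " residues")
  n <- min(nchar(aa_seq), reference$length)
  q <- strsplit(substr(aa_seq, 1L, n), "")[[1]]
  r <- strsplit(substr(reference$aa_sequence, 1L, n), "")[[1]]
  i <- which(q != r & q != "X")
  if (length(i) == 0L) return("WT")
  paste0(r[i], i, q[i], collapse = ",")
}

#' Drop observations mutated beyond a position limit
#'
#' Pooled observations whose genotype carries a substitution strictly
#' beyond `max_pos` are removed (mutations outside the mutagenised
#' region -- e.g. beyond the end of a transmembrane segment -- are not
#' analysed). A substitution exactly at `max_pos` is retained.
#'
#' @param observations Data frame with at least a `genotype` column
#'   ([parse_genotype()] format) and typically `phenotype` and `count`.
#' @param max_pos Largest analysed residue position (>= 1).
#' @return The filtered data frame, with attribute `"n_removed"` holding
#'   the number of removed observations (rows). Idempotent.
#' @export
filter_by_max_position <- function(observations, max_pos) {
  stopifnot(is.data.frame(observations), "genotype" %in% names(observations),
            length(max_pos) == 1L, max_pos >= 1)
  beyond <- vapply(observations$genotype,
                   function(g) any(genotype_positions(g) > max_pos), NA)
  out <- observations[!beyond, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(beyond)
  out
}

#' Tally pooled observations per genotype and per substitution
#'
#' Aggregates phenotype-labelled observations into a genotype-level count
#' table and a single-substitution-level count table; the substitution
#' counts of a mutation sum the genotype counts over every genotype that
#' contains it, matching the pooled-count convention (`WT_i` = times the
#' mutation was seen with wild-type phenotype, `MUT_i` with mutant
#' phenotype).
#'
#' @param observations Data frame with columns `genotype`, `phenotype`
#'   (`"wild_type"` or `"mutant"`) and `count` (non-negative integers;
#'   defaults to 1 per row if absent).
#' @return Object of class `"mutation_tally"`: list with data frames
#'   `genotypes` (`genotype`, `n_subs`, `wt_count`, `mut_count`) and
#'   `substitutions` (`sub`, `position`, `ref`, `alt`, `wt_count`,
#'   `mut_count`), plus the per-pool `totals`.
#' @export
tally_counts <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("genotype", "phenotype") %in% names(observations)))
  if (!"count" %in% names(observations)) observations$count <- 1L
  if (!all(observations$phenotype %in% c("wild_type", "mutant")))
    stop("unknown phenotype label(s): ",
         paste(unique(setdiff(observations$phenotype,
                              c("wild_type", "mutant"))), collapse = ", "))
  if (any(observations$count < 0)) stop("counts must be non-negative")

  agg <- function(df) {
    if (nrow(df) == 0L) return(setNames(numeric(), character()))
    tapply(df$count, df$genotype, sum)
  }
  wt <- agg(observations[observations$phenotype == "wild_type", ])
  mut <- agg(observations[observations$phenotype == "mutant", ])
  genos <- sort(unique(c(names(wt), names(mut))))
  wtc <- as.numeric(wt[genos]); wtc[is.na(wtc)] <- 0
  mutc <- as.numeric(mut[genos]); mutc[is.na(mutc)] <- 0
  gt <- data.frame(genotype = genos, n_subs = genotype_size(genos),
                   wt_count = wtc, mut_count = mutc)
  rownames(gt) <- NULL

  sub_sets <- genotype_subs(gt$genotype)
  flat <- data.frame(sub = unlist(sub_sets),
                     wt_count = rep(gt$wt_count, lengths(sub_sets)),
                     mut_count = rep(gt$mut_count, lengths(sub_sets)))
  if (nrow(flat) > 0L) {
    swt <- tapply(flat$wt_count, flat$sub, sum)
    smut <- tapply(flat$mut_count, flat$sub, sum)
    subs <- names(swt)
    m <- regmatches(subs, regexec("^([A-Z])([0-9]+)([A-Z*])$", subs))
    st <- data.frame(sub = subs,
                     position = as.integer(vapply(m, `[`, "", 3L)),
                     ref = vapply(m, `[`, "", 2L),
                     alt = vapply(m, `[`, "", 4L),
                     wt_count = as.numeric(swt[subs]),
                     mut_count = as.numeric(smut[subs]))
    st <- st[order(st$position, st$alt), ]
    rownames(st) <- NULL
  } else {
    st <- data.frame(sub = character(), position = integer(),
                     ref = character(), alt = character(),
                     wt_count = numeric(), mut_count = numeric())
  }
  totals <- c(wild_type = sum(gt$wt_count), mutant = sum(gt$mut_count))
  structure(list(genotypes = gt, substitutions = st, totals = totals),
            class = "mutation_tally")
}

#' @export
print.mutation_tally <- function(x, ...) {
  cat("Mutation tally:", nrow(x$genotypes), "genotypes,",
      nrow(x$substitutions), "distinct single substitutions\n")
  cat("  reads: wild-type pool", x$totals[["wild_type"]],
      "/ mutant pool", x$totals[["mutant"]], "\n")
  invisible(x)
}

# vectorised translation + substitution calling for read pools ---------------

# reads: character vector of equal-frame DNA; returns list(genotype, nonsense)
call_reads <- function(reads, reference, code = Biostrings::GENETIC_CODE) {
  n_codon <- reference$length
  keep <- nchar(reads) >= 3L * n_codon & nchar(reads) %% 3L == 0L
  frame_dropped <- sum(!keep)
  reads <- reads[keep]
  if (length(reads) == 0L)
    return(list(genotype = character(), nonsense = 0L,
                frame_dropped = frame_dropped))
  aam <- matrix("", nrow = length(reads), ncol = n_codon)
  for (k in seq_len(n_codon)) {
    codons <- substr(reads, 3L * k - 2L, 3L * k)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    aam[, k] <- aa
  }
  nonsense <- rowSums(aam == "*") > 0L
  aam <- aam[!nonsense, , drop = FALSE]
  refv <- strsplit(reference$aa_sequence, "")[[1]][seq_len(n_codon)]
  diffm <- aam != rep(refv, each = nrow(aam)) & aam != "X"
  hits <- which(diffm, arr.ind = TRUE)
  geno <- rep("WT", nrow(aam))
  if (nrow(hits) > 0L) {
    o <- order(hits[, 1L], hits[, 2L])
    hits <- hits[o, , drop = FALSE]
    sub <- paste0(refv[hits[, 2L]], hits[, 2L], aam[hits])
    per_read <- vapply(split(sub, hits[, 1L]), paste, "", collapse = ",")
    geno[as.integer(names(per_read))] <- per_read
  }
  list(genotype = geno, nonsense = sum(nonsense), frame_dropped = frame_dropped)
}

#' Call variants from two phenotype-labelled read pools
#'
#' End-to-end variant calling: translates full-ORF amplicon reads from the
#' wild-type-phenotype and mutant-phenotype pools, calls substitutions
#' against the reference, discards frame-broken reads and reads carrying a
#' stop codon inside the analysed span (nonsense variants are reported
#' separately, not mixed into missense statistics), removes observations
#' mutated beyond `max_pos` and tallies pooled counts.
#'
#' @param wt_reads,mut_reads Character vectors of nucleotide reads, or
#'   paths to FASTA/FASTQ files (read with Biostrings).
#' @param reference A [reference_protein()].
#' @param max_pos Largest analysed residue position (default: the full
#'   reference length, i.e. no positional filter).
#' @param code Genetic code table.
#' @return A [tally_counts()] object with an additional `log` element
#'   recording discarded read counts per pool.
#' @export
call_pools <- function(wt_reads, mut_reads, reference,
                       max_pos = reference$length,
                       code = Biostrings::GENETIC_CODE) {
  load_pool <- function(x) {
    if (length(x) == 1L && file.exists(x)) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x)) "fastq" else "fasta"
      x <- as.character(Biostrings::readDNAStringSet(x, format = fmt))
    }
    toupper(as.character(x))
  }
  wt <- call_reads(load_pool(wt_reads), reference, code)
  mut <- call_reads(load_pool(mut_reads), reference, code)
  obs <- data.frame(
    genotype = c(wt$genotype, mut$genotype),
    phenotype = rep(c("wild_type", "mutant"),
                    c(length(wt$genotype), length(mut$genotype))),
    count = 1L)
  obs <- filter_by_max_position(obs, max_pos)
  tal <- tally_counts(obs)
  tal$log <- data.frame(
    pool = c("wild_type", "mutant"),
    frame_dropped = c(wt$frame_dropped, mut$frame_dropped),
    nonsense = c(wt$nonsense, mut$nonsense),
    beyond_max_pos = c(NA, NA))
  tal$log$beyond_max_pos[1] <- attr(obs, "n_removed")
  tal
}
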