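#' Protein multiple sequence alignment with a designated reference row
#'
#' Wraps a gapped protein alignment together with a reference row and the
#' map from alignment columns to 1-based reference positions (columns
#' where the reference is gapped map to `NA` and are skipped by all
#' reference-coordinate analyses).
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (gap characters `-` and `.`).
#' @param reference_id Name of the reference row.
#' @return Object of class `"protein_msa"`: list with `ids`, `seqs`,
#'   `reference_id`, `ref_seq` (ungapped reference), `column_map`
#'   (integer per alignment column) and `n_col`.
#' @export
protein_msa <- function(seqs, reference_id) {
  ids <- names(seqs)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique names")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows must all have equal length")
  if (!reference_id %in% ids)
    stop("reference_id '", reference_id, "' not found in the alignment")
  ref_row <- strsplit(seqs[[which(ids == reference_id)]], "")[[1]]
  is_res <- !ref_row %in% c("-", ".")
  column_map <- rep(NA_integer_, length(ref_row))
  column_map[is_res] <- seq_len(sum(is_res))
  structure(list(ids = ids, seqs = unname(seqs), reference_id = reference_id,
                 ref_seq = paste(ref_row[is_res], collapse = ""),
                 column_map = column_map, n_col = length(ref_row)),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("Protein MSA:", length(x$ids), "sequences x", x$n_col, "columns;",
      "reference", x$reference_id, "(", nchar(x$ref_seq), "residues )\n")
  invisible(x)
}

#' Read an alignment from FASTA or Stockholm
#'
#' @param path Path to an aligned FASTA or Stockholm file.
#' @param reference_id Identifier of the reference row (sequence names are
#'   matched first exactly, then with any `/start-end` range stripped).
#' @param format `"fasta"` or `"stockholm"`; guessed from the file
#'   extension by default (`.sto`/`.stk` mean Stockholm).
#' @return A [protein_msa()].
#' @export
read_msa <- function(path, reference_id,
                     format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(sto|stk|stockholm)$", path)) "stockholm" else "fasta"
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  if (!reference_id %in% names(seqs)) {
    stripped <- sub("/[0-9]+-[0-9]+$", "", names(seqs))
    hit <- which(stripped == reference_id)
    if (length(hit) == 1L) names(seqs)[hit] <- reference_id
  }
  protein_msa(seqs, reference_id)
}

# residues of every row at the columns mapping to reference positions:
# matrix [n_rows x ref_length], rownames = ids
msa_residue_matrix <- function(msa) {
  cols <- which(!is.na(msa$column_map))
  m <- matrix(unlist(strsplit(msa$seqs, ""), use.names = FALSE),
              nrow = length(msa$ids), ncol = msa$n_col, byrow = TRUE)
  m <- m[, cols, drop = FALSE]
  rownames(m) <- msa$ids
  m
}

#' Reference-based conservation scores
#'
#' For every reference position, the fraction of alignment rows whose
#' residue at the corresponding column equals the reference residue. A
#' gap never matches the reference, and gapped rows stay in the
#' denominator unless `gap_policy = "exclude"`.
#'
#' @param msa A [protein_msa()].
#' @param include_reference Count the reference row itself (default TRUE).
#' @param gap_policy `"count"` (gaps are mismatches, default) or
#'   `"exclude"` (rows gapped at a position leave their denominator).
#' @return Data frame with `position`, `ref_aa`, `n_match`, `n_rows`,
#'   `score` in \[0, 1\].
#' @export
conservation_scores <- function(msa, include_reference = TRUE,
                                gap_policy = c("count", "exclude")) {
  gap_policy <- match.arg(gap_policy)
  m <- msa_residue_matrix(msa)
  if (!include_reference) m <- m[rownames(m) != msa$reference_id, , drop = FALSE]
  ref <- strsplit(msa$ref_seq, "")[[1]]
  match_m <- m == rep(ref, each = nrow(m))
  gap_m <- m == "-" | m == "."
  match_m[gap_m] <- FALSE
  n_match <- colSums(match_m)
  n_rows <- if (gap_policy == "exclude") colSums(!gap_m) else rep(nrow(m), ncol(m))
  data.frame(position = seq_along(ref), ref_aa = ref,
             n_match = n_match, n_rows = n_rows,
             score = ifelse(n_rows > 0, n_match / n_rows, NA_real_))
}

#' Substitutions of every alignment row relative to the reference
#'
#' @param msa A [protein_msa()].
#' @param drop_reference Omit the reference row (default TRUE).
#' @return Named character vector of genotype strings (see
#'   [parse_genotype()]); gap and non-standard characters are never
#'   called as substitutions.
#' @export
reference_substitutions <- function(msa, drop_reference = TRUE) {
  m <- msa_residue_matrix(msa)
  if (drop_reference) m <- m[rownames(m) != msa$reference_id, , drop = FALSE]
  ref <- strsplit(msa$ref_seq, "")[[1]]
  out <- apply(m, 1L, function(row) {
    i <- which(row != ref & row %in% AA1)
    if (length(i) == 0L) "WT" else paste0(ref[i], i, row[i], collapse = ",")
  })
  out
}

#' Count family sequences carrying compensated deleterious mutations
#'
#' Counts alignment rows whose substitution set (relative to the
#' reference) contains at least one experimentally deleterious single
#' substitution *and* at least two substitutions in total -- multiple
#' mutations harbouring a loss-of-function mutation, i.e. candidate
#' compensated homologs.
#'
#' @param msa A [protein_msa()].
#' @param deleterious Character vector of deleterious substitutions in
#'   reference coordinates (e.g. `"A6T"`), or, with
#'   `match = "position"`, any substitution at the same position counts.
#' @param match `"substitution"` (exact ref/pos/alt, default) or
#'   `"position"`.
#' @return List with `count` and `detail`, a data frame per non-reference
#'   row (`id`, `n_subs`, `contained_deleterious`, `qualifies`).
#' @export
count_compensated_sequences <- function(msa, deleterious,
                                        match = c("substitution", "position")) {
  match <- match.arg(match)
  genos <- reference_substitutions(msa)
  sets <- genotype_subs(genos)
  if (match == "position") {
    del_pos <- unique(unlist(lapply(deleterious, genotype_positions)))
    contained <- vapply(sets, function(s) {
      pos <- unlist(lapply(s, genotype_positions))
      paste(s[pos %in% del_pos], collapse = ",")
    }, "")
  } else {
    contained <- vapply(sets, function(s)
      paste(intersect(s, deleterious), collapse = ","), "")
  }
  n_subs <- genotype_size(genos)
  qualifies <- n_subs >= 2L & contained != ""
  detail <- data.frame(id = names(genos), n_subs = n_subs,
                       contained_deleterious = contained,
                       qualifies = qualifies, row.names = NULL)
  list(count = sum(qualifies), detail = detail)
}

#' Contact-conditioned correlated mutation index
#'
#' For every pair of residues in contact in the reference structure, the
#' reference amino-acid pair type is tallied (`observed`); a pair counts
#' as *mutated* in an alignment row when both positions carry non-gap
#' residues that differ from the reference (`mutated` accumulates such
#' row-by-pair events). The index of a pair type is
#' `mutated / observed` -- the convention of the worked example in which
#' 30 contacting Ala--Ala pairs mutated 15 times give 50% -- or, with
#' `normalizer = "rows"`, `mutated / (observed * n_rows)`, which is
#' bounded by 1.
#'
#' @param msa A [protein_msa()].
#' @param contacts A [contact_graph()] whose node indices are reference
#'   positions of `msa`.
#' @param normalizer `"observed"` (default) or `"rows"`.
#' @return Data frame of class `"pair_mutation_table"` with one row per
#'   ordered amino-acid pair type (400 rows): `aa_i`, `aa_j`, `observed`,
#'   `mutated`, `frequency` (NA where `observed` is 0). The row count of
#'   the alignment (reference excluded) is kept in attribute `"n_rows"`.
#' @export
correlated_mutation_index <- function(msa, contacts,
                                      normalizer = c("observed", "rows")) {
  normalizer <- match.arg(normalizer)
  stopifnot(inherits(contacts, "contact_graph"))
  ref <- strsplit(msa$ref_seq, "")[[1]]
  edges <- contacts$edges
  if (nrow(edges) > 0L && max(edges$i, edges$j) > length(ref))
    stop("coordinate mismatch: contact node beyond the reference length (",
         length(ref), ")")
  m <- msa_residue_matrix(msa)
  m <- m[rownames(m) != msa$reference_id, , drop = FALSE]
  n_rows <- nrow(m)
  diff_m <- m != rep(ref, each = n_rows) & !(m %in% c("-", ".")) &
    matrix(m %in% AA1, nrow = n_rows)
  types <- expand.grid(aa_j = AA1, aa_i = AA1, stringsAsFactors = FALSE)
  tab <- data.frame(aa_i = types$aa_i, aa_j = types$aa_j,
                    observed = 0L, mutated = 0L)
  key <- paste(tab$aa_i, tab$aa_j)
  if (nrow(edges) > 0L) {
    ek <- paste(ref[edges$i], ref[edges$j])
    obs <- table(ek)
    tab$observed[match(names(obs), key)] <- as.integer(obs)
    mut_events <- colSums(diff_m[, edges$i, drop = FALSE] &
                            diff_m[, edges$j, drop = FALSE])
    mut_by_type <- tapply(mut_events, ek, sum)
    tab$mutated[match(names(mut_by_type), key)] <- as.integer(mut_by_type)
  }
  denom <- if (normalizer == "rows") tab$observed * n_rows else tab$observed
  tab$frequency <- ifelse(tab$observed > 0, tab$mutated / denom, NA_real_)
  tab <- tab[order(tab$aa_i, tab$aa_j), ]
  rownames(tab) <- NULL
  structure(tab, class = c("pair_mutation_table", "data.frame"),
            n_rows = n_rows, normalizer = normalizer)
}

#' Symmetrise a pair-type mutation table
#'
#' Collapses the 400 ordered amino-acid pair types into the 210 unordered
#' ones by summing `observed` and `mutated` over the two orders.
#'
#' @param tab A [correlated_mutation_index()] table.
#' @return Data frame with unordered pair types and recomputed frequency.
#' @export
symmetrize_pair_table <- function(tab) {
  stopifnot(inherits(tab, "pair_mutation_table"))
  a <- pmin(tab$aa_i, tab$aa_j); b <- pmax(tab$aa_i, tab$aa_j)
  k <- paste(a, b)
  obs <- tapply(tab$observed, k, sum)
  mut <- tapply(tab$mutated, k, sum)
  ks <- strsplit(names(obs), " ")
  denom <- if (attr(tab, "normalizer") == "rows")
    obs * attr(tab, "n_rows") else obs
  out <- data.frame(aa_i = vapply(ks, `[`, "", 1L),
                    aa_j = vapply(ks, `[`, "", 2L),
                    observed = as.integer(obs), mutated = as.integer(mut),
                    frequency = ifelse(obs > 0, mut / denom, NA_real_))
  rownames(out) <- NULL
  out
}
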