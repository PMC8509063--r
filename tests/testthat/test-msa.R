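msa_fixture <- function() {
  protein_msa(c(REF = "MKQA", h1 = "MKQA", h2 = "MKTA", h3 = "M-QA"), "REF")
}

test_that("alignment construction validates rows and maps columns", {
  expect_error(protein_msa(c(a = "ABC", b = "AB"), "a"), "equal length")
  expect_error(protein_msa(c(a = "ABC"), "zzz"), "not found")
  expect_error(protein_msa(c("ABC", "ABD"), "a"), "unique names")

  gapped <- protein_msa(c(REF = "M-KA", h1 = "MQKA"), "REF")
  expect_identical(gapped$ref_seq, "MKA")
  expect_identical(gapped$column_map, c(1L, NA, 2L, 3L))
})

test_that("conservation counts reference-matching residues per position", {
  m <- msa_fixture()
  cs <- conservation_scores(m)
  expect_equal(cs$score, c(1, 0.75, 0.75, 1))  # hand counts over 4 rows
  expect_true(all(cs$score >= 0 & cs$score <= 1))

  # a column gapped in every non-reference row scores 1/n with gaps counted
  allgap <- protein_msa(c(REF = "MA", h1 = "M-", h2 = "M-", h3 = "M-"), "REF")
  expect_equal(conservation_scores(allgap)$score, c(1, 0.25))
  expect_equal(conservation_scores(allgap, gap_policy = "exclude")$score[2], 1)
  expect_equal(conservation_scores(allgap, include_reference = FALSE)$score,
               c(1, 0))

  # score is 1 everywhere iff all rows equal the reference
  same <- protein_msa(c(REF = "MKQA", h1 = "MKQA"), "REF")
  expect_true(all(conservation_scores(same)$score == 1))
})

test_that("per-row substitutions are a positionwise diff in reference coordinates", {
  m <- msa_fixture()
  subs <- reference_substitutions(m)
  expect_identical(unname(subs[c("h1", "h2", "h3")]), c("WT", "Q3T", "WT"))

  set.seed(41)
  ref <- paste(sample(AA20, 25, TRUE), collapse = "")
  refv <- strsplit(ref, "")[[1]]
  for (rep in 1:20) {
    q <- refv
    pos <- sample(25, sample(0:5, 1))
    for (p in pos) q[p] <- sample(setdiff(c(AA20, "-"), refv[p]), 1)
    msa <- protein_msa(c(REF = ref, row = paste(q, collapse = "")), "REF")
    got <- unname(reference_substitutions(msa))
    keep <- which(q != refv & q != "-")
    oracle <- if (length(keep) == 0) "WT" else
      paste0(refv[keep], keep, q[keep], collapse = ",")
    expect_identical(got, oracle)
  }
})

test_that("compensated-sequence counting needs >= 2 substitutions incl. a deleterious one", {
  ref <- "MKAVLA"
  rows <- c(REF = ref,
            a = "MMTVLA",   # K2M + A3T, contains A3T        -> qualifies
            b = "MKTVLA",   # single A3T                     -> no (single)
            c = "MMAVLG",   # K2M + A6G, no deleterious sub  -> no
            d = "MKTVLG",   # A3T + A6G                      -> qualifies
            e = "MKAVLA")   # identical                      -> no
  msa <- protein_msa(rows, "REF")
  res <- count_compensated_sequences(msa, deleterious = c("A3T", "V4W"))
  expect_identical(res$count, 2L)
  expect_setequal(res$detail$id[res$detail$qualifies], c("a", "d"))

  # position matching widens the deleterious definition
  res_pos <- count_compensated_sequences(msa, deleterious = "A6T",
                                         match = "position")
  expect_identical(res_pos$count, 2L)  # rows c and d carry A6G at position 6

  # planted fraction on a simulated alignment: plant 12 qualifying rows of 40
  set.seed(9)
  base <- strsplit("MKAVLAWIVALK", "")[[1]]
  rows <- vapply(1:40, function(i) {
    q <- base
    if (i <= 12) {         # deleterious W7L plus one companion substitution
      q[7] <- "L"; q[10] <- "T"
    } else if (i <= 20) {  # companion only
      q[10] <- "T"
    }
    paste(q, collapse = "")
  }, "")
  names(rows) <- sprintf("r%02d", 1:40)
  msa2 <- protein_msa(c(REF = paste(base, collapse = ""), rows), "REF")
  expect_identical(count_compensated_sequences(msa2, "W7L")$count, 12L)
})

test_that("correlated mutation index reproduces the worked pair-frequency example", {
  fx <- ala_pair_fixture(n_pairs = 30, n_events = 15)
  tab <- correlated_mutation_index(fx$msa, fx$contacts)
  aa_row <- tab[tab$aa_i == "A" & tab$aa_j == "A", ]
  expect_identical(aa_row$observed, 30L)
  expect_identical(aa_row$mutated, 15L)
  expect_equal(aa_row$frequency, 0.5)  # 50%
  expect_true(all(tab$observed[!(tab$aa_i == "A" & tab$aa_j == "A")] == 0))
  expect_identical(nrow(tab), 400L)

  # an alignment without substitutions has zero frequency everywhere observed
  fx0 <- ala_pair_fixture(n_pairs = 5, n_events = 0, n_extra_rows = 4)
  tab0 <- correlated_mutation_index(fx0$msa, fx0$contacts)
  expect_true(all(tab0$frequency[tab0$observed > 0] == 0))
  expect_true(all(is.na(tab0$frequency[tab0$observed == 0])))
})

test_that("the index is invariant under row permutation and respects coordinates", {
  fx <- ala_pair_fixture(n_pairs = 10, n_events = 6)
  tab <- correlated_mutation_index(fx$msa, fx$contacts)
  seqs <- setNames(fx$msa$seqs, fx$msa$ids)
  perm <- c("REF", sample(setdiff(names(seqs), "REF")))
  tab_perm <- correlated_mutation_index(protein_msa(seqs[perm], "REF"),
                                        fx$contacts)
  expect_equal(tab$mutated, tab_perm$mutated)
  expect_equal(tab$observed, tab_perm$observed)

  too_big <- contact_graph(100, data.frame(i = 1, j = 99))
  expect_error(correlated_mutation_index(fx$msa, too_big),
               "coordinate mismatch")
})

test_that("both normalizers are consistent and symmetrization sums orders", {
  fx <- ala_pair_fixture(n_pairs = 30, n_events = 15, n_extra_rows = 5)
  tab <- correlated_mutation_index(fx$msa, fx$contacts)
  tab_rows <- correlated_mutation_index(fx$msa, fx$contacts, normalizer = "rows")
  n_rows <- attr(tab_rows, "n_rows")
  i <- which(tab$aa_i == "A" & tab$aa_j == "A")
  expect_equal(tab_rows$frequency[i], tab$frequency[i] / n_rows)
  expect_true(all(tab_rows$frequency >= 0 & tab_rows$frequency <= 1, na.rm = TRUE))

  sym <- symmetrize_pair_table(tab)
  expect_identical(nrow(sym), 210L)
  expect_identical(sum(sym$observed), sum(tab$observed))
  expect_identical(sum(sym$mutated), sum(tab$mutated))
})

test_that("alignments round-trip through FASTA and Stockholm readers", {
  dir <- withr::local_tempdir()
  seqs <- c(REF = "MKQ-A", h1 = "MKTTA", h2 = "M-QCA")

  fa <- file.path(dir, "aln.fasta")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), fa)
  m1 <- read_msa(fa, "REF")
  expect_identical(m1$ref_seq, "MKQA")
  expect_identical(m1$column_map, c(1L, 2L, 3L, NA, 4L))

  sto <- file.path(dir, "aln.sto")
  writeLines(c("# STOCKHOLM 1.0",
               paste("REF/1-4", "MKQ-A"), paste("h1", "MKTTA"),
               paste("h2", "M-QCA"), "//"), sto)
  m2 <- read_msa(sto, "REF")  # id matched with the /start-end range stripped
  expect_identical(m2$ref_seq, "MKQA")
  expect_identical(unname(reference_substitutions(m2)["h1"]), "Q3T")
})
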