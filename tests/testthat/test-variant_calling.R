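test_that("ORF translation handles stops, ambiguity and frame errors", {
  expect_identical(translate_orf("ATGGCG")$aa, "MA")

  tr <- translate_orf("ATGTAAGCG")
  expect_identical(tr$aa, "M")
  expect_identical(tr$stop_at, 2L)

  expect_identical(translate_orf("ATGANG")$aa, "MX")
  expect_error(translate_orf("ATGA"), "frame error")
  expect_error(translate_orf(""), "empty")
  expect_error(translate_orf("ATGXAA"), "invalid base")
})

test_that("translation matches the Biostrings oracle on random ORFs", {
  set.seed(5)
  for (rep in 1:25) {
    dna <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    oracle <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                                 no.init.codon = TRUE))
    oracle <- sub("\\*.*$", "", oracle)  # truncate at the first stop
    expect_identical(translate_orf(dna)$aa, oracle)
  }
})

test_that("substitution calling against the reference is a positionwise diff", {
  ref <- hokc_reference()
  expect_identical(call_substitutions(ref$aa_sequence, ref), "WT")

  mut <- apply_genotype(ref$aa_sequence, "M7W,I12S")
  expect_identical(call_substitutions(mut, ref), "M7W,I12S")

  # ambiguous residues are never called
  amb <- paste0("X", substr(ref$aa_sequence, 2, ref$length))
  expect_identical(call_substitutions(amb, ref), "WT")

  expect_error(call_substitutions("MKQ", ref), "coverage error")

  set.seed(17)
  refv <- strsplit(ref$aa_sequence, "")[[1]]
  for (rep in 1:100) {
    q <- refv
    k <- sample(0:4, 1)
    pos <- sample(ref$length, k)
    for (p in pos) q[p] <- sample(setdiff(AA20, refv[p]), 1)
    called <- call_substitutions(paste(q, collapse = ""), ref)
    oracle_pos <- which(q != refv)
    oracle <- if (length(oracle_pos) == 0) "WT" else
      paste0(refv[oracle_pos], oracle_pos, q[oracle_pos], collapse = ",")
    expect_identical(called, oracle)
  }
})

test_that("calling round-trips genotypes applied to the reference", {
  ref <- hokc_reference()
  set.seed(23)
  refv <- strsplit(ref$aa_sequence, "")[[1]]
  for (rep in 1:50) {
    pos <- sort(sample(ref$length, sample(1:5, 1)))
    geno <- paste0(refv[pos], pos,
                   vapply(refv[pos], function(a) sample(setdiff(AA20, a), 1), ""),
                   collapse = ",")
    expect_identical(call_substitutions(apply_genotype(ref$aa_sequence, geno), ref),
                     geno)
  }
})

test_that("genotype parsing and formatting are canonical and validated", {
  g <- parse_genotype("I12S,M7W")
  expect_identical(g$sub, c("M7W", "I12S"))  # reordered by position
  expect_identical(format_genotype(g), "M7W,I12S")
  expect_identical(format_genotype(parse_genotype("WT")), "WT")
  expect_error(parse_genotype("M7M"), "identical")
  expect_error(parse_genotype("M7W,M7S"), "more than one substitution")
  expect_error(parse_genotype("7MW"), "malformed")
})

test_that("position filtering removes only genotypes mutated beyond the limit", {
  obs <- data.frame(
    genotype = c("D28E", "V24G", "M7W,D28E", "M7W", "WT"),
    phenotype = "wild_type", count = 1L)
  kept <- filter_by_max_position(obs, 24)
  expect_setequal(kept$genotype, c("V24G", "M7W", "WT"))
  expect_identical(attr(kept, "n_removed"), 2L)

  # idempotent
  again <- filter_by_max_position(kept, 24)
  expect_identical(again$genotype, kept$genotype)
  expect_identical(attr(again, "n_removed"), 0L)

  empty <- filter_by_max_position(obs[0, ], 24)
  expect_identical(nrow(empty), 0L)
})

test_that("tallying aggregates genotype and substitution counts coherently", {
  one <- tally_counts(data.frame(genotype = "WT", phenotype = "wild_type",
                                 count = 5L))
  expect_identical(one$genotypes$wt_count, 5)
  expect_identical(one$genotypes$mut_count, 0)
  expect_identical(nrow(one$substitutions), 0L)

  tal <- tally_counts(data.frame(
    genotype = c("M7W", "M7W,I12S"),
    phenotype = c("mutant", "wild_type"),
    count = c(3L, 2L)))
  m7w <- tal$substitutions[tal$substitutions$sub == "M7W", ]
  expect_identical(c(m7w$wt_count, m7w$mut_count), c(2, 3))  # hand aggregation
  i12s <- tal$substitutions[tal$substitutions$sub == "I12S", ]
  expect_identical(c(i12s$wt_count, i12s$mut_count), c(2, 0))

  expect_error(tally_counts(data.frame(genotype = "WT", phenotype = "odd",
                                       count = 1L)), "unknown phenotype")
})

test_that("tallying conserves per-pool read totals on random observation sets", {
  ref <- hokc_reference()
  refv <- strsplit(ref$aa_sequence, "")[[1]]
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    genos <- vapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return("WT")
      pos <- sort(sample(ref$length, k))
      paste0(refv[pos], pos,
             vapply(refv[pos], function(a) sample(setdiff(AA20, a), 1), ""),
             collapse = ",")
    }, "")
    obs <- data.frame(genotype = genos,
                      phenotype = sample(c("wild_type", "mutant"), n, TRUE),
                      count = sample(1:50, n, TRUE))
    tal <- tally_counts(obs)
    expect_equal(tal$totals[["wild_type"]],
                 sum(obs$count[obs$phenotype == "wild_type"]))
    expect_equal(tal$totals[["mutant"]],
                 sum(obs$count[obs$phenotype == "mutant"]))
    expect_equal(sum(tal$genotypes$wt_count) + sum(tal$genotypes$mut_count),
                 sum(obs$count))
  }
})

test_that("pool calling reads FASTA files and logs discarded reads", {
  ref <- hokc_reference()
  orf <- ref$orf_sequence
  mut7 <- orf
  substr(mut7, 19, 21) <- "TGG"  # M7W codon swap
  stop_read <- orf
  substr(stop_read, 4, 6) <- "TAA"  # nonsense at codon 2
  dir <- withr::local_tempdir()
  wt_path <- file.path(dir, "wt.fasta")
  mut_path <- file.path(dir, "mut.fasta")
  writeLines(c(">r1", orf, ">r2", orf, ">r3", stop_read), wt_path)
  writeLines(c(">m1", mut7, ">m2", substr(orf, 1, 10)), mut_path)

  tal <- call_pools(wt_path, mut_path, ref, max_pos = 24)
  expect_identical(tal$genotypes$wt_count[tal$genotypes$genotype == "WT"], 2)
  expect_identical(tal$genotypes$mut_count[tal$genotypes$genotype == "M7W"], 1)
  expect_identical(tal$log$nonsense[tal$log$pool == "wild_type"], 1L)
  expect_identical(tal$log$frame_dropped[tal$log$pool == "mutant"], 1L)
})
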