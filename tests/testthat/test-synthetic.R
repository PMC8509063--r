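test_that("ideal helix has canonical backbone geometry", {
  h <- make_ideal_helix(2)
  ca <- h$atoms[h$atoms$atom == "CA", ]
  d <- sqrt(sum((ca[2, c("x", "y", "z")] - ca[1, c("x", "y", "z")])^2))
  expect_equal(d, 3.81, tolerance = 0.01)  # closed form from rise/twist/radius

  single <- make_ideal_helix(1)
  expect_identical(single$n_residues, 1L)
  expect_identical(nrow(build_contact_map(single)$edges), 0L)

  h20 <- make_ideal_helix(20)
  g <- build_contact_map(h20, cutoff = 5)
  key <- paste(g$edges$i, g$edges$j)
  for (s in c(3L, 4L))
    expect_true(all(paste(1:(20 - s), (1 + s):20) %in% key))

  expect_error(make_ideal_helix(0), "n_residues")
  expect_error(make_ideal_helix(5, jitter = 0.1), "seed")
  j1 <- make_ideal_helix(8, jitter = 0.2, seed = 4)
  j2 <- make_ideal_helix(8, jitter = 0.2, seed = 4)
  expect_identical(j1$atoms, j2$atoms)
})

test_that("globular decoys are self-avoiding, compact, connected and reproducible", {
  for (s in 1:10) {
    d <- make_globular_decoy(50, seed = s)
    ca <- as.matrix(d$atoms[d$atoms$atom == "CA", c("x", "y", "z")])
    dm <- as.matrix(dist(ca))
    diag(dm) <- Inf
    expect_gte(min(dm), 3.5)
    expect_lt(mean(apply(dm, 1, min)), 6)  # compact: near neighbours close by
    g <- build_contact_map(d, cutoff = 5)
    comp <- igraph::components(as_igraph(g))
    expect_equal(comp$no, 1)
  }
  a <- make_globular_decoy(30, seed = 7)
  b <- make_globular_decoy(30, seed = 7)
  expect_identical(a$atoms, b$atoms)
  expect_error(make_globular_decoy(1, seed = 1), "n_residues")
})

test_that("screen truth validates its planted configuration", {
  expect_error(screen_truth(error_rate = 0.2), "error_rate")
  expect_error(screen_truth(deleterious = "M7W",
                            compensatory_pairs = list(c("A6V", "I8L"))),
               "no planted deleterious")
  expect_no_error(screen_truth(deleterious = "M7C",
                               compensatory_pairs = list()))
  expect_error(screen_truth(deleterious = "K7W", compensatory_pairs = list()),
               "does not match")

  tr <- screen_truth()
  expect_false(any(tr$deleterious %in% tr$tolerated))
  # default tolerated singles: SNS amino acids over the seven regions
  expect_true(all(grepl("^[A-Z][0-9]+[LPHQRVADEG]$", tr$tolerated)))
})

test_that("noiseless pools place planted variants in the expected pools", {
  tr <- screen_truth(deleterious = "M7W",
                     compensatory_pairs = list(c("M7W", "I12S")),
                     tolerated = c("A6V", "I12S"),
                     depth = 100, comp_depth = 40, enrichment = 2,
                     error_rate = 0, seed = 5)
  pools <- simulate_read_pools(tr)
  tal <- call_pools(pools$wt_reads, pools$mut_reads, hokc_reference())

  g <- tal$genotypes
  expect_identical(g$mut_count[g$genotype == "M7W"], 200)   # depth * enrichment
  expect_identical(g$wt_count[g$genotype == "M7W"], 0)
  expect_identical(g$wt_count[g$genotype == "M7W,I12S"], 40)  # compensated
  expect_identical(g$mut_count[g$genotype == "M7W,I12S"], 0)
  expect_identical(g$wt_count[g$genotype == "A6V"], 100)

  # substitution-level counts aggregate across genotypes
  s <- tal$substitutions
  expect_identical(s$wt_count[s$sub == "M7W"], 40)
  expect_identical(s$mut_count[s$sub == "M7W"], 200)

  # truth table is consistent with the phenotype rule
  tt <- pools$truth_table
  expect_identical(tt$phenotype[tt$genotype == "M7W"], "mutant")
  expect_identical(tt$phenotype[tt$genotype == "M7W,I12S"], "wild_type")
  expect_identical(tt$phenotype[tt$genotype == "WT"], "wild_type")
})

test_that("pool simulation is reproducible and writes valid FASTA", {
  tr <- screen_truth(deleterious = "M7W", compensatory_pairs = list(),
                     tolerated = "A6V", depth = 30, enrichment = 2,
                     error_rate = 0.01, seed = 42)
  p1 <- simulate_read_pools(tr)
  p2 <- simulate_read_pools(tr)
  expect_identical(p1$wt_reads, p2$wt_reads)
  expect_identical(p1$mut_reads, p2$mut_reads)

  dir <- withr::local_tempdir()
  paths <- write_pools(p1, dir)
  expect_true(all(file.exists(paths)))
  rt <- as.character(Biostrings::readDNAStringSet(paths[["wild_type"]]))
  expect_identical(unname(rt), p1$wt_reads)
})

test_that("small noisy screens are recovered end to end", {
  tr <- screen_truth(deleterious = c("M7W", "I12S"),
                     compensatory_pairs = list(c("M7W", "I12S")),
                     tolerated = c("A6V", "L11H", "V24G"),
                     depth = 200, comp_depth = 150, enrichment = 5,
                     error_rate = 0.002, seed = 13)
  pools <- simulate_read_pools(tr)
  tal <- call_pools(pools$wt_reads, pools$mut_reads, hokc_reference(),
                    max_pos = 24)
  an <- screen_analysis(tal, min_total = 50, min_compensatory_count = 50)
  expect_setequal(an$deleterious, tr$deleterious)
  expect_identical(an$compensatory$genotype, "M7W,I12S")
})

test_that("simulated alignments honour their planted truth", {
  ref <- "MKAVLAWIVALK"
  clean <- simulate_msa(msa_truth(ref, n_rows = 10, background = 0, seed = 1))
  expect_true(all(clean$msa$seqs == ref))

  tru <- msa_truth(ref, n_rows = 200, background = 0,
                   correlated = data.frame(pos_i = 2, pos_j = 9, rate = 0.5),
                   seed = 6)
  sim <- simulate_msa(tru)
  m <- do.call(rbind, strsplit(sim$msa$seqs[sim$msa$ids != "REF"], ""))
  co <- m[, 2] != "K" & m[, 9] != "V"
  expect_identical(sum(co), sim$truth_table$co_mutated_rows)
  expect_lt(abs(mean(co) - 0.5), 0.07)  # binomial concentration at n = 200
  # co-substitution is all-or-none at the planted pair
  expect_identical(sum(xor(m[, 2] != "K", m[, 9] != "V")), 0L)

  s1 <- simulate_msa(tru)
  expect_identical(s1$msa$seqs, sim$msa$seqs)

  expect_error(msa_truth(ref, correlated = data.frame(pos_i = 1, pos_j = 99,
                                                      rate = 0.1)),
               "within the reference")
  expect_error(msa_truth(ref, background = 2), "background")
})
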