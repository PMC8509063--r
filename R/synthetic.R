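# run expr with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# cylindrical parameters of an ideal poly-Ala alpha-helix (phi = -57,
# psi = -47): per-atom radius, phase offset (deg) and axial offset (A)
# relative to the CA of the same residue
HELIX_ATOM_PARAMS <- data.frame(
  atom = c("N", "CA", "C", "O", "CB"),
  r    = c(1.565, 2.286, 1.666, 1.905, 3.385),
  dphi = c(-26.40, 0.00, 26.84, 20.56, -16.89),
  dz   = c(-0.927, 0.000, 1.059, 2.250, 0.661))

#' Ideal alpha-helix chain
#'
#' Generates a poly-alanine alpha-helix on a cylinder: 1.5 Angstrom rise
#' and 100 degree twist per residue, with N, CA, C, O and a CB
#' side-chain atom placed at canonical helix radii and phase offsets.
#' Consecutive CA atoms come out ~3.8 Angstrom apart, and at a 5
#' Angstrom any-atom cutoff every (i, i+1), (i, i+3) and (i, i+4) pair
#' is in contact -- the backbone hydrogen-bonding pattern of a real
#' helix.
#'
#' @param n_residues Number of residues (>= 1).
#' @param rise Rise per residue in Angstrom (default 1.5).
#' @param twist Twist per residue in degrees (default 100).
#' @param radius CA helix radius in Angstrom (default 2.286); the other
#'   atom radii are scaled proportionally.
#' @param jitter Standard deviation of seeded Gaussian coordinate noise
#'   in Angstrom (default 0).
#' @param atoms Which atoms to emit (subset of N, CA, C, O, CB).
#' @param aa Residue type (default `"A"`), recycled to length `n_residues`.
#' @param seed Seed for the jitter; required when `jitter > 0`.
#' @return A [structure_chain()].
#' @export
make_ideal_helix <- function(n_residues, rise = 1.5, twist = 100,
                             radius = 2.286, jitter = 0,
                             atoms = c("N", "CA", "C", "O", "CB"),
                             aa = "A", seed = NULL) {
  if (length(n_residues) != 1L || n_residues < 1)
    stop("n_residues must be >= 1")
  p <- HELIX_ATOM_PARAMS[HELIX_ATOM_PARAMS$atom %in% atoms, , drop = FALSE]
  if (nrow(p) == 0L) stop("no valid atom names requested")
  scale <- radius / 2.286
  idx <- rep(seq_len(n_residues), each = nrow(p))
  name <- rep(p$atom, n_residues)
  theta <- (twist * (idx - 1L) + rep(p$dphi, n_residues)) * pi / 180
  r <- rep(p$r, n_residues) * scale
  df <- data.frame(res = idx, atom = name,
                   x = r * cos(theta), y = r * sin(theta),
                   z = rise * (idx - 1L) + rep(p$dz, n_residues))
  if (jitter > 0) {
    if (is.null(seed)) stop("jitter > 0 requires a seed")
    noise <- with_seed(seed, matrix(rnorm(3L * nrow(df), sd = jitter),
                                    ncol = 3L))
    df$x <- df$x + noise[, 1L]; df$y <- df$y + noise[, 2L]
    df$z <- df$z + noise[, 3L]
  }
  structure_chain(id = sprintf("helix_n%d", n_residues),
                  aa = rep_len(aa, n_residues), atoms = df)
}

#' Compact globular decoy chain
#'
#' Generates a compact, self-avoiding chain as a confined random walk:
#' consecutive residues are placed 3.8 Angstrom apart (so the 5 Angstrom
#' contact graph is connected by construction), no two residues come
#' closer than `min_sep`, and the walk is confined to a sphere whose
#' volume allots ~113 cubic Angstrom per residue -- the packing density
#' of folded proteins. Each residue gets a CA and a pseudo side-chain
#' atom 1.5 Angstrom away in a random direction. Deterministic per seed.
#'
#' @param n_residues Number of residues (>= 2).
#' @param seed Integer seed (required).
#' @param min_sep Minimum non-consecutive residue separation in Angstrom
#'   (default 3.5).
#' @param step CA--CA distance of consecutive residues (default 3.8).
#' @param volume_per_residue Confinement volume per residue (default 113).
#' @param aa Residue types; default samples the 20 amino acids uniformly.
#' @param max_restarts Walk restarts before giving up (default 50).
#' @return A [structure_chain()].
#' @export
make_globular_decoy <- function(n_residues, seed, min_sep = 3.5, step = 3.8,
                                volume_per_residue = 113, aa = NULL,
                                max_restarts = 50) {
  if (length(n_residues) != 1L || n_residues < 2) stop("n_residues must be >= 2")
  R <- (3 * n_residues * volume_per_residue / (4 * pi))^(1 / 3)
  with_seed(seed, {
    pts <- NULL
    for (restart in seq_len(max_restarts)) {
      pts <- matrix(runif(3L, -R / 4, R / 4), nrow = 1L)
      ok <- TRUE
      for (k in seq_len(n_residues - 1L)) {
        placed <- FALSE
        for (t in seq_len(500L)) {
          d <- rnorm(3L); d <- d / sqrt(sum(d^2))
          p <- pts[nrow(pts), ] + step * d
          if (sum(p^2) > R^2) next
          if (nrow(pts) > 1L) {
            dd <- sqrt(colSums((t(pts[-nrow(pts), , drop = FALSE]) - p)^2))
            if (min(dd) < min_sep) next
          }
          pts <- rbind(pts, p); placed <- TRUE; break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("decoy generation failed after ", max_restarts, " restarts")
    dirs <- matrix(rnorm(3L * n_residues), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cb <- pts + 1.5 * dirs
    if (is.null(aa)) aa <- sample(AA1, n_residues, replace = TRUE)
    atoms <- data.frame(
      res = rep(seq_len(n_residues), times = 2L),
      atom = rep(c("CA", "CB"), each = n_residues),
      x = c(pts[, 1L], cb[, 1L]), y = c(pts[, 2L], cb[, 2L]),
      z = c(pts[, 3L], cb[, 3L]))
    atoms <- atoms[order(atoms$res, atoms$atom), ]
    structure_chain(id = sprintf("decoy_n%d_s%d", n_residues, seed),
                    aa = rep_len(aa, n_residues), atoms = atoms)
  })
}

#' Write a structure chain as PDB
#'
#' @param chain A [structure_chain()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  aa3 <- bio3d::aa123(chain$aa)
  at <- chain$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[c("x", "y", "z")]))),
                   resno = at$res, resid = aa3[at$res], elety = at$atom,
                   chain = rep("A", nrow(at)))
  invisible(path)
}

# ---------------------------------------------------------------------------
# planted screen truth + read-pool simulator

#' Planted truth for a simulated saturation-mutagenesis screen
#'
#' Defines the ground truth of a simulated pooled screen. The defaults
#' emulate the HokC transmembrane screen: the short-ORF reference, the
#' seven-region tiling, loss-of-function singles and frequent
#' compensatory pairs as observed experimentally, with tolerated singles
#' defaulting to every SNS-reachable substitution in the mutagenised
#' regions. Mutant-phenotype variants grow into colonies and dominate
#' their pool, so deleterious singles are sequenced `enrichment` times
#' deeper than tolerated ones; compensatory genotypes are rare events
#' and get their own (smaller) depth.
#'
#' @param reference A [reference_protein()] with an ORF.
#' @param regions A [region_layout()] of the mutagenised positions.
#' @param deleterious Character vector of planted loss-of-function single
#'   substitutions.
#' @param compensatory_pairs List of character vectors (genotypes of >= 2
#'   substitutions, each containing >= 1 planted deleterious single)
#'   that show the wild-type phenotype.
#' @param tolerated Planted tolerated singles; `NULL` (default) takes
#'   every SNS-encodable substitution in the regions not planted as
#'   deleterious.
#' @param depth Reads per tolerated variant (default 500).
#' @param comp_depth Reads per compensatory genotype (default 250).
#' @param enrichment Depth multiplier for deleterious singles in the
#'   mutant pool (default 10).
#' @param error_rate Per-base sequencing error rate in \[0, 0.05\]
#'   (default 0.005).
#' @param seed Integer seed.
#' @return Object of class `"screen_truth"`.
#' @export
screen_truth <- function(reference = hokc_reference(),
                         regions = hokc_regions(),
                         deleterious = c("M7W", "L11P", "I12S", "I12C",
                                         "I14S", "V19G", "A22T"),
                         compensatory_pairs = list(
                           c("M7W", "I12S"), c("I12S", "I14S"),
                           c("L11P", "I12S"), c("M7W", "I12C"),
                           c("M7W", "I14S"), c("M7W", "L11P"),
                           c("I12S", "V19G"), c("I12S", "A22T")),
                         tolerated = NULL, depth = 500, comp_depth = 250,
                         enrichment = 10, error_rate = 0.005, seed = 1) {
  stopifnot(inherits(reference, "reference_protein"),
            !is.null(reference$orf_sequence))
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  refaa <- strsplit(reference$aa_sequence, "")[[1]]
  check_sub <- function(s) {
    g <- parse_genotype(s)
    if (any(refaa[g$position] != g$ref))
      stop("substitution ", s, " does not match the reference sequence")
  }
  lapply(deleterious, check_sub)
  for (p in compensatory_pairs) {
    if (length(p) < 2L) stop("compensatory genotypes need >= 2 substitutions")
    if (!any(p %in% deleterious))
      stop("compensatory genotype ", format_genotype(p),
           " contains no planted deleterious single")
    lapply(p, check_sub)
  }
  if (is.null(tolerated)) {
    sns <- encoded_amino_acids(degenerate_scheme("SNS"))$amino_acids
    pos <- unlist(mapply(seq, regions$start_pos, regions$end_pos,
                         SIMPLIFY = FALSE))
    tolerated <- unlist(lapply(pos, function(p)
      paste0(refaa[p], p, setdiff(sns, refaa[p]))))
    tolerated <- setdiff(tolerated, deleterious)
  } else {
    lapply(tolerated, check_sub)
  }
  structure(list(reference = reference, regions = regions,
                 deleterious = deleterious,
                 compensatory_pairs = compensatory_pairs,
                 tolerated = tolerated, depth = depth,
                 comp_depth = comp_depth, enrichment = enrichment,
                 error_rate = error_rate, seed = seed),
            class = "screen_truth")
}

# pick a codon for an amino acid: prefer an SNS codon, else first in the code
codon_for <- function(aa, code = Biostrings::GENETIC_CODE) {
  cands <- names(code)[code == aa]
  if (length(cands) == 0L) stop("no codon encodes '", aa, "'")
  sns <- cands[grepl("^[GC][ACGT][GC]$", cands)]
  if (length(sns) > 0L) sns[1L] else cands[1L]
}

# ORF of a genotype: swap whole codons of the reference ORF
mutant_orf <- function(genotype, reference) {
  orf <- reference$orf_sequence
  g <- parse_genotype(genotype)
  if (nrow(g) == 0L) return(orf)
  for (k in seq_len(nrow(g))) {
    p <- g$position[k]
    substr(orf, 3L * p - 2L, 3L * p) <- codon_for(g$alt[k])
  }
  orf
}

# phenotype rule: mutant iff some planted deleterious single in the
# genotype is not accompanied by a full planted compensating combination
planted_phenotype <- function(genotype, truth) {
  subs <- genotype_subs(genotype)[[1]]
  dels <- intersect(subs, truth$deleterious)
  if (length(dels) == 0L) return("wild_type")
  uncompensated <- vapply(dels, function(d) {
    !any(vapply(truth$compensatory_pairs, function(p)
      d %in% p && all(p %in% subs), NA))
  }, NA)
  if (any(uncompensated)) "mutant" else "wild_type"
}

#' Simulate phenotype-labelled read pools from planted truth
#'
#' Generates full-ORF reads for the wild type, every planted single and
#' every planted compensatory genotype. Each read is assigned to the
#' mutant pool iff its (pre-error) genotype contains a planted
#' deleterious single not accompanied by its planted compensating
#' partner(s); per-base sequencing errors are then applied at the stated
#' rate, so errors act on the nucleotide sequence but never on the
#' phenotype label -- the mechanism that produces incorrect
#' sequence-phenotype assignments in a real screen.
#'
#' @param truth A [screen_truth()].
#' @return List with `wt_reads` and `mut_reads` (character vectors of
#'   DNA), and `truth_table`, a data frame with one row per generated
#'   genotype (`genotype`, `class`, `phenotype`, `depth`).
#' @seealso [write_pools()] to write the pools as FASTA.
#' @export
simulate_read_pools <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  genos <- data.frame(
    genotype = c("WT", truth$tolerated, truth$deleterious,
                 vapply(truth$compensatory_pairs, format_genotype, "")),
    class = c("wild_type",
              rep("tolerated_single", length(truth$tolerated)),
              rep("deleterious_single", length(truth$deleterious)),
              rep("compensatory", length(truth$compensatory_pairs))))
  genos$phenotype <- vapply(genos$genotype, planted_phenotype, "",
                            truth = truth)
  genos$depth <- ifelse(genos$class == "compensatory", truth$comp_depth,
                        ifelse(genos$phenotype == "mutant",
                               truth$depth * truth$enrichment, truth$depth))
  orfs <- vapply(genos$genotype, mutant_orf, "", reference = truth$reference)
  reads <- rep(orfs, genos$depth)
  phen <- rep(genos$phenotype, genos$depth)
  L <- nchar(truth$reference$orf_sequence)
  with_seed(truth$seed, {
    if (truth$error_rate > 0 && length(reads) > 0L) {
      m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                  nrow = length(reads), byrow = TRUE)
      hit <- which(runif(length(m)) < truth$error_rate)
      if (length(hit) > 0L) {
        bases <- c("A", "C", "G", "T")
        repl <- vapply(m[hit], function(b)
          sample(setdiff(bases, b), 1L), "")
        m[hit] <- repl
        reads <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      }
    }
    reads <- reads  # RNG scope
  })
  list(wt_reads = unname(reads[phen == "wild_type"]),
       mut_reads = unname(reads[phen == "mutant"]),
       truth_table = genos[c("genotype", "class", "phenotype", "depth")])
}

#' Write simulated pools as FASTA
#'
#' @param pools A [simulate_read_pools()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths plus the truth
#'   table TSV.
#' @export
write_pools <- function(pools, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(wild_type = file.path(dir, "pool_wild_type.fasta"),
             mutant = file.path(dir, "pool_mutant.fasta"),
             truth = file.path(dir, "truth_table.tsv"))
  wt <- Biostrings::DNAStringSet(pools$wt_reads)
  names(wt) <- sprintf("wt_read_%06d", seq_along(wt))
  mut <- Biostrings::DNAStringSet(pools$mut_reads)
  names(mut) <- sprintf("mut_read_%06d", seq_along(mut))
  Biostrings::writeXStringSet(wt, paths[["wild_type"]])
  Biostrings::writeXStringSet(mut, paths[["mutant"]])
  write.table(pools$truth_table, paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths
}

# ---------------------------------------------------------------------------
# planted MSA truth + alignment simulator

#' Planted truth for a simulated family alignment
#'
#' @param reference Reference protein ([reference_protein()]) or plain
#'   amino-acid string.
#' @param n_rows Number of homolog rows to draw (default 148, the size
#'   of the HokC family alignment).
#' @param background Per-column background substitution rate in \[0, 1\]
#'   (default 0.05).
#' @param correlated Data frame with columns `pos_i`, `pos_j`, `rate`:
#'   pairs of positions that co-substitute (both or neither) at the
#'   given per-row rate. Correlated positions are exempt from background
#'   substitution so the planted signal is clean.
#' @param gap_rate Per-cell gap rate (default 0).
#' @param seed Integer seed.
#' @return Object of class `"msa_truth"`.
#' @export
msa_truth <- function(reference, n_rows = 148, background = 0.05,
                      correlated = NULL, gap_rate = 0, seed = 1) {
  aa <- if (inherits(reference, "reference_protein"))
    reference$aa_sequence else toupper(reference)
  L <- nchar(aa)
  if (is.null(correlated))
    correlated <- data.frame(pos_i = integer(), pos_j = integer(),
                             rate = numeric())
  stopifnot(all(c("pos_i", "pos_j", "rate") %in% names(correlated)),
            background >= 0, background <= 1, gap_rate >= 0, gap_rate < 1,
            n_rows >= 1)
  if (nrow(correlated) > 0L) {
    if (any(correlated$pos_i < 1 | correlated$pos_j < 1 |
              correlated$pos_i > L | correlated$pos_j > L))
      stop("correlated positions must lie within the reference length ", L)
    if (any(correlated$rate < 0 | correlated$rate > 1))
      stop("co-mutation rates must lie in [0, 1]")
  }
  structure(list(reference = aa, n_rows = n_rows, background = background,
                 correlated = correlated, gap_rate = gap_rate, seed = seed),
            class = "msa_truth")
}

#' Simulate a family alignment with planted correlated substitutions
#'
#' Rows are drawn independently of one another. Every background column
#' substitutes to a random non-reference residue at the background rate;
#' each planted correlated pair co-substitutes -- both positions or
#' neither -- at its stated rate. The reference row is included as the
#' first row.
#'
#' @param truth An [msa_truth()].
#' @return List with `msa` (a [protein_msa()], reference row `"REF"`) and
#'   `truth_table` (data frame: per correlated pair, the realised number
#'   of co-mutated rows).
#' @export
simulate_msa <- function(truth) {
  stopifnot(inherits(truth, "msa_truth"))
  ref <- strsplit(truth$reference, "")[[1]]
  L <- length(ref)
  n <- truth$n_rows
  corr_pos <- unique(c(truth$correlated$pos_i, truth$correlated$pos_j))
  with_seed(truth$seed, {
    m <- matrix(rep(ref, each = n), nrow = n)
    bg_cols <- setdiff(seq_len(L), corr_pos)
    for (p in bg_cols) {
      hit <- which(runif(n) < truth$background)
      if (length(hit) > 0L)
        m[hit, p] <- sample(setdiff(AA1, ref[p]), length(hit), replace = TRUE)
    }
    realized <- integer(nrow(truth$correlated))
    if (nrow(truth$correlated) > 0L)
      for (k in seq_len(nrow(truth$correlated))) {
        i <- truth$correlated$pos_i[k]; j <- truth$correlated$pos_j[k]
        hit <- which(runif(n) < truth$correlated$rate[k])
        realized[k] <- length(hit)
        if (length(hit) > 0L) {
          m[hit, i] <- sample(setdiff(AA1, ref[i]), length(hit), replace = TRUE)
          m[hit, j] <- sample(setdiff(AA1, ref[j]), length(hit), replace = TRUE)
        }
      }
    if (truth$gap_rate > 0) {
      gap <- which(runif(length(m)) < truth$gap_rate)
      m[gap] <- "-"
    }
    rows <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    seqs <- c(truth$reference, rows)
    names(seqs) <- c("REF", sprintf("hom_%04d", seq_len(n)))
    tt <- truth$correlated
    if (nrow(tt) > 0L) tt$co_mutated_rows <- realized
    list(msa = protein_msa(seqs, "REF"), truth_table = tt)
  })
}
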