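# Independent brute-force oracles used to freeze expected values.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# exhaustive subset enumeration: counts maximal cliques of each size
oracle_clique_profile <- function(adj, sizes = 3:5) {
  n <- nrow(adj)
  counts <- setNames(integer(length(sizes)), sprintf("MC(%d)", sizes))
  for (k in sizes) {
    if (n < k) next
    subs <- combn(n, k)
    pairs <- combn(k, 2)
    is_clique <- rep(TRUE, ncol(subs))
    for (p in seq_len(ncol(pairs)))
      is_clique <- is_clique &
        adj[cbind(subs[pairs[1, p], ], subs[pairs[2, p], ])]
    n_max <- 0L
    for (ci in which(is_clique)) {
      s <- subs[, ci]
      ext <- setdiff(seq_len(n), s)
      extendable <- length(ext) > 0L &&
        any(colSums(adj[s, ext, drop = FALSE]) == k)
      if (!extendable) n_max <- n_max + 1L
    }
    counts[sprintf("MC(%d)", k)] <- n_max
  }
  counts
}

adjacency_matrix <- function(graph) {
  a <- matrix(FALSE, graph$n, graph$n)
  if (nrow(graph$edges) > 0L) {
    a[cbind(graph$edges$i, graph$edges$j)] <- TRUE
    a[cbind(graph$edges$j, graph$edges$i)] <- TRUE
  }
  a
}

random_contact_graph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- combn(n, 2)
  keep <- runif(ncol(pairs)) < p
  contact_graph(n, data.frame(i = pairs[1, keep], j = pairs[2, keep]))
}

# O(n^2) all-pairs min atom distance oracle
oracle_contact_edges <- function(chain, cutoff = 5) {
  xyz <- as.matrix(chain$atoms[c("x", "y", "z")])
  res <- chain$atoms$res
  out <- NULL
  for (i in seq_len(chain$n_residues - 1L))
    for (j in seq((i + 1L), chain$n_residues)) {
      ai <- xyz[res == i, , drop = FALSE]
      aj <- xyz[res == j, , drop = FALSE]
      dmin <- Inf
      for (r in seq_len(nrow(ai)))
        dmin <- min(dmin, sqrt(colSums((t(aj) - ai[r, ])^2)))
      if (dmin < cutoff) out <- rbind(out, c(i, j))
    }
  out
}

# truncated-Euclidean vector metric + max-min Hausdorff, written directly
oracle_vdist <- function(v, w) {
  n <- min(length(v), length(w))
  sqrt(sum((v[seq_len(n)] - w[seq_len(n)])^2))
}
oracle_hausdorff <- function(A, B, offset = 0) {
  va <- A$vectors; vb <- lapply(B$vectors, function(v) v + offset)
  dab <- max(vapply(va, function(v)
    min(vapply(vb, function(w) oracle_vdist(v, w), 0)), 0))
  dba <- max(vapply(vb, function(w)
    min(vapply(va, function(v) oracle_vdist(v, w), 0)), 0))
  max(dab, dba)
}
oracle_grid_min_hausdorff <- function(A, B, by = 1) {
  offsets <- seq(-180, 180, by = by)
  min(vapply(offsets, function(d) oracle_hausdorff(A, B, d), 0))
}

# random angle-vector set (canonical descending vectors)
random_angle_set <- function(n_vec, seed, max_len = 6) {
  set.seed(seed)
  vecs <- lapply(seq_len(n_vec), function(i)
    sort(runif(sample(2:max_len, 1), 0, 180), decreasing = TRUE))
  structure(list(id = paste0("rand", seed), n_residues = n_vec,
                 vectors = setNames(vecs, seq_len(n_vec))),
            class = "angle_vector_set")
}

# random proper rotation matrix
random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_chain <- function(chain, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(chain$atoms[c("x", "y", "z")]) %*% t(rot)
  chain$atoms$x <- xyz[, 1] + shift[1]
  chain$atoms$y <- xyz[, 2] + shift[2]
  chain$atoms$z <- xyz[, 3] + shift[3]
  chain
}

# apply a genotype string to an amino-acid sequence
apply_genotype <- function(aa_seq, genotype) {
  g <- parse_genotype(genotype)
  chars <- strsplit(aa_seq, "")[[1]]
  chars[g$position] <- g$alt
  paste(chars, collapse = "")
}

# small worked-example fixture: poly-Ala reference with 30 disjoint
# contacting Ala-Ala pairs and an alignment in which `n_events` rows each
# mutate both residues of one pair
ala_pair_fixture <- function(n_pairs = 30, n_events = 15, n_extra_rows = 5) {
  L <- 2L * n_pairs
  ref <- paste(rep("A", L), collapse = "")
  edges <- data.frame(i = seq(1L, L, 2L), j = seq(2L, L, 2L))
  g <- contact_graph(L, edges, labels = rep("A", L))
  rows <- character(n_events + n_extra_rows)
  for (k in seq_len(n_events)) {
    chars <- rep("A", L)
    chars[c(edges$i[k], edges$j[k])] <- "V"
    rows[k] <- paste(chars, collapse = "")
  }
  for (k in seq_len(n_extra_rows)) rows[n_events + k] <- ref
  seqs <- c(ref, rows)
  names(seqs) <- c("REF", sprintf("row%03d", seq_along(rows)))
  list(msa = protein_msa(seqs, "REF"), contacts = g)
}
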