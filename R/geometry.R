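#' Default hydrophobic residue set
#'
#' Alanine, valine, leucine, isoleucine, methionine, phenylalanine,
#' tryptophan and cysteine.
#' @export
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")

# representative point per residue: side-chain centroid, falling back to
# CA for glycine / side-chain-less residues; NA rows where neither exists
residue_rep_points <- function(chain) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  out <- matrix(NA_real_, nrow = chain$n_residues, ncol = 3)
  at <- chain$atoms
  for (r in seq_len(chain$n_residues)) {
    a <- at[at$res == r, , drop = FALSE]
    side <- a[!a$atom %in% backbone, , drop = FALSE]
    if (nrow(side) > 0L) {
      out[r, ] <- c(mean(side$x), mean(side$y), mean(side$z))
    } else if ("CA" %in% a$atom) {
      ca <- a[a$atom == "CA", , drop = FALSE][1, ]
      out[r, ] <- c(ca$x, ca$y, ca$z)
    }
  }
  out
}

# angle (degrees, [0, 180]) at vertex c subtended by points p and q
vertex_angle <- function(p, c, q) {
  u <- p - c; v <- q - c
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Angle vectors of hydrophobic contact shells
#'
#' Encodes the spatial arrangement of contacting hydrophobic residues:
#' for every hydrophobic residue with at least two hydrophobic contacting
#' neighbours, the vector of angles subtended at the central residue's
#' representative point (side-chain centroid; CA for glycine) by every
#' unordered pair of neighbours. Being built from angles only, the
#' encoding is invariant under rigid-body motion of the chain. Each
#' vector is sorted in descending order for a canonical form.
#'
#' @param chain A [structure_chain()].
#' @param contacts Optional [build_contact_map()] result at the desired
#'   cutoff; built at 5 Angstrom by default.
#' @param hydrophobic Hydrophobic residue set (default [HYDROPHOBIC_AA]).
#' @return Object of class `"angle_vector_set"`: list with `id`,
#'   `n_residues`, and `vectors`, a list (named by central residue index)
#'   of descending numeric angle vectors in degrees.
#' @export
hydrophobic_contact_angles <- function(chain, contacts = NULL,
                                       hydrophobic = HYDROPHOBIC_AA) {
  stopifnot(inherits(chain, "structure_chain"), length(hydrophobic) > 0)
  if (is.null(contacts)) contacts <- build_contact_map(chain, cutoff = 5)
  stopifnot(inherits(contacts, "contact_graph"),
            contacts$n == chain$n_residues)
  rp <- residue_rep_points(chain)
  hydro <- chain$aa %in% hydrophobic
  adj <- lapply(seq_len(contacts$n), function(r)
    sort(c(contacts$edges$j[contacts$edges$i == r],
           contacts$edges$i[contacts$edges$j == r])))
  vectors <- list()
  for (r in which(hydro)) {
    nb <- adj[[r]]
    nb <- nb[hydro[nb] & !is.na(rp[nb, 1L])]
    if (length(nb) < 2L || is.na(rp[r, 1L])) next
    prs <- combn(nb, 2L)
    ang <- vapply(seq_len(ncol(prs)), function(k)
      vertex_angle(rp[prs[1L, k], ], rp[r, ], rp[prs[2L, k], ]), 0)
    vectors[[as.character(r)]] <- sort(ang, decreasing = TRUE)
  }
  structure(list(id = chain$id, n_residues = chain$n_residues,
                 vectors = vectors),
            class = "angle_vector_set")
}

#' @export
print.angle_vector_set <- function(x, ...) {
  cat("Angle vector set", x$id, ":", length(x$vectors),
      "hydrophobic centres (chain of", x$n_residues, "residues)\n")
  invisible(x)
}

# Hausdorff evaluator for a fixed set pair: precomputes padded vector
# matrices and prefix sums so that every offset evaluation is a single
# matrix product. With zero padding, the full dot product of two padded
# vectors equals their dot product over the shorter length, and prefix
# sums of squares give the truncated norms, so
# d^2(i,j) = |a_i|^2_[1:m] + |b_j + offset|^2_[1:m] - 2 <a_i, b_j + offset>
# with m = min(len_i, len_j) ("truncate") or the common padded length
# ("pad").
hausdorff_engine <- function(A, B, method = "truncate") {
  va <- A$vectors; vb <- B$vectors
  na <- length(va); nb <- length(vb)
  la <- lengths(va); lb <- lengths(vb)
  L <- max(la, lb)
  pad0 <- function(v) c(v, rep(0, L - length(v)))
  Am <- do.call(rbind, lapply(va, pad0))
  Bm <- do.call(rbind, lapply(vb, pad0))
  maskB <- do.call(rbind, lapply(vb, function(v)
    rep(c(1, 0), c(length(v), L - length(v)))))
  SA <- t(apply(Am^2, 1L, cumsum))
  if (L == 1L) SA <- matrix(Am^2, ncol = 1L)
  m_idx <- if (method == "truncate") outer(la, lb, pmin) else
    matrix(L, na, nb)
  ia <- rep(seq_len(na), times = nb)
  jb <- rep(seq_len(nb), each = na)
  function(offset = 0) {
    Bo <- Bm + offset * maskB
    SB <- t(apply(Bo^2, 1L, cumsum))
    if (L == 1L) SB <- matrix(Bo^2, ncol = 1L)
    d2 <- SA[cbind(ia, as.vector(m_idx))] +
      SB[cbind(jb, as.vector(m_idx))] -
      2 * as.vector(Am %*% t(Bo))
    d <- matrix(sqrt(pmax(d2, 0)), na, nb)
    row_min <- do.call(pmin, as.data.frame(d))
    col_min <- do.call(pmin, as.data.frame(t(d)))
    max(max(row_min), max(col_min))
  }
}

#' Hausdorff distance between two angle vector sets
#'
#' Classical symmetric Hausdorff distance: the larger of the two directed
#' distances `max over one set of the min distance to the other`, taken
#' over all vector pairs under an elementwise Euclidean metric (vectors
#' of unequal length are truncated to the shorter length by default, or
#' zero-padded with `method = "pad"`).
#'
#' @param A,B [hydrophobic_contact_angles()] results (non-empty).
#' @param method `"truncate"` (default) or `"pad"`.
#' @return Non-negative scalar distance (degrees).
#' @export
hausdorff_distance <- function(A, B, method = c("truncate", "pad")) {
  method <- match.arg(method)
  if (length(A$vectors) == 0L || length(B$vectors) == 0L)
    stop("Hausdorff distance is undefined for empty vector sets")
  hausdorff_engine(A, B, method)(0)
}

#' Minimum Hausdorff distance under a global angular offset
#'
#' Minimises the Hausdorff distance between two angle vector sets over a
#' global angular offset added to every angle of the second set -- the
#' one-parameter relative-orientation family. The search combines
#' seeded simulated annealing (Metropolis acceptance, geometric cooling)
#' started at the identity (offset 0) with a final local refinement
#' around the best state; the identity is always evaluated, so the
#' result never exceeds the unminimised distance.
#'
#' @param A,B [hydrophobic_contact_angles()] results.
#' @param t0 Initial annealing temperature (default 100).
#' @param cooling Geometric cooling factor per step (default 0.95).
#' @param steps Number of annealing steps (default 500).
#' @param offset_range Half-width of the searched offset interval in
#'   degrees (default 180).
#' @param coarse_step Spacing in degrees of the deterministic coarse scan
#'   that seeds the annealer (default 2).
#' @param method Vector metric, as in [hausdorff_distance()].
#' @param seed Integer seed for the annealing proposals; the caller's RNG
#'   state is preserved.
#' @return List with `distance`, `offset` (degrees) and `raw` (the
#'   unminimised distance).
#' @export
min_hausdorff <- function(A, B, t0 = 100, cooling = 0.95, steps = 500,
                          offset_range = 180, coarse_step = 2,
                          method = c("truncate", "pad"), seed = NULL) {
  method <- match.arg(method)
  if (t0 <= 0 || cooling <= 0 || cooling >= 1 || steps < 1 || coarse_step <= 0)
    stop("invalid annealing schedule (need t0 > 0, 0 < cooling < 1, steps >= 1)")
  if (length(A$vectors) == 0L || length(B$vectors) == 0L)
    stop("Hausdorff distance is undefined for empty vector sets")
  obj <- hausdorff_engine(A, B, method)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  raw <- obj(0)
  # deterministic coarse scan seeds the stochastic search
  grid <- seq(-offset_range, offset_range, by = coarse_step)
  grid_v <- vapply(grid, obj, 0)
  best <- grid[which.min(grid_v)]; best_v <- min(grid_v)
  cur <- best; cur_v <- best_v
  temp <- t0
  for (s in seq_len(steps)) {
    prop <- cur + rnorm(1L, sd = coarse_step * (0.2 + temp / t0))
    prop <- ((prop + offset_range) %% (2 * offset_range)) - offset_range
    v <- obj(prop)
    if (v < cur_v || runif(1L) < exp((cur_v - v) / temp)) {
      cur <- prop; cur_v <- v
      if (v < best_v) { best <- prop; best_v <- v }
    }
    temp <- temp * cooling
  }
  ref <- optimize(obj, c(best - coarse_step, best + coarse_step), tol = 1e-9)
  if (ref$objective < best_v) { best <- ref$minimum; best_v <- ref$objective }
  if (raw <= best_v) { best <- 0; best_v <- raw }  # identity always included
  list(distance = best_v, offset = best, raw = raw)
}

#' Pairwise geometry comparison of a structure cohort
#'
#' Compares the hydrophobic contact geometry of every within-class pair
#' of proteins: only pairs sharing a CATH class label and differing in
#' length by at most `max_len_diff` residues are compared. For each pair
#' the raw and the offset-minimised Hausdorff distance are reported; a
#' pair with minimised distance at or below `tolerance` counts as having
#' identical orientation of its contacting hydrophobic residues.
#'
#' @param sets Named list of [hydrophobic_contact_angles()] results.
#' @param cath Character vector of CATH class labels, parallel to `sets`
#'   (or named by the same names).
#' @param max_len_diff Maximum residue-count difference (default 20,
#'   inclusive).
#' @param tolerance Identical-orientation threshold in degrees (default 1).
#' @param seed Base seed; pair `k` uses `seed + k` for its annealing.
#' @param ... Further arguments passed to [min_hausdorff()].
#' @return Object of class `"cohort_comparison"`: list with `pairs` (data
#'   frame `a`, `b`, `cath_class`, `raw_hausdorff`, `min_hausdorff`,
#'   `identical`) and `by_class` (per-class `n_pairs`, `median`, `min`,
#'   `max` of the minimised distances and `frac_identical`).
#' @export
compare_cohort <- function(sets, cath, max_len_diff = 20, tolerance = 1,
                           seed = 1, ...) {
  stopifnot(length(sets) >= 2, length(cath) == length(sets))
  ids <- names(sets)
  if (is.null(ids)) ids <- paste0("P", seq_along(sets))
  if (!is.null(names(cath))) cath <- cath[ids]
  lens <- vapply(sets, function(s) s$n_residues, 0)
  rows <- list(); k <- 0L
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (j <= i) next
    if (cath[i] != cath[j]) next
    if (abs(lens[i] - lens[j]) > max_len_diff) next
    k <- k + 1L
    mh <- min_hausdorff(sets[[i]], sets[[j]], seed = seed + k, ...)
    rows[[k]] <- data.frame(a = ids[i], b = ids[j], cath_class = cath[i],
                            raw_hausdorff = mh$raw,
                            min_hausdorff = mh$distance,
                            identical = mh$distance <= tolerance)
  }
  pairs <- if (k > 0L) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), cath_class = character(),
               raw_hausdorff = numeric(), min_hausdorff = numeric(),
               identical = logical())
  by_class <- if (k > 0L) {
    sp <- split(pairs, pairs$cath_class)
    do.call(rbind, lapply(sp, function(p) data.frame(
      cath_class = p$cath_class[1], n_pairs = nrow(p),
      median = median(p$min_hausdorff), min = min(p$min_hausdorff),
      max = max(p$min_hausdorff), frac_identical = mean(p$identical))))
  } else data.frame()
  rownames(by_class) <- NULL
  structure(list(pairs = pairs, by_class = by_class,
                 tolerance = tolerance, max_len_diff = max_len_diff),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Cohort geometry comparison:", nrow(x$pairs), "within-class pairs",
      "(length difference <=", x$max_len_diff, ")\n")
  if (nrow(x$by_class) > 0L) print(x$by_class, row.names = FALSE)
  invisible(x)
}
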