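#' Structure chain
#'
#' A single protein chain as an ordered list of residues (re-indexed
#' 1..n) with labelled atom coordinates in Angstrom.
#'
#' @param id Chain identifier (e.g. `"1abc_A"`).
#' @param aa Character vector of one-letter residue types (length n).
#' @param atoms Data frame with columns `res` (residue index, 1..n),
#'   `atom` (atom name, e.g. `"CA"`), `x`, `y`, `z`.
#' @return Object of class `"structure_chain"` with elements `id`, `aa`,
#'   `atoms` and `n_residues`.
#' @export
structure_chain <- function(id, aa, atoms) {
  aa <- as.character(aa)
  n <- length(aa)
  if (n < 1L) stop("chain must contain at least one residue")
  stopifnot(is.data.frame(atoms),
            all(c("res", "atom", "x", "y", "z") %in% names(atoms)))
  if (!all(atoms$res %in% seq_len(n)))
    stop("atom residue indices must lie in 1..", n)
  if (!all(seq_len(n) %in% atoms$res))
    stop("every residue needs at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  structure(list(id = id, aa = aa,
                 atoms = atoms[c("res", "atom", "x", "y", "z")],
                 n_residues = n),
            class = "structure_chain")
}

#' @export
print.structure_chain <- function(x, ...) {
  cat("Structure chain", x$id, ":", x$n_residues, "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Read one chain from a PDB or mmCIF file
#'
#' Thin wrapper around bio3d. Keeps `ATOM` records of the requested
#' chain, takes the first alternate-location conformer, optionally drops
#' hydrogens, and re-indexes residues 1..n in file order (missing
#' residues are simply skipped).
#'
#' @param path Path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param chain Chain identifier; defaults to the first chain present.
#' @param heavy_only Drop hydrogen atoms (default TRUE; deposited crystal
#'   structures usually lack them anyway).
#' @return A [structure_chain()].
#' @export
read_structure_chain <- function(path, chain = NULL, heavy_only = TRUE) {
  pdb <- if (grepl("\\.cif$", path)) bio3d::read.cif(path) else
    bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain '", chain, "'")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (heavy_only && "elesy" %in% names(at))
    at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  key <- paste(at$resno, at$insert)
  res <- match(key, unique(key))
  aa3 <- at$resid[!duplicated(res)]
  aa1 <- suppressWarnings(bio3d::aa321(aa3))
  aa1[is.na(aa1) | !aa1 %in% AA1] <- "X"
  structure_chain(id = paste0(basename(path), "_", chain),
                  aa = aa1,
                  atoms = data.frame(res = res, atom = at$elety,
                                     x = at$x, y = at$y, z = at$z))
}

#' Residue contact graph
#'
#' Simple undirected graph over residue indices; an edge joins two
#' residues whose closest atom pair lies strictly below the distance
#' cutoff.
#'
#' @param n Number of residues (nodes).
#' @param edges Data frame with columns `i`, `j` (1-based residue
#'   indices) and optionally `min_dist`.
#' @param labels Character vector of amino-acid labels (length `n`),
#'   optional.
#' @param cutoff Distance cutoff in Angstrom used to build the graph
#'   (bookkeeping only).
#' @return Object of class `"contact_graph"`.
#' @export
contact_graph <- function(n, edges, labels = NULL, cutoff = NA_real_) {
  stopifnot(n >= 1, is.data.frame(edges), all(c("i", "j") %in% names(edges)))
  i <- pmin(edges$i, edges$j); j <- pmax(edges$i, edges$j)
  if (any(i == j)) stop("self-loops are not allowed")
  if (any(i < 1L | j > n)) stop("edge endpoints must lie in 1..", n)
  o <- order(i, j)
  edges <- data.frame(i = i[o], j = j[o],
                      min_dist = if ("min_dist" %in% names(edges))
                        edges$min_dist[o] else rep(NA_real_, length(o)))
  if (anyDuplicated(paste(edges$i, edges$j))) stop("duplicate edges")
  if (!is.null(labels)) stopifnot(length(labels) == n)
  structure(list(n = as.integer(n), edges = edges, labels = labels,
                 cutoff = cutoff),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("Contact graph: size", x$n, "order", nrow(x$edges))
  if (!is.na(x$cutoff)) cat(" (cutoff", x$cutoff, "A)")
  cat("\n")
  invisible(x)
}

#' Build a residue contact map from a structure chain
#'
#' Residues i and j (i != j) are in contact when any atom of i lies
#' strictly closer than `cutoff` to any atom of j. Sequence-adjacent
#' pairs are included by default; `min_seq_sep` > 1 excludes short-range
#' pairs.
#'
#' @param chain A [structure_chain()].
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @param min_seq_sep Minimum sequence separation `|i - j|` for an edge
#'   (default 1 = all pairs).
#' @return A [contact_graph()] with per-edge minimum atom distances.
#' @export
build_contact_map <- function(chain, cutoff = 5, min_seq_sep = 1) {
  stopifnot(inherits(chain, "structure_chain"), cutoff > 0, min_seq_sep >= 1)
  xyz <- as.matrix(chain$atoms[c("x", "y", "z")])
  res <- chain$atoms$res
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  ri <- res[hit[, 1L]]; rj <- res[hit[, 2L]]
  keep <- abs(ri - rj) >= min_seq_sep
  if (any(keep)) {
    i <- pmin(ri[keep], rj[keep]); j <- pmax(ri[keep], rj[keep])
    dmin <- tapply(d[hit[keep, , drop = FALSE]], paste(i, j), min)
    ij <- do.call(rbind, lapply(strsplit(names(dmin), " "), as.integer))
    edges <- data.frame(i = ij[, 1L], j = ij[, 2L],
                        min_dist = as.numeric(dmin))
  } else {
    edges <- data.frame(i = integer(), j = integer(), min_dist = numeric())
  }
  contact_graph(chain$n_residues, edges, labels = chain$aa, cutoff = cutoff)
}

#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @rdname as_igraph
#' @param x A [contact_graph()].
#' @param ... Unused.
#' @return An igraph graph with `n` vertices.
#' @export
as_igraph.contact_graph <- function(x, ...) {
  g <- igraph::make_empty_graph(n = x$n, directed = FALSE)
  if (nrow(x$edges) > 0L)
    g <- igraph::add_edges(g, rbind(x$edges$i, x$edges$j))
  g
}

#' Size and order of a contact graph
#'
#' Size is the number of residues (nodes), order the number of contacts
#' (edges); `2 * order / size` is the mean number of contacts per
#' residue, the packing-density statistic.
#'
#' @param graph A [contact_graph()].
#' @return Named numeric vector `c(size = , order = )`.
#' @export
size_order <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  c(size = graph$n, order = nrow(graph$edges))
}

#' @rdname size_order
#' @return `contacts_per_residue()`: the scalar `2 * order / size`.
#' @export
contacts_per_residue <- function(graph) {
  so <- size_order(graph)
  unname(2 * so["order"] / so["size"])
}

#' Linear size-versus-order packing fit
#'
#' Ordinary least-squares fit of contact-map order (edge count) against
#' size (residue count) across a set of chains; under constant packing
#' density the points fall on a line whose slope is the number of
#' contacts gained per added residue.
#'
#' @param points Data frame with columns `size` and `order` (one row per
#'   chain), or a list of [contact_graph()]s.
#' @return List of class `"packing_fit"`: `slope`, `intercept`,
#'   `residual` (residual standard error), `r_squared`, `n`, and
#'   `mean_contacts_per_residue` (mean of `2 * order / size`).
#' @export
fit_packing_line <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- as.data.frame(t(vapply(points, size_order, c(size = 0, order = 0))))
  stopifnot(all(c("size", "order") %in% names(points)))
  if (length(unique(points$size)) < 2L)
    stop("degenerate fit: need at least two distinct sizes")
  fit <- lm(order ~ size, data = points)
  s <- suppressWarnings(summary(fit))  # exact-line fixtures fit perfectly
  structure(list(slope = unname(coef(fit)["size"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 residual = s$sigma, r_squared = s$r.squared,
                 n = nrow(points),
                 mean_contacts_per_residue =
                   mean(2 * points$order / points$size)),
            class = "packing_fit")
}

#' @export
print.packing_fit <- function(x, ...) {
  cat(sprintf("Packing fit over %d chains: order = %.3f * size %+.2f\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  residual SE %.2f, R^2 %.4f, mean contacts/residue %.3f\n",
              x$residual, x$r_squared, x$mean_contacts_per_residue))
  invisible(x)
}

#' Maximal-clique packing profile
#'
#' Counts the maximal cliques (cliques not contained in any larger
#' clique) of the requested sizes, enumerated with igraph's pivoting
#' Bron--Kerbosch algorithm; maximal cliques larger than the largest
#' requested size are counted separately for diagnostics.
#'
#' @param graph A [contact_graph()] or igraph graph.
#' @param sizes Clique sizes to profile (default 3:5).
#' @return Named integer vector of class `"clique_profile"` (names
#'   `"MC(3)"` etc.), with attribute `"larger"` counting maximal cliques
#'   above `max(sizes)`.
#' @export
maximal_cliques_by_size <- function(graph, sizes = 3:5) {
  g <- if (inherits(graph, "contact_graph")) as_igraph(graph) else graph
  cl <- igraph::max_cliques(g, min = 1)
  len <- lengths(cl)
  counts <- vapply(sizes, function(s) sum(len == s), 0L)
  structure(setNames(counts, sprintf("MC(%d)", sizes)),
            larger = sum(len > max(sizes)),
            class = "clique_profile")
}

#' @export
print.clique_profile <- function(x, ...) {
  print(setNames(as.integer(x), names(x)))
  if (attr(x, "larger") > 0L)
    cat("  (+", attr(x, "larger"), "maximal cliques above the profiled sizes)\n")
  invisible(x)
}

#' Per-chain packing summary table
#'
#' @param chains List of [structure_chain()]s (or ready-made
#'   [contact_graph()]s).
#' @param cutoff Contact cutoff in Angstrom.
#' @param sizes Clique sizes to profile.
#' @return Data frame with one row per chain: `id`, `size`, `order`,
#'   `contacts_per_residue` and one `MC(k)` column per requested size.
#' @export
pack_profile <- function(chains, cutoff = 5, sizes = 3:5) {
  rows <- lapply(chains, function(ch) {
    g <- if (inherits(ch, "contact_graph")) ch else
      build_contact_map(ch, cutoff = cutoff)
    so <- size_order(g)
    mc <- maximal_cliques_by_size(g, sizes)
    cbind(data.frame(id = if (inherits(ch, "structure_chain")) ch$id else NA,
                     size = so[["size"]], order = so[["order"]],
                     contacts_per_residue = contacts_per_residue(g)),
          as.data.frame(as.list(setNames(as.integer(mc),
                                         paste0("MC", sizes)))))
  })
  do.call(rbind, rows)
}
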