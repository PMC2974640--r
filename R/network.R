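#' Construct an undirected network
#'
#' A network is the model-selection object of the package: a simple undirected
#' graph on `p` nodes indexed `1..p`. Edges are stored as an integer matrix
#' with two columns, each row an unordered pair written with the smaller index
#' first; rows are kept in lexicographic order so that two networks with the
#' same edge set compare identical.
#'
#' @param p Number of nodes (positive integer, at least 1).
#' @param edges Edge set: a matrix (or data.frame) with two columns of node
#'   indices, or `NULL` for the empty network. Self-loops and duplicated pairs
#'   are rejected.
#' @return An object of class `sfggm_network` with fields `p` and `edges`.
#' @examples
#' g <- network(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
#' degree_sequence(g)
#' @export
network <- function(p, edges = NULL) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 1L)
    stop("'p' must be a single positive integer")
  edges <- canonical_edges(edges, p)
  structure(list(p = p, edges = edges), class = "sfggm_network")
}

canonical_edges <- function(edges, p) {
  if (is.null(edges) || NROW(edges) == 0L)
    return(matrix(integer(0), 0L, 2L))
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "integer"
  if (anyNA(edges) || any(edges < 1L) || any(edges > p))
    stop("edge endpoints must lie in 1..p")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L)]
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  if (anyDuplicated(edges)) stop("duplicated edges are not allowed")
  dimnames(edges) <- NULL
  edges
}

#' @export
print.sfggm_network <- function(x, ...) {
  cat(sprintf("<sfggm_network> p = %d, |E| = %d\n", x$p, nrow(x$edges)))
  invisible(x)
}

is_network <- function(x) inherits(x, "sfggm_network")

stopifnot_network <- function(g) {
  if (!is_network(g)) stop("expected an 'sfggm_network' object")
  invisible(g)
}

#' Number of edges and possible edges
#'
#' @param g A network.
#' @return `n_edges`: the edge count; `max_edges`: M = p(p-1)/2.
#' @export
n_edges <- function(g) {
  stopifnot_network(g)
  nrow(g$edges)
}

#' @rdname n_edges
#' @export
max_edges <- function(g) {
  p <- if (is_network(g)) g$p else as.integer(g)
  as.integer(p * (p - 1L) / 2L)
}

#' Dense adjacency matrix of a network
#'
#' @param g A network.
#' @return A p x p logical matrix, symmetric with `FALSE` diagonal.
#' @export
adjacency_matrix <- function(g) {
  stopifnot_network(g)
  A <- matrix(FALSE, g$p, g$p)
  if (nrow(g$edges)) {
    A[g$edges] <- TRUE
    A[g$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  A
}

adjacency_to_network <- function(A) {
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  network(nrow(A), idx)
}

#' @rdname adjacency_matrix
#' @param i,j Node indices.
#' @return `has_edge`: `TRUE` when \{i, j\} is an edge.
#' @export
has_edge <- function(g, i, j) {
  stopifnot_network(g)
  if (i == j) return(FALSE)
  a <- min(i, j); b <- max(i, j)
  any(g$edges[, 1L] == a & g$edges[, 2L] == b)
}

#' Degree sequence
#'
#' Entry v counts the edges incident on node v; the sum over nodes is twice
#' the edge count.
#'
#' @param g A network.
#' @return Integer vector of length p.
#' @export
degree_sequence <- function(g) {
  stopifnot_network(g)
  tabulate(g$edges, nbins = g$p)
}

## ---- chordality / clique decomposition ------------------------------------

## Maximum cardinality search on a logical adjacency matrix. Ties are broken
## by lowest node index (which.max picks the first maximum) so the visit
## order, and hence the clique ordering, is deterministic.
mcs_order <- function(A) {
  p <- nrow(A)
  wt <- integer(p)
  ord <- integer(p)
  placed <- logical(p)
  for (i in seq_len(p)) {
    cand <- which(!placed)
    v <- cand[which.max(wt[cand])]
    ord[i] <- v
    placed[v] <- TRUE
    nb <- A[, v] & !placed
    wt[nb] <- wt[nb] + 1L
  }
  ord
}

## Zero-fill-in check for an MCS visit order: for each vertex, its earlier
## neighbours minus the latest of them must be adjacent to that latest one.
## Succeeds for every MCS order iff the graph is chordal.
chordal_given_order <- function(A, ord) {
  p <- length(ord)
  if (p < 4L) return(TRUE)
  pos <- integer(p)
  pos[ord] <- seq_len(p)
  for (i in 2:p) {
    v <- ord[i]
    earlier <- which(A[, v])
    earlier <- earlier[pos[earlier] < i]
    if (length(earlier) > 1L) {
      u <- earlier[which.max(pos[earlier])]
      rest <- earlier[earlier != u]
      if (!all(A[rest, u])) return(FALSE)
    }
  }
  TRUE
}

is_decomposable_adj <- function(A) {
  chordal_given_order(A, mcs_order(A))
}

#' Test a network for decomposability (chordality)
#'
#' A network is decomposable when every cycle of length four or more has a
#' chord. Decomposability does not require connectivity: the empty network is
#' decomposable. The test runs a maximum cardinality search followed by a
#' zero-fill-in verification of the visit order.
#'
#' @param g A network.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_decomposable(network(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))) # 4-cycle
#' @export
is_decomposable <- function(g) {
  stopifnot_network(g)
  is_decomposable_adj(adjacency_matrix(g))
}

## Maximal cliques of a chordal graph in a perfect ordering, plus separators.
## Candidate cliques are {v} union earlier-neighbours(v) along the MCS order;
## the maximal ones are kept (subset filtering via crossprod) in discovery
## order, which satisfies the running-intersection property.
clique_decomposition_adj <- function(A, ord = NULL) {
  p <- nrow(A)
  if (is.null(ord)) ord <- mcs_order(A)
  pos <- integer(p)
  pos[ord] <- seq_len(p)
  Cmat <- matrix(FALSE, p, p)
  for (i in seq_len(p)) {
    v <- ord[i]
    e <- which(A[, v])
    e <- e[pos[e] < i]
    Cmat[c(v, e), i] <- TRUE
  }
  sizes <- colSums(Cmat)
  cross <- crossprod(Cmat)           # |C_i intersect C_j|
  contained <- vapply(seq_len(p), function(i) {
    any(cross[i, -i] == sizes[i])
  }, logical(1))
  keep <- which(!contained)
  cliques <- lapply(keep, function(i) which(Cmat[, i]))
  nk <- length(cliques)
  seps <- vector("list", max(nk - 1L, 0L))
  seen <- logical(p)
  for (k in seq_len(nk)) {
    ck <- cliques[[k]]
    if (k > 1L) seps[[k - 1L]] <- ck[seen[ck]]
    seen[ck] <- TRUE
  }
  list(cliques = cliques, separators = seps)
}

#' Clique/separator decomposition of a decomposable network
#'
#' Returns the maximal cliques in a perfect ordering together with the
#' separators S_k = C_k intersected with the union of the earlier cliques.
#' The ordering is deterministic: maximum cardinality search with ties broken
#' by lowest node index. Isolated nodes appear as singleton cliques, so the
#' empty network on p nodes decomposes into p singletons with empty
#' separators.
#'
#' @param g A decomposable network; non-decomposable input is an error.
#' @return A list with `cliques` (list of increasing integer vectors) and
#'   `separators` (list of length `length(cliques) - 1`).
#' @export
clique_decomposition <- function(g) {
  stopifnot_network(g)
  A <- adjacency_matrix(g)
  ord <- mcs_order(A)
  if (!chordal_given_order(A, ord))
    stop("network is not decomposable; no clique/separator factorization exists")
  clique_decomposition_adj(A, ord)
}

## ---- node labelings -------------------------------------------------------

#' Node labelings
#'
#' A node labeling is a permutation `pi` of `1..p`: `pi[v]` is the integer
#' label carried by node `v`. Labels index the Zipf weights of the static
#' model, so label 1 marks the node the scale-free prior expects to be the
#' best-connected.
#'
#' @param p Number of nodes.
#' @return `identity_labeling`: the labeling `pi[v] = v`.
#' @export
identity_labeling <- function(p) seq_len(as.integer(p))

check_labeling <- function(pi) {
  p <- length(pi)
  if (!identical(sort(as.integer(pi)), seq_len(p)))
    stop("'pi' must be a permutation of 1..p")
  as.integer(pi)
}

#' @rdname identity_labeling
#' @param pi A labeling (permutation of 1..p).
#' @param k Label in `1..p-1`; the nodes carrying labels `k` and `k + 1`
#'   exchange them.
#' @return `swap_adjacent_labels`: the labeling after the exchange.
#' @export
swap_adjacent_labels <- function(pi, k) {
  pi <- check_labeling(pi)
  p <- length(pi)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k >= p)
    stop("'k' must lie in 1..p-1")
  a <- which(pi == k)
  b <- which(pi == k + 1L)
  pi[a] <- k + 1L
  pi[b] <- k
  pi
}

## ---- edge list / GraphML I/O ----------------------------------------------

#' Read and write networks as edge-list text files
#'
#' The format is one edge per line, "i<TAB>j" with 1-based node indices, and
#' an optional header line `# p=<int>` recording the node count (needed to
#' preserve isolated nodes).
#'
#' @param g A network.
#' @param path File path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot_network(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# p=%d", g$p), con)
  if (nrow(g$edges))
    writeLines(sprintf("%d\t%d", g$edges[, 1L], g$edges[, 2L]), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @param p Node count override when the file has no header.
#' @export
read_edge_list <- function(path, p = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (is.null(p)) {
    m <- regmatches(hdr, regexpr("p=\\d+", hdr))
    if (length(m)) p <- as.integer(sub("p=", "", m[[1L]]))
  }
  edges <- if (length(body)) {
    do.call(rbind, lapply(strsplit(body, "[\t, ]+"), function(x) as.integer(x[1:2])))
  } else NULL
  if (is.null(p)) p <- if (is.null(edges)) 0L else max(edges)
  network(p, edges)
}

#' Convert to igraph / export GraphML
#'
#' @param g A network.
#' @return `as_igraph`: an igraph object with `p` vertices.
#' @export
as_igraph <- function(g) {
  stopifnot_network(g)
  ig <- igraph::make_empty_graph(n = g$p, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

#' @rdname as_igraph
#' @param path Output file.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}
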