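#' Build the euclidean-threshold geometric graph of a point set
#'
#' Undirected, unweighted graph in which particles i and j are linked
#' exactly when their euclidean distance satisfies
#' `d_ij <= r * (1 + tol)`, with a relative tolerance that keeps
#' constructed exact-unit contacts (d = 1) from being dropped by
#' floating-point noise. At r = 1 the result is the contact graph of the hard-disk
#' configuration; node order is the point-set row order, so node 1 is
#' the center particle.
#'
#' @param points a [point_set()].
#' @param r connectivity parameter, in diameters; must be >= 1
#'   (sub-contact radii would disconnect every hard-disk system).
#' @param tol relative edge tolerance (default 1e-9).
#' @return an object of class `geometric_graph`: a list with elements
#'   `points`, `r`, `tol`, `edges` (L x 2 integer matrix, 1-based,
#'   i < j, lexicographically sorted), `graph` (the igraph object) and
#'   `n` (node count). The edge count is `edge_count()`.
#' @seealso [degree_sequence()], [network_summary()], [write_edge_list()]
#' @export
#' @examples
#' g <- build_geometric_graph(generate_hexagonal(7), r = 1)
#' edge_count(g)  # 12
build_geometric_graph <- function(points, r, tol = 1e-9) {
  stopifnot(inherits(points, "point_set"))
  if (!is.numeric(r) || length(r) != 1L || r < 1)
    stop("r must be a single number >= 1")
  edges <- radius_edges_cpp(points$coords, r, tol)
  structure(
    list(points = points, r = r, tol = tol, edges = edges,
         graph = contact_igraph(points$coords, edges),
         n = n_points(points)),
    class = "geometric_graph")
}

#' @export
print.geometric_graph <- function(x, ...) {
  cat(sprintf("<geometric_graph> %s, N = %d, r = %g, L = %d\n",
              x$points$model, x$n, x$r, edge_count(x)))
  invisible(x)
}

#' Number of edges of a geometric graph
#' @param graph a [build_geometric_graph()] result.
#' @return integer edge count L.
#' @export
edge_count <- function(graph) {
  stopifnot(inherits(graph, "geometric_graph"))
  nrow(graph$edges)
}

#' Degree sequence of a geometric graph
#'
#' The degree of node i is its number of incident links; the sequence
#' satisfies the handshake identity `sum(k_i) = 2 L`.
#'
#' @param graph a [build_geometric_graph()] result.
#' @return integer vector of node degrees, in node order.
#' @export
degree_sequence <- function(graph) {
  stopifnot(inherits(graph, "geometric_graph"))
  tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n)
}
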