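#' Degree distribution, mean degree and density
#'
#' `p_k = N_k / N` over the observed degrees, the mean degree
#' `<k> = 2L/N = d (N - 1)`, and the density `d = L / (N(N-1)/2)`.
#'
#' @param graph a [build_geometric_graph()] result.
#' @return a list with `p_k` (data frame, columns `k`, `p_k`, summing to
#'   1), `k_mean`, `density` and `L`.
#' @export
#' @examples
#' degree_distribution(build_geometric_graph(generate_hexagonal(7), 1))
degree_distribution <- function(graph) {
  stopifnot(inherits(graph, "geometric_graph"))
  k <- degree_sequence(graph)
  n <- graph$n
  tab <- table(k)
  p <- data.frame(k = as.integer(names(tab)),
                  p_k = as.numeric(tab) / n)
  list(p_k = p, k_mean = mean(k),
       density = if (n > 1) edge_count(graph) / (n * (n - 1) / 2) else 0,
       L = edge_count(graph))
}

#' Average clustering coefficient
#'
#' `C_i = 2 tau_i / (k_i (k_i - 1))` with `tau_i` the number of
#' triangles through node i; the average is the arithmetic mean over
#' the nodes of degree >= 2 (nodes with fewer than two neighbors are
#' excluded). Returns 0 for a graph with no such nodes.
#'
#' @param graph a [build_geometric_graph()] result.
#' @return the mean clustering coefficient, in `[0, 1]`.
#' @export
mean_clustering <- function(graph) {
  stopifnot(inherits(graph, "geometric_graph"))
  k <- degree_sequence(graph)
  if (!any(k >= 2L)) return(0)
  ci <- igraph::transitivity(graph$graph, type = "local", isolates = "NaN")
  mean(ci[k >= 2L])
}

#' Average shortest-path length and global efficiency
#'
#' Path lengths are hop counts (minimum number of links), never
#' euclidean lengths. Exact mode runs one BFS per node and returns
#' `<l> = mean over connected ordered pairs of l_ij` and
#' `<E> = (1/(N(N-1))) * sum over ordered pairs of 1/l_ij`, with
#' disconnected pairs contributing efficiency 0 and being excluded from
#' the `<l>` average (their count is reported). Sampled mode runs BFS
#' from a seeded uniform subset of sources and reports the standard
#' error of the per-source means.
#'
#' @param graph a [build_geometric_graph()] result.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_sources number of BFS sources in sampled mode.
#' @param seed RNG seed for the source sample.
#' @param chunk number of BFS sources processed per distance-matrix
#'   block (memory/time trade-off; results are identical).
#' @return a list with `l_mean`, `e_mean`, `n_disconnected_pairs`
#'   (unordered), `mode`, and in sampled mode `l_se`, `e_se` and
#'   `sources`.
#' @export
#' @examples
#' p3 <- point_set(cbind(0:2, 0), model = "EXTERNAL")
#' path_stats(build_geometric_graph(p3, 1))  # l = 4/3, E = 5/6
path_stats <- function(graph, mode = c("exact", "sampled"),
                       n_sources = 300L, seed = NULL, chunk = 512L) {
  stopifnot(inherits(graph, "geometric_graph"))
  mode <- match.arg(mode)
  n <- graph$n
  if (n < 2L)
    return(list(l_mean = NaN, e_mean = 0, n_disconnected_pairs = 0L,
                mode = mode))
  if (mode == "sampled") {
    n_sources <- as.integer(n_sources)
    if (n_sources > n) stop("n_sources exceeds the number of nodes")
    if (!is.null(seed)) set.seed(as.integer(seed))
    sources <- sort(sample.int(n, n_sources))
  } else {
    sources <- seq_len(n)
  }
  sum_l <- 0
  n_conn <- 0
  sum_inv <- 0
  l_src <- numeric(length(sources))
  e_src <- numeric(length(sources))
  for (lo in seq(1L, length(sources), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(sources))
    d <- igraph::distances(graph$graph, v = sources[lo:hi],
                           algorithm = "unweighted")
    for (i in seq_len(nrow(d))) {
      di <- d[i, -sources[lo + i - 1L]]
      fin <- is.finite(di)
      sum_l <- sum_l + sum(di[fin])
      n_conn <- n_conn + sum(fin)
      inv <- sum(1 / di[fin])
      sum_inv <- sum_inv + inv
      l_src[lo + i - 1L] <- if (any(fin)) mean(di[fin]) else NaN
      e_src[lo + i - 1L] <- inv / (n - 1)
    }
  }
  if (mode == "exact") {
    n_disc <- (n * (n - 1) - n_conn) / 2
    list(l_mean = if (n_conn > 0) sum_l / n_conn else NaN,
         e_mean = sum_inv / (n * (n - 1)),
         n_disconnected_pairs = n_disc, mode = mode)
  } else {
    m <- length(sources)
    list(l_mean = if (n_conn > 0) sum_l / n_conn else NaN,
         e_mean = sum_inv / (m * (n - 1)),
         l_se = sd(l_src, na.rm = TRUE) / sqrt(m),
         e_se = sd(e_src) / sqrt(m),
         n_disconnected_pairs = NA_integer_,
         sources = sources, mode = mode)
  }
}

#' Center-perimeter communication ratio
#'
#' `eta_max = l0_max / R`, where `l0_max` is the shortest-path hop
#' count from the center particle (node 1) to the perimeter particle,
#' and R the euclidean radius (the maximum distance from the origin).
#' Straight radial paths give `eta_max = 1`; the tortuous branches of
#' stochastic aggregates give `eta_max > 1`.
#'
#' In a hard-disk system the perimeter is a shell one particle thick,
#' not a single point: every particle whose center lies within half a
#' diameter of R is radially indistinguishable at particle resolution.
#' The target is therefore the particle within `shell` of R with the
#' smallest polar angle (then smallest index) — for ordered systems
#' this is the particle sitting on a straight lattice line through the
#' origin whenever the shell contains one. The ratio for the strict
#' euclidean maximizer (tie rule of [radius()]) is reported as
#' `eta_max_strict`, and the worst case over the whole shell as
#' `eta_max_shell_max`; for disordered aggregates all three agree to a
#' few percent, while for lattices the strict variant inherits the
#' anisotropy of the hop metric (up to 2/sqrt(3) on the triangular
#' lattice).
#'
#' @param graph a [build_geometric_graph()] result.
#' @param shell half-thickness of the perimeter shell, in diameters
#'   (default 0.5 = half a particle diameter; 0 reproduces the strict
#'   maximizer).
#' @return a list with `l0_max`, `eta_max`, `R`, `target` (index of the
#'   perimeter node used), `l0_max_strict`, `eta_max_strict`,
#'   `target_strict`, and `l0_max_shell_max` / `eta_max_shell_max`
#'   (maximum over every shell particle, a tie-sensitivity diagnostic).
#' @export
#' @examples
#' chain <- point_set(cbind(0:4, 0), model = "EXTERNAL")
#' center_perimeter(build_geometric_graph(chain, 1))$eta_max  # 1
center_perimeter <- function(graph, shell = 0.5) {
  stopifnot(inherits(graph, "geometric_graph"))
  rad <- radius(graph$points, tie_tol = shell)
  strict <- radius(graph$points)
  center <- graph$points$center_index
  targets <- union(rad$tied, strict$index)
  d <- igraph::distances(graph$graph, v = center, to = targets,
                         algorithm = "unweighted")
  l0 <- d[1L, match(rad$index, targets)]
  if (!is.finite(l0)) {
    comp <- igraph::components(graph$graph)
    stop(sprintf(paste0(
      "the perimeter particle is unreachable from the center: ",
      "%d components of sizes %s"),
      comp$no, paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")))
  }
  l0_strict <- d[1L, match(strict$index, targets)]
  l0_shell <- suppressWarnings(max(d[1L, is.finite(d[1L, ])]))
  list(l0_max = unname(l0), eta_max = unname(l0) / rad$R, R = rad$R,
       target = rad$index,
       l0_max_strict = unname(l0_strict),
       eta_max_strict = unname(l0_strict) / rad$R,
       target_strict = strict$index,
       l0_max_shell_max = l0_shell,
       eta_max_shell_max = l0_shell / rad$R)
}

#' Topological metric panel of a geometric graph
#'
#' Assembles the network quantities of the analysis at one connectivity
#' parameter: edge count L, mean degree, degree distribution, density,
#' mean clustering, mean shortest-path length, global efficiency,
#' center-perimeter path length and ratio, and the component count.
#'
#' @param graph a [build_geometric_graph()] result.
#' @param path_mode,n_sources,seed passed to [path_stats()].
#' @return a list of class `network_summary` with elements `N`, `r`,
#'   `L`, `k_mean`, `density`, `p_k`, `C_mean`, `l_mean`, `E_mean`,
#'   `n_disconnected_pairs`, `l0_max`, `eta_max`, `n_components` (and
#'   `l_se`, `e_se` in sampled mode).
#' @export
network_summary <- function(graph, path_mode = c("exact", "sampled"),
                            n_sources = 300L, seed = NULL) {
  stopifnot(inherits(graph, "geometric_graph"))
  path_mode <- match.arg(path_mode)
  dd <- degree_distribution(graph)
  ps <- path_stats(graph, mode = path_mode, n_sources = n_sources,
                   seed = seed)
  cp <- center_perimeter(graph)
  out <- list(N = graph$n, r = graph$r, L = dd$L, k_mean = dd$k_mean,
              density = dd$density, p_k = dd$p_k,
              C_mean = mean_clustering(graph),
              l_mean = ps$l_mean, E_mean = ps$e_mean,
              n_disconnected_pairs = ps$n_disconnected_pairs,
              l0_max = cp$l0_max, eta_max = cp$eta_max,
              n_components = igraph::count_components(graph$graph))
  if (path_mode == "sampled") {
    out$l_se <- ps$l_se
    out$e_se <- ps$e_se
  }
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<network_summary> N = %d, r = %g, L = %d, <k> = %.4f, ",
           "<C> = %.4g, <l> = %.4f, <E> = %.4g, eta_max = %.4f\n"),
    x$N, x$r, x$L, x$k_mean, x$C_mean, x$l_mean, x$E_mean, x$eta_max))
  invisible(x)
}
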