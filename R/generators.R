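#' Grow a diffusion-limited aggregate (DLA)
#'
#' Off-lattice particle-cluster aggregation: unit-diameter particles are
#' launched one at a time from a circle of radius `L = r_max + delta`
#' (with `r_max` the current cluster radius) and perform an isotropic
#' random walk with mean free path `mean_free_path` until they touch the
#' cluster, where they stick irreversibly. Walkers wandering beyond the
#' killing radius `kill_factor * L` are discarded and relaunched. Far
#' from the cluster the walk takes isotropic long jumps of length
#' `d_near - 1` (the distance to the nearest particle minus one
#' diameter), which leaves the contact distribution unchanged while
#' removing almost all of the cost of the empty-space walk. On contact
#' the final step is shortened so that the distance to the first
#' contacted particle is exactly one diameter.
#'
#' The growing cluster's radius of gyration about the origin is recorded
#' against the particle count: at every particle up to N = 1000 and at
#' every 10th particle beyond, which is where the power law
#' `R_g(N) ~ N^beta` is fitted (see [fractal_dimension()]).
#'
#' @param n_particles number of particles to aggregate (>= 1).
#' @param delta launch-circle offset, in diameters (default 100).
#' @param kill_factor killing radius as a multiple of the launch radius
#'   (default 2; must be > 1).
#' @param mean_free_path walker step length near the cluster, in
#'   diameters (default 1).
#' @param seed integer seed; if supplied, the R RNG is seeded so the
#'   result is bit-reproducible.
#' @param record_history record the (N, R_g) growth history?
#' @param walker_step_budget steps allowed to a single walker before it
#'   is relaunched.
#' @param global_step_budget total steps allowed to the whole
#'   aggregation before it aborts with an error.
#'
#' @return a list with elements
#'   * `points`: a [point_set()] in aggregation order (row 1 = seed
#'     particle at the origin; every later particle touches an earlier
#'     one),
#'   * `history`: a `growth_history` data frame with columns `n`, `rg`
#'     (empty when `record_history = FALSE`).
#' @seealso [generate_ba()], [fractal_dimension()]
#' @export
#' @examples
#' dla <- generate_dla(200, seed = 1)
#' dla$points
generate_dla <- function(n_particles, delta = 100, kill_factor = 2,
                         mean_free_path = 1, seed = NULL,
                         record_history = TRUE,
                         walker_step_budget = 1e7,
                         global_step_budget = 1e9) {
  aggregate_impl(n_particles, delta, kill_factor, mean_free_path,
                 model = "DLA", seed = seed,
                 record_history = record_history,
                 walker_step_budget = walker_step_budget,
                 global_step_budget = global_step_budget)
}

#' Grow a ballistic aggregate (BA)
#'
#' Like [generate_dla()] but the particles travel along straight lines:
#' each walker is launched from a uniformly random point of the circle
#' of radius `L = r_max + delta` and aimed at a uniformly random point
#' of the disk of radius `r_max + 1` centered at the origin, so that
#' every chord intersecting the occupied region can occur; trajectories
#' that miss the cluster are discarded and relaunched.
#'
#' @inheritParams generate_dla
#' @param delta launch-circle offset, in diameters (default 1000).
#' @return as [generate_dla()].
#' @export
#' @examples
#' ba <- generate_ba(100, seed = 1)
generate_ba <- function(n_particles, delta = 1000, kill_factor = 2,
                        mean_free_path = 1, seed = NULL,
                        record_history = TRUE,
                        walker_step_budget = 1e7,
                        global_step_budget = 1e9) {
  aggregate_impl(n_particles, delta, kill_factor, mean_free_path,
                 model = "BA", seed = seed,
                 record_history = record_history,
                 walker_step_budget = walker_step_budget,
                 global_step_budget = global_step_budget)
}

aggregate_impl <- function(n_particles, delta, kill_factor, mean_free_path,
                           model, seed, record_history,
                           walker_step_budget, global_step_budget) {
  n_particles <- as.integer(n_particles)
  stopifnot(n_particles >= 1L, delta > 0, kill_factor > 1,
            mean_free_path > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- grow_aggregate_cpp(n_particles, delta, kill_factor,
                            mean_free_path,
                            model = if (model == "DLA") 0L else 1L,
                            record_history = record_history,
                            walker_step_budget = walker_step_budget,
                            global_step_budget = global_step_budget)
  points <- point_set(res$coords, model = model, seed = seed,
                      reorder = FALSE)
  history <- growth_history(res$history[, 1], res$history[, 2])
  list(points = points, history = history)
}

#' Growth history of an aggregate
#'
#' A record of the radius of gyration (about the origin) as a function
#' of the particle count during aggregate growth; the input of
#' [fractal_dimension()].
#'
#' @param n integer particle counts, strictly increasing.
#' @param rg radii of gyration at those counts, non-negative.
#' @return a data frame of class `growth_history` with columns `n`, `rg`.
#' @export
growth_history <- function(n, rg) {
  n <- as.numeric(n)
  rg <- as.numeric(rg)
  stopifnot(length(n) == length(rg))
  if (length(n) > 1 && any(diff(n) <= 0))
    stop("particle counts must be strictly increasing")
  if (any(rg < 0)) stop("radii of gyration must be non-negative")
  structure(data.frame(n = n, rg = rg),
            class = c("growth_history", "data.frame"))
}

# iterated function system shared by the Vicsek and Hexaflake fractals:
# n-th iterate = union over unit directions u_k (plus the identity) of
# the (n-1)-th iterate translated by 3^(n-2) * u_k.  This is the IFS
# w_0 = p/3, w_k = (p + u_k)/3 followed by the 3^n rescaling that makes
# nearest neighbors sit at unit distance, evaluated in exact offsets so
# no floating-point error accumulates over iterations.
ifs_points <- function(iterations, angles, max_points) {
  stopifnot(iterations >= 1)
  n_final <- (length(angles) + 1)^(iterations - 1)
  if (n_final > max_points)
    stop(sprintf("iteration %d would produce %g points (max_points = %g)",
                 iterations, n_final, max_points))
  ux <- cos(angles)
  uy <- sin(angles)
  ux[abs(ux) < 1e-12] <- 0  # snap exact axis directions
  uy[abs(uy) < 1e-12] <- 0
  pts <- matrix(0, nrow = 1, ncol = 2)
  if (iterations > 1) {
    for (it in seq_len(iterations - 1)) {
      scale <- 3^(it - 1)
      pieces <- vector("list", length(angles) + 1)
      pieces[[1]] <- pts
      for (k in seq_along(angles)) {
        pieces[[k + 1]] <- cbind(pts[, 1] + scale * ux[k],
                                 pts[, 2] + scale * uy[k])
      }
      pts <- do.call(rbind, pieces)
    }
  }
  # defensive dedup at the contact tolerance; the copies are disjoint by
  # construction, so this should never drop anything
  key <- paste(round(pts[, 1], 9), round(pts[, 2], 9))
  pts <- pts[!duplicated(key), , drop = FALSE]
  if (nrow(pts) != n_final)
    stop("IFS produced overlapping copies; this is a bug")
  pts
}

#' Generate the Vicsek fractal
#'
#' Deterministic cross-shaped fractal: each iteration replaces the set
#' by five copies scaled by 1/3 (center plus the four axis directions);
#' after rescaling, nearest neighbors are at unit distance and the n-th
#' iterate has `5^(n-1)` points. Its contact graph is a tree and its
#' fractal dimension is `log(5)/log(3) ~ 1.465`.
#'
#' @param iterations iteration number n >= 1 (n = 1 is the single seed
#'   point at the origin).
#' @param max_points refuse to generate more points than this.
#' @return a [point_set()] in canonical radial order.
#' @export
#' @examples
#' generate_vicsek(3)  # 25 points
generate_vicsek <- function(iterations, max_points = 1e6) {
  pts <- ifs_points(iterations, angles = (1:4) * pi / 2,
                    max_points = max_points)
  point_set(pts, model = "VICSEK")
}

#' Generate the Hexaflake fractal
#'
#' Deterministic hexagonal fractal: each iteration replaces the set by
#' seven copies scaled by 1/3 (center plus the six hexagonal
#' directions); the n-th iterate has `7^(n-1)` points at unit nearest
#' spacing. All bond angles are multiples of 60 degrees, so the sixfold
#' bond-orientational parameter is exactly 1; its fractal dimension is
#' `log(7)/log(3) ~ 1.771`.
#'
#' @inheritParams generate_vicsek
#' @return a [point_set()] in canonical radial order.
#' @export
#' @examples
#' generate_hexaflake(2)  # hexagon plus center
generate_hexaflake <- function(iterations, max_points = 1e6) {
  pts <- ifs_points(iterations, angles = (1:6) * pi / 3,
                    max_points = max_points)
  point_set(pts, model = "HEXAFLAKE")
}

#' Generate a hexagonal (triangular-packing) lattice patch
#'
#' Sites of the triangular close packing with unit spacing (every
#' interior particle touches 6 neighbors), truncated to exactly
#' `n_particles` sites around the origin by radial burning
#' (see [truncate_radial()]).
#'
#' @param n_particles number of sites to keep (>= 1).
#' @return a [point_set()] in burn (radial) order, row 1 at the origin.
#' @export
#' @examples
#' generate_hexagonal(7)  # origin plus first ring
generate_hexagonal <- function(n_particles) {
  n_particles <- as.integer(n_particles)
  stopifnot(n_particles >= 1L)
  # site density 2/sqrt(3) per unit area
  pts <- lattice_disk(n_particles, density = 2 / sqrt(3),
                      a1 = c(1, 0), a2 = c(0.5, sqrt(3) / 2),
                      basis = matrix(c(0, 0), ncol = 2))
  truncate_radial(point_set(pts, model = "HEXAGONAL"), n_particles)
}

#' Generate a Kagome (trihexagonal) lattice patch
#'
#' Sites of the Kagome lattice at unit spacing: a triangular Bravais
#' lattice with vectors (2, 0) and (1, sqrt(3)) and a three-site basis
#' (0,0), (1,0), (1/2, sqrt(3)/2), forming equilateral triangles and
#' hexagonal voids with every interior particle touching 4 neighbors.
#' Truncated to exactly `n_particles` sites by radial burning.
#'
#' @inheritParams generate_hexagonal
#' @return a [point_set()] in burn (radial) order, row 1 at the origin.
#' @export
generate_kagome <- function(n_particles) {
  n_particles <- as.integer(n_particles)
  stopifnot(n_particles >= 1L)
  # 3 sites per primitive cell of area 2*sqrt(3)
  pts <- lattice_disk(n_particles, density = 3 / (2 * sqrt(3)),
                      a1 = c(2, 0), a2 = c(1, sqrt(3)),
                      basis = rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  truncate_radial(point_set(pts, model = "KAGOME"), n_particles)
}

# all lattice sites within a disk guaranteed to contain >= target sites
lattice_disk <- function(target, density, a1, a2, basis) {
  rad <- sqrt(target / (pi * density)) * 1.05 + 3
  det <- abs(a1[1] * a2[2] - a1[2] * a2[1])
  repeat {
    # coefficient bounds covering the disk: |a| <= rad |a2| / det etc.
    amax <- ceiling(rad * sqrt(sum(a2^2)) / det) + 2
    bmax <- ceiling(rad * sqrt(sum(a1^2)) / det) + 2
    idx <- expand.grid(a = -amax:amax, b = -bmax:bmax)
    pieces <- lapply(seq_len(nrow(basis)), function(k) {
      cbind(idx$a * a1[1] + idx$b * a2[1] + basis[k, 1],
            idx$a * a1[2] + idx$b * a2[2] + basis[k, 2])
    })
    pts <- do.call(rbind, pieces)
    keep <- pts[, 1]^2 + pts[, 2]^2 <= rad^2
    if (sum(keep) >= target) return(pts[keep, , drop = FALSE])
    rad <- rad * 1.3
  }
}

#' Truncate a point set to a target size by radial burning
#'
#' Selects exactly `target_n` particles, always keeping the center
#' particle: starting from the center, the not-yet-selected particle
#' with the smallest radius among those in unit contact (r = 1) with the
#' selected set is admitted repeatedly (ties broken by polar angle, then
#' by index), so the selection is connected at r = 1 by construction and
#' fills radially symmetric shells in order.
#'
#' @param points a [point_set()] whose r = 1 contact graph is connected.
#' @param target_n number of particles to keep (1 <= target_n <= N).
#' @return a [point_set()] with `target_n` rows in admission order
#'   (row 1 = center particle).
#' @export
#' @examples
#' hx <- generate_hexagonal(19)
#' truncate_radial(hx, 7)
truncate_radial <- function(points, target_n) {
  stopifnot(inherits(points, "point_set"))
  target_n <- as.integer(target_n)
  n <- n_points(points)
  if (target_n < 1L || target_n > n)
    stop("target_n must be between 1 and the number of particles")
  co <- points$coords
  ed <- radius_edges_cpp(co, 1, 1e-9)
  pri <- integer(n)
  pri[radial_order(co)] <- seq_len(n)
  ord <- burn_order_cpp(pri, ed, start = points$center_index,
                        target_n = target_n)
  if (length(ord) < target_n) {
    comp <- igraph::components(contact_igraph(co, ed))
    stop(sprintf(paste0(
      "input is disconnected at r = 1: %d components of sizes %s; ",
      "burning from the center reached only %d of the %d requested ",
      "particles"),
      comp$no, paste(sort(comp$csize, decreasing = TRUE), collapse = ", "),
      length(ord), target_n))
  }
  # rows keep the input order (burning only decides membership), so
  # truncating to the full size is the identity
  point_set(co[sort(ord), , drop = FALSE], model = points$model,
            seed = points$seed, reorder = FALSE)
}

contact_igraph <- function(coords, edges) {
  igraph::make_graph(edges = as.vector(t(edges)), n = nrow(coords),
                     directed = FALSE)
}
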