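#' Point sets of unit-diameter particles
#'
#' A `point_set` holds an origin-centered configuration of 2-D particle
#' coordinates in particle-diameter units, together with its model
#' provenance and, for stochastic models, the seed that produced it.
#' Row 1 is always the center particle (the particle at, or nearest to,
#' the origin).
#'
#' @param coords numeric matrix with two columns (x, y), one row per
#'   particle, in particle-diameter units.
#' @param model character label of the generating model; one of
#'   `"DLA"`, `"BA"`, `"VICSEK"`, `"HEXAFLAKE"`, `"KAGOME"`,
#'   `"HEXAGONAL"`, `"EXTERNAL"`.
#' @param seed integer seed used to generate the configuration, or `NULL`
#'   for deterministic models and external data.
#' @param reorder if `TRUE` (default), rows are put into the canonical
#'   order: increasing distance from the origin, ties broken by polar
#'   angle in `[0, 2*pi)`, then by original row index. If `FALSE` the
#'   caller guarantees that row 1 is the center particle.
#'
#' @return an object of class `point_set`: a list with elements `coords`
#'   (N x 2 matrix, columns `x`, `y`), `model`, `seed`, `center_index`
#'   (always 1 after construction).
#'
#' @details Particle systems treated here are hard disks of diameter 1:
#' every valid configuration has minimum pairwise distance >= 1 (up to a
#' contact tolerance of 1e-9) and contains a particle within half a
#' diameter of the origin. [validate_point_set()] checks both.
#'
#' @seealso [generate_dla()], [generate_hexagonal()],
#'   [build_geometric_graph()], [read_point_set()]
#' @export
#' @examples
#' ps <- point_set(cbind(c(0, 1, 2), c(0, 0, 0)), model = "EXTERNAL")
#' n_points(ps)
point_set <- function(coords, model = "EXTERNAL", seed = NULL,
                      reorder = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must have exactly two columns (x, y)")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  model <- match.arg(toupper(model), c(
    "DLA", "BA", "VICSEK", "HEXAFLAKE", "KAGOME", "HEXAGONAL", "EXTERNAL"))
  if (reorder) coords <- coords[radial_order(coords), , drop = FALSE]
  colnames(coords) <- c("x", "y")
  rownames(coords) <- NULL
  r0 <- sqrt(sum(coords[1L, ]^2))
  if (r0 >= 0.5)
    stop("no particle within half a diameter of the origin (closest at ",
         format(r0), ")")
  structure(
    list(coords = coords, model = model,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         center_index = 1L),
    class = "point_set")
}

# canonical ordering: radius, then polar angle in [0, 2pi), then index
radial_order <- function(coords) {
  r2 <- coords[, 1]^2 + coords[, 2]^2
  ang <- atan2(coords[, 2], coords[, 1])
  ang[ang < 0] <- ang[ang < 0] + 2 * pi
  ang[r2 == 0] <- 0
  order(r2, ang, seq_len(nrow(coords)))
}

#' @export
print.point_set <- function(x, ...) {
  n <- nrow(x$coords)
  r <- if (n > 0) sqrt(max(x$coords[, 1]^2 + x$coords[, 2]^2)) else 0
  cat(sprintf("<point_set> model = %s, N = %d, R = %.4g%s\n",
              x$model, n, r,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Number of particles in a point set
#' @param points a [point_set()].
#' @return integer particle count.
#' @export
n_points <- function(points) {
  stopifnot(inherits(points, "point_set"))
  nrow(points$coords)
}

#' Validate the hard-disk and centering invariants of a point set
#'
#' Checks that (i) the minimum pairwise distance is at least
#' `1 - tol` (non-overlapping unit disks), (ii) a particle lies within
#' half a diameter of the origin at `center_index`, and (iii) all
#' coordinates are finite.
#'
#' @param points a [point_set()].
#' @param tol contact tolerance (absolute, diameter units).
#' @return `points`, invisibly; errors describe any violated invariant.
#' @export
validate_point_set <- function(points, tol = 1e-9) {
  stopifnot(inherits(points, "point_set"))
  co <- points$coords
  if (!all(is.finite(co))) stop("non-finite coordinates")
  if (sqrt(sum(co[points$center_index, ]^2)) >= 0.5)
    stop("center particle is not within half a diameter of the origin")
  msep <- min_separation(points, upper = 1)
  if (msep < 1 - tol)
    stop(sprintf("hard-disk violation: minimum separation %.12g < 1 - %g",
                 msep, tol))
  invisible(points)
}

#' Minimum pairwise distance of a point set
#'
#' Computed through the same spatial index as graph construction, so it
#' scales to large N: pairs farther apart than `upper` are ignored and
#' `Inf` is returned when no pair lies within `upper`.
#'
#' @param points a [point_set()].
#' @param upper only pairs within this distance are examined.
#' @return the minimum pairwise distance, or `Inf`.
#' @export
min_separation <- function(points, upper = 1.5) {
  stopifnot(inherits(points, "point_set"))
  co <- points$coords
  if (nrow(co) < 2L) return(Inf)
  ed <- radius_edges_cpp(co, upper, 0)
  if (nrow(ed) == 0L) return(Inf)
  d <- sqrt((co[ed[, 1], 1] - co[ed[, 2], 1])^2 +
            (co[ed[, 1], 2] - co[ed[, 2], 2])^2)
  min(d)
}
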