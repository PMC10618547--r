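#' Read and write point sets as CSV
#'
#' The on-disk form is a comma-separated file with header `x,y`, one
#' row per particle in particle-diameter units, UTF-8, LF endings; row
#' 1 (the first data row) is the center particle. Coordinates round-trip
#' to 15 significant digits.
#'
#' @param points a [point_set()].
#' @param path file path.
#' @param model,seed provenance attached to the result of
#'   [read_point_set()] (files do not carry provenance).
#' @return `read_point_set()` returns a [point_set()] with rows in file
#'   order; `write_point_set()` returns `path` invisibly.
#' @export
write_point_set <- function(points, path) {
  stopifnot(inherits(points, "point_set"))
  df <- data.frame(x = format_num(points$coords[, 1]),
                   y = format_num(points$coords[, 2]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_point_set
#' @export
read_point_set <- function(path, model = "EXTERNAL", seed = NULL) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("point-set CSV must have columns x,y")
  point_set(cbind(df$x, df$y), model = model, seed = seed,
            reorder = FALSE)
}

format_num <- function(x) formatC(x, digits = 15, format = "g")

#' Read and write growth histories as CSV
#'
#' Columns `n,rg`: the particle count and the radius of gyration about
#' the origin recorded during aggregate growth.
#'
#' @param history a [growth_history()].
#' @param path file path.
#' @return `read_growth_history()` returns a [growth_history()];
#'   `write_growth_history()` returns `path` invisibly.
#' @export
write_growth_history <- function(history, path) {
  stopifnot(is.data.frame(history))
  df <- data.frame(n = format_num(history$n), rg = format_num(history$rg))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_history
#' @export
read_growth_history <- function(path) {
  df <- read.csv(path)
  if (!all(c("n", "rg") %in% names(df)))
    stop("growth-history CSV must have columns n,rg")
  growth_history(df$n, df$rg)
}

#' Write an edge list as TSV
#'
#' Two tab-separated 0-based integer columns `i`, `j` with `i < j`, one
#' edge per line, sorted lexicographically (the in-memory edge matrix
#' is 1-based; file indices refer to the rows of the companion
#' point-set CSV, row 0 = center particle).
#'
#' @param graph a [build_geometric_graph()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "geometric_graph"))
  df <- data.frame(i = graph$edges[, 1] - 1L, j = graph$edges[, 2] - 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = c("i", "j"), quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as.matrix(df) + 1L
}

#' Serialize a metric panel to JSON
#'
#' [spatial_summary()] and [network_summary()] objects are written as a
#' single JSON object keyed like the metric panel (R, Rg, D, psi6, L,
#' k_mean, C_mean, l0_max, l_mean, E_mean, eta_max, ...), with the
#' degree distribution as parallel `k` / `p_k` arrays. Numbers keep
#' full precision.
#'
#' @param summary a `spatial_summary` or `network_summary`.
#' @param path file path.
#' @return `path` invisibly; `read_summary_json()` returns a list.
#' @export
write_summary_json <- function(summary, path) {
  x <- unclass(summary)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write the deterministic test fixtures
#'
#' Regenerates, byte-identically, the small deterministic fixtures used
#' by the examples and the command-line interface: the 7-particle
#' hexagonal patch, the Vicsek 2nd and 3rd iterates, the Hexaflake 2nd
#' iterate, a 3-node path, and a two-component set, each as a point-set
#' CSV plus a JSON file of independently precomputed metrics
#' (enumerated by hand on these few-particle systems).
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(points, name, oracle) {
    pcsv <- file.path(dir, paste0(name, ".csv"))
    pjson <- file.path(dir, paste0(name, ".json"))
    write_point_set(points, pcsv)
    jsonlite::write_json(oracle, pjson, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, pcsv, pjson)
  }
  put(generate_hexagonal(7), "hexagonal_n7",
      list(N = 7, L = 12, k_mean = 24 / 7,
           C_mean = (6 / 15 + 6 * (2 / 3)) / 7, psi6 = 1,
           l_mean = 30 / 21, E_mean = 33 / 42, eta_max = 1))
  put(generate_vicsek(2), "vicsek_n2",
      list(N = 5, L = 4, k_mean = 8 / 5, C_mean = 0, psi6 = 0,
           l_mean = 8 / 5, E_mean = 7 / 10, eta_max = 1))
  put(generate_vicsek(3), "vicsek_n3",
      list(N = 25, L = 24, C_mean = 0, psi6 = 0, eta_max = 1))
  put(generate_hexaflake(2), "hexaflake_n2",
      list(N = 7, L = 12, k_mean = 24 / 7,
           C_mean = (6 / 15 + 6 * (2 / 3)) / 7, psi6 = 1, eta_max = 1))
  put(point_set(cbind(0:2, 0), model = "EXTERNAL"), "path3",
      list(N = 3, L = 2, C_mean = 0, l_mean = 4 / 3, E_mean = 5 / 6))
  put(point_set(rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0)),
                model = "EXTERNAL"), "two_components",
      list(N = 4, L = 2, n_components = 2,
           E_mean = 2 * (1 + 1) / (4 * 3)))
  invisible(files)
}
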