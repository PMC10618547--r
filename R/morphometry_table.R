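#' Full metric panel for the six reference systems
#'
#' Runs the whole pipeline at r = 1 for the six radially symmetric
#' systems — Hexagonal, Kagome, Hexaflake, BA, DLA, Vicsek — at a
#' common particle count and assembles the spatial and topological
#' panel (N, R, R_g, D, psi6, L, <k>, <C>, l0_max, <l>, <E>) in one
#' data frame, with ensemble mean, SD and SEM over replicate clusters
#' for the stochastic aggregates.
#'
#' The deterministic fractals are generated at the smallest iterate
#' with at least `n_particles` points and radially truncated (the
#' Vicsek column uses `n_particles + 1` so that an even cross of arms
#' surrounds the center, matching the convention of a 15001-particle
#' tree at the reference size); their D comes from iterate scaling
#' ([ifs_dimension()]), the lattices are reported at the embedding
#' dimension 2, and the aggregates are fitted per cluster from their
#' growth histories with the ensemble mean reported.
#'
#' @param n_particles particles per system.
#' @param replicates ensemble size for BA and DLA.
#' @param base_seed replicate i of a stochastic model uses seed
#'   `base_seed + i - 1`.
#' @param path_mode,n_sources passed to [path_stats()]; the default
#'   exact mode reproduces the reference panel, sampled mode is for
#'   quick looks at large N.
#' @param models subset of systems to run.
#' @return a data frame with one row per (system, statistic): columns
#'   `model`, `stat` (`"value"` for deterministic systems; `"mean"`,
#'   `"sd"`, `"sem"` for ensembles) and the metric columns.
#' @export
#' @examples
#' \donttest{
#' morphometry_table(300, replicates = 2, base_seed = 1)
#' }
morphometry_table <- function(n_particles, replicates = 10,
                              base_seed = 1,
                              path_mode = c("exact", "sampled"),
                              n_sources = 300L,
                              models = c("HEXAGONAL", "KAGOME",
                                         "HEXAFLAKE", "BA", "DLA",
                                         "VICSEK")) {
  path_mode <- match.arg(path_mode)
  models <- match.arg(models, several.ok = TRUE)
  metric_cols <- c("N", "R", "Rg", "D", "psi6", "L", "k_mean", "C_mean",
                   "l0_max", "l_mean", "E_mean", "eta_max")

  panel_row <- function(points, history = NULL, D = NA_real_) {
    g <- build_geometric_graph(points, 1)
    ns <- network_summary(g, path_mode = path_mode,
                          n_sources = n_sources, seed = base_seed)
    ss <- spatial_summary(points)
    if (!is.null(history))
      D <- tryCatch(fractal_dimension(history)$D,
                    error = function(e) NA_real_)  # too small for the fit
    c(N = ns$N, R = ss$R, Rg = ss$Rg, D = D, psi6 = ss$psi6, L = ns$L,
      k_mean = ns$k_mean, C_mean = ns$C_mean, l0_max = ns$l0_max,
      l_mean = ns$l_mean, E_mean = ns$E_mean, eta_max = ns$eta_max)
  }

  min_iterations <- function(branching, target) {
    it <- 1
    while (branching^(it - 1) < target) it <- it + 1
    it
  }

  rows <- list()
  add <- function(model, stat, vals) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, stat = stat, as.list(vals))
  }
  for (model in models) {
    if (model %in% c("BA", "DLA")) {
      gen <- if (model == "BA") generate_ba else generate_dla
      reps <- lapply(seq_len(replicates), function(i) {
        run <- gen(n_particles, seed = base_seed + i - 1L)
        panel_row(run$points, history = run$history)
      })
      mat <- do.call(rbind, reps)
      add(model, "mean", colMeans(mat))
      add(model, "sd", apply(mat, 2, sd))
      add(model, "sem", apply(mat, 2, sd) / sqrt(nrow(mat)))
    } else if (model %in% c("VICSEK", "HEXAFLAKE")) {
      branching <- if (model == "VICSEK") 5 else 7
      target <- if (model == "VICSEK") n_particles + 1L else n_particles
      it <- min_iterations(branching, target)
      gen <- if (model == "VICSEK") generate_vicsek else
        generate_hexaflake
      pts <- truncate_radial(gen(it, max_points = branching^it), target)
      D <- ifs_dimension(tolower(model), iterations = max(it, 5))$D
      add(model, "value", panel_row(pts, D = D))
    } else {
      gen <- if (model == "HEXAGONAL") generate_hexagonal else
        generate_kagome
      add(model, "value", panel_row(gen(n_particles), D = 2))
    }
  }
  out <- do.call(rbind, rows)
  out[, c("model", "stat", metric_cols)]
}
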