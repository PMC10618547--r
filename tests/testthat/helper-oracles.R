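# Independent brute-force oracles, deliberately naive: O(N^2) scans and a
# Floyd-Warshall-style all-pairs recursion, sharing no code with the
# package's spatial-index / BFS production paths.

brute_edges <- function(coords, r, tol = 1e-9) {
  n <- nrow(coords)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= r * (1 + tol)) out <- rbind(out, c(i, j))
    }
  }
  out
}

brute_dist_matrix <- function(edges, n) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      d[edges[k, 1], edges[k, 2]] <- 1
      d[edges[k, 2], edges[k, 1]] <- 1
    }
  }
  for (via in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, via] + d[via, j] < d[i, j])
          d[i, j] <- d[i, via] + d[via, j]
      }
    }
  }
  d
}

brute_path_stats <- function(edges, n) {
  d <- brute_dist_matrix(edges, n)
  off <- d[upper.tri(d)]
  fin <- is.finite(off)
  list(l_mean = if (any(fin)) mean(off[fin]) else NaN,
       e_mean = 2 * sum(1 / off[fin]) / (n * (n - 1)),
       n_disconnected_pairs = sum(!fin))
}

brute_clustering <- function(edges, n) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edges) > 0) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  ci <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]]) tri <- tri + 1
      }
    }
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  if (all(is.na(ci))) 0 else mean(ci, na.rm = TRUE)
}

brute_psi6 <- function(coords, edges) {
  n <- nrow(coords)
  total <- 0 + 0i
  for (i in seq_len(n)) {
    nb <- c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
    if (length(nb) == 0) next
    z <- 0 + 0i
    for (j in nb) {
      th <- atan2(coords[j, 2] - coords[i, 2], coords[j, 1] - coords[i, 1])
      z <- z + exp(6i * th)
    }
    total <- total + z / length(nb)
  }
  as.numeric(Mod(total)) / n
}

# uniform random points in a square box, min-separation thinned so they
# form a legal (if sparse) hard-disk configuration around the origin
random_point_set <- function(n, box = 12, seed = 1) {
  set.seed(seed)
  pts <- cbind(runif(3 * n, -box / 2, box / 2),
               runif(3 * n, -box / 2, box / 2))
  pts <- rbind(c(0, 0), pts)
  keep <- 1L
  for (i in 2:nrow(pts)) {
    d2 <- (pts[keep, 1] - pts[i, 1])^2 + (pts[keep, 2] - pts[i, 2])^2
    if (min(d2) >= 1) keep <- c(keep, i)
    if (length(keep) == n) break
  }
  point_set(pts[keep, , drop = FALSE], model = "EXTERNAL", reorder = FALSE)
}
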