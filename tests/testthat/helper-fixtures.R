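# Shared fixtures and independent oracles used across the suite.

# Minimal closed mesh: regular tetrahedron.
tetrahedron <- function(scale = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * scale
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  triangle_mesh(v, f)
}

# Flat triangulated square patch with one interior vertex (open mesh).
flat_patch <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0.5, 0.5, 0))
  f <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  triangle_mesh(v, f)
}

# O(n^2) union-find single-linkage oracle for cluster_vertices():
# enumerate all pairs within the radius, then take the transitive
# closure with union-find (no igraph involved).
union_find_clusters <- function(points, radius) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  dm <- as.matrix(stats::dist(points))
  hits <- which(dm <= radius & upper.tri(dm), arr.ind = TRUE)
  if (nrow(hits)) {
    for (k in seq_len(nrow(hits))) {
      ri <- find(hits[k, 1L]); rj <- find(hits[k, 2L])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(seq_len(n), roots)
}

# Canonical form of a partition for comparison: sorted list of sorted
# member vectors.
partition_canonical <- function(groups) {
  gs <- lapply(groups, function(g) sort(as.integer(g)))
  unname(gs[order(vapply(gs, min, 1L))])
}

# Brute-force optimal one-to-one matching count under a tolerance
# (exhaustive over permutations; small instances only).
optimal_match_count <- function(a, b, tol) {
  na <- nrow(a); nb <- nrow(b)
  d <- as.matrix(stats::dist(rbind(a, b)))[seq_len(na),
                                           na + seq_len(nb), drop = FALSE]
  k <- min(na, nb)
  best <- 0L
  idxs <- seq_len(nb)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (p in perms(idxs)) {
    cnt <- sum(d[cbind(seq_len(k), p[seq_len(k)])] <= tol)
    best <- max(best, cnt)
  }
  best
}

# Small mirror-symmetric montage for labeling unit tests: 2 midline +
# 3 symmetric pairs on a sphere-ish cap.  Deliberately NOT front-back
# symmetric so only left/right pairs share distance profiles.
toy_montage <- function() {
  dirs <- list(
    FPZ = c(0.94, 0, 0.34), OZ = c(-0.98, 0, 0.20),
    C1 = c(0.1, 0.45, 0.89), C2 = c(0.1, -0.45, 0.89),
    F1 = c(0.55, 0.5, 0.67), F2 = c(0.55, -0.5, 0.67),
    P1 = c(-0.5, 0.58, 0.64), P2 = c(-0.5, -0.58, 0.64))
  montage_spec(
    ordered_labels = c("FPZ", "F1", "F2", "C1", "C2", "P1", "P2", "OZ"),
    midline_labels = c("FPZ", "OZ"),
    symmetric_pairs = rbind(c("F1", "F2"), c("C1", "C2"), c("P1", "P2")),
    directions = dirs)
}

toy_points <- function(scale = 0.09) {
  m <- toy_montage()
  do.call(rbind, m$directions[m$ordered_labels]) * scale
}

# Toy points with a fixed asymmetric perturbation so no two distance
# profiles tie exactly (mirror twins stay approximate, as on real heads).
toy_points_perturbed <- function() {
  toy_points() + matrix(sin(1:24) * 3e-3, 8L, 3L)
}

# Cached default phantom (expensive; shared across test files).
default_phantom <- local({
  cache <- new.env()
  function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      params <- phantom_params(seed = seed)
      set.seed(seed)
      cache[[key]] <- make_phantom(quikcap64_montage(), params)
    }
    cache[[key]]
  }
})

# Nearest-truth distances for a candidate set.
match_distances <- function(cands, truth) {
  d <- as.matrix(stats::dist(rbind(cands$points, truth$points)))
  nc <- nrow(cands$points)
  d[seq_len(nc), nc + seq_len(nrow(truth$points)), drop = FALSE]
}
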