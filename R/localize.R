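# Candidate electrode extraction: restrict the search space, take the
# top-K curvature vertices, cluster by proximity, filter by cluster size,
# return cluster centroids.

#' Localization parameters
#'
#' @param z_min lower bound of the axial search space in meters (default 0:
#'   only vertices above the fiducial plane are searched, which excludes
#'   nose/cheek/lip vertices).
#' @param top_k number of highest-curvature vertices retained (default
#'   2000; sized for a 64-channel cap on a ~10,000-vertex mesh and
#'   adjustable for other systems).
#' @param cluster_radius linkage distance for clustering in meters
#'   (default 0.01, the approximate diameter of one electrode).
#' @param min_cluster_size smallest cluster accepted as an electrode
#'   (default 10 vertices).
#' @param n_expected number of real electrodes (default 64).
#' @param baseline_guard drop selected vertices whose curvature is not
#'   prominent against the scalp baseline (default TRUE; see
#'   [localize_electrodes()]).
#' @param guard_frac position of the prominence threshold between the
#'   eligible curvature median and its 99th percentile (default 0.25).
#' @param contrast_min minimum relative contrast `(q99 - q50) / |q50|`
#'   below which the surface is judged free of protrusions and no
#'   candidates are returned (default 0.5).
#' @return object of class `localize_params`.
#' @export
localize_params <- function(z_min = 0, top_k = 2000L, cluster_radius = 0.01,
                            min_cluster_size = 10L, n_expected = 64L,
                            baseline_guard = TRUE, guard_frac = 0.25,
                            contrast_min = 0.5) {
  stopifnot(top_k >= n_expected, cluster_radius > 0, min_cluster_size >= 1,
            guard_frac >= 0, guard_frac <= 1)
  structure(list(z_min = z_min, top_k = as.integer(top_k),
                 cluster_radius = cluster_radius,
                 min_cluster_size = as.integer(min_cluster_size),
                 n_expected = as.integer(n_expected),
                 baseline_guard = isTRUE(baseline_guard),
                 guard_frac = guard_frac,
                 contrast_min = contrast_min),
            class = "localize_params")
}

#' Restrict the electrode search space
#'
#' Returns the indices of mesh vertices strictly above `z_min`, the axial
#' cut that excludes face vertices from the search.
#'
#' @param mesh a `triangle_mesh` in the SCS frame.
#' @param curv optional `curvature_field` (unused for the cut itself;
#'   accepted so the pipeline stages compose naturally).
#' @param z_min cut height in meters.
#' @return integer vector of eligible vertex indices.
#' @export
restrict_search_space <- function(mesh, curv = NULL, z_min = 0) {
  if (mesh$frame != "SCS") {
    stop("mesh is not in the SCS frame; apply to_scs() first")
  }
  idx <- which(mesh$vertices[, 3L] > z_min)
  if (length(idx) == 0L) stop("search space empty: no vertices above z_min")
  idx
}

#' Top-K curvature vertices
#'
#' The `k` eligible vertices of highest curvature; ties at the cut are
#' broken by ascending vertex index so results are deterministic and
#' stable in mesh order.
#'
#' @param curv a `curvature_field`.
#' @param eligible integer vertex indices to search within.
#' @param k number of vertices to keep.
#' @return integer vector of at most `min(k, length(eligible))` indices.
#' @export
top_k_vertices <- function(curv, eligible, k) {
  stopifnot(k >= 1, length(eligible) >= 1)
  vals <- curv$values[eligible]
  ord <- order(-vals, eligible)
  eligible[ord[seq_len(min(k, length(eligible)))]]
}

#' Single-linkage proximity clustering
#'
#' Partitions points into the connected components of the graph joining
#' every pair at Euclidean distance at most `radius` (single-linkage
#' transitive closure).
#'
#' @param points n x 3 coordinate matrix.
#' @param radius linkage distance in meters.
#' @param member_ids optional ids carried into the clusters (defaults to
#'   row indices).
#' @return list of clusters, each a list with `member_indices`, `centroid`
#'   and `size`; clusters are ordered by their smallest member id.
#' @export
cluster_vertices <- function(points, radius, member_ids = NULL) {
  stopifnot(radius > 0)
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(member_ids)) member_ids <- seq_len(n)
  if (n == 1L) {
    return(list(list(member_indices = member_ids, centroid = points[1L, ],
                     size = 1L)))
  }
  d <- stats::dist(points)
  # rows of the lower-triangle pair list with d <= radius
  hit <- which(d <= radius)
  comp <- if (length(hit)) {
    nb <- pair_from_dist_index(hit, n)
    g <- igraph::graph_from_edgelist(nb, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::components(g)$membership
  } else {
    seq_len(n)
  }
  split_ids <- unname(split(seq_len(n), comp))
  # order clusters by smallest member id
  split_ids <- split_ids[order(vapply(split_ids, min, 1L))]
  lapply(split_ids, function(ii) {
    list(member_indices = member_ids[ii],
         centroid = colMeans(points[ii, , drop = FALSE]),
         size = length(ii))
  })
}

# Recover (i, j) pairs from lower-triangle dist indices.
pair_from_dist_index <- function(idx, n) {
  # dist stores pairs (i<j) column-major: index = (i-1)*(n - i/2) ...;
  # invert with the standard closed form
  j <- ceiling((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
  i <- idx - (j - 1) * (n - j / 2) + j
  cbind(as.integer(j), as.integer(i))
}

#' Filter clusters by size
#'
#' Keeps clusters with at least `min_size` members, preserving order.
#'
#' @param clusters list of clusters from [cluster_vertices()].
#' @param min_size minimum member count.
#' @return filtered list.
#' @export
filter_clusters <- function(clusters, min_size) {
  stopifnot(min_size >= 1)
  clusters[vapply(clusters, function(cl) cl$size >= min_size, TRUE)]
}

#' Localize candidate electrodes on a scalp mesh
#'
#' The full detection pipeline: compute per-vertex curvature, restrict the
#' search to `z > z_min`, keep the `top_k` highest-curvature vertices,
#' optionally discard vertices whose curvature is not prominent above the
#' scalp's baseline, cluster the survivors by `cluster_radius`, drop
#' clusters smaller than `min_cluster_size`, and return one centroid per
#' surviving cluster.
#'
#' The baseline guard works on the eligible curvature distribution:
#' electrode protrusions put a heavy tail above the smooth-scalp baseline,
#' so if the 99th percentile does not stand clear of the median (relative
#' contrast below `contrast_min`) the mesh is judged protrusion-free and
#' no candidates are returned; otherwise vertices below
#' `q50 + guard_frac * (q99 - q50)` are discarded.  This keeps smooth
#' scalp, gentle anatomical relief and the negative-curvature ring around
#' each bump out of the clusters while leaving protrusion cores intact.  The candidate count routinely exceeds the true electrode
#' count (spurious protrusions); pruning to exactly `n_expected` is a
#' separate explicit step ([prune_candidates()]).
#'
#' @param mesh a `triangle_mesh` in the SCS frame.
#' @param params a [localize_params()].
#' @param curv optional precomputed `curvature_field`.
#' @param method curvature estimator if `curv` is not supplied.
#' @return object of class `candidate_set`: list with `points` (c x 3
#'   centroids), `cluster_sizes`, and `source`.
#' @export
localize_electrodes <- function(mesh, params = localize_params(),
                                curv = NULL,
                                method = c("mean_cotan", "angle_deficit")) {
  method <- match.arg(method)
  if (is.null(curv)) curv <- vertex_curvature(mesh, method)
  eligible <- restrict_search_space(mesh, curv, params$z_min)
  sel <- top_k_vertices(curv, eligible, params$top_k)
  if (params$baseline_guard) {
    q <- stats::quantile(curv$values[eligible], c(0.5, 0.99), names = FALSE)
    contrast <- (q[2L] - q[1L]) / max(abs(q[1L]), .Machine$double.eps)
    sel <- if (contrast < params$contrast_min) integer(0) else {
      sel[curv$values[sel] > q[1L] + params$guard_frac * (q[2L] - q[1L])]
    }
  }
  if (length(sel) == 0L) {
    return(candidate_set(matrix(numeric(0), 0L, 3L), integer(0),
                         source = "localize_electrodes"))
  }
  clusters <- cluster_vertices(mesh$vertices[sel, , drop = FALSE],
                               params$cluster_radius, member_ids = sel)
  clusters <- filter_clusters(clusters, params$min_cluster_size)
  if (length(clusters) == 0L) {
    return(candidate_set(matrix(numeric(0), 0L, 3L), integer(0),
                         source = "localize_electrodes"))
  }
  pts <- do.call(rbind, lapply(clusters, `[[`, "centroid"))
  sizes <- vapply(clusters, `[[`, 1L, "size")
  candidate_set(pts, sizes, source = "localize_electrodes")
}

#' Candidate electrode set
#'
#' @param points c x 3 matrix of cluster centroids (meters).
#' @param cluster_sizes integer vector of cluster member counts.
#' @param source provenance string.
#' @return object of class `candidate_set`.
#' @export
candidate_set <- function(points, cluster_sizes, source = "") {
  points <- matrix(as.numeric(points), ncol = 3L)
  stopifnot(length(cluster_sizes) == nrow(points))
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points,
                 cluster_sizes = as.integer(cluster_sizes),
                 source = source),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidates (cluster sizes %s)\n",
              nrow(x$points),
              if (nrow(x$points)) paste0(min(x$cluster_sizes), "..",
                                         max(x$cluster_sizes)) else "-"))
  invisible(x)
}

#' Prune candidates to the expected electrode count
#'
#' Replaces interactive removal of spurious detections with an explicit,
#' reproducible keep/drop list.  Exactly one of `keep` or `drop` must be
#' given, and the result must contain exactly `n_expected` points.
#'
#' @param cands a `candidate_set`.
#' @param keep indices (into the candidate list) to retain.
#' @param drop indices to remove.
#' @param n_expected required electrode count (default 64).
#' @return an unlabeled [electrode_set()] of exactly `n_expected` points,
#'   in candidate order.
#' @export
prune_candidates <- function(cands, keep = NULL, drop = NULL,
                             n_expected = 64L) {
  if (is.null(keep) == is.null(drop)) {
    stop("give exactly one of keep or drop")
  }
  n <- nrow(cands$points)
  idx <- if (!is.null(keep)) sort(unique(as.integer(keep)))
         else setdiff(seq_len(n), as.integer(drop))
  if (any(idx < 1L | idx > n)) stop("keep/drop index out of range")
  if (length(idx) != n_expected) {
    stop(sprintf("pruning left %d candidates but exactly %d are required",
                 length(idx), n_expected))
  }
  electrode_set(cands$points[idx, , drop = FALSE], frame = "SCS")
}

#' Rank candidates for pruning
#'
#' Convenience beyond the core pipeline: orders candidate indices by
#' decreasing cluster size (largest first), a useful starting point when
#' composing a keep list.
#'
#' @param cands a `candidate_set`.
#' @return integer permutation of candidate indices.
#' @export
rank_candidates <- function(cands) {
  order(-cands$cluster_sizes, seq_along(cands$cluster_sizes))
}
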