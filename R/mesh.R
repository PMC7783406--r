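# Core mesh container and geometry utilities.

#' Triangulated surface mesh
#'
#' Container for a triangulated scalp (or phantom) surface: vertex
#' coordinates in meters and triangle vertex indices.  Meshes are tagged
#' with a coordinate-frame label so downstream steps can insist on the
#' subject coordinate system (SCS: origin at the preauricular midpoint,
#' +x anterior through the nasion, +y left, +z superior).
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (meters).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @param frame coordinate-frame tag, `"SCS"` or `"unknown"`.
#' @return An object of class `triangle_mesh` with components `vertices`,
#'   `faces` and `frame`.
#' @export
triangle_mesh <- function(vertices, faces, frame = c("unknown", "SCS")) {
  frame <- match.arg(frame)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  if (nrow(vertices) < 4L) stop("a closed mesh needs at least 4 vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    bad <- which(rowSums(faces < 1L | faces > nrow(vertices)) > 0L)[1L]
    stop(sprintf("face %d references a vertex outside 1..%d",
                 bad, nrow(vertices)))
  }
  degen <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
    faces[, 2L] == faces[, 3L]
  if (any(degen)) {
    stop(sprintf("degenerate face (repeated vertex) at face %d",
                 which(degen)[1L]))
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, frame=%s\n",
              nrow(x$vertices), nrow(x$faces), x$frame))
  rng <- apply(x$vertices, 2L, range)
  cat(sprintf("  extent [m]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

# Directed edge table: one row per face corner, columns (from, to).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  cbind(from = c(f[, 1L], f[, 2L], f[, 3L]),
        to   = c(f[, 2L], f[, 3L], f[, 1L]))
}

# Undirected edge key for matching half-edges.
edge_keys <- function(edges) {
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  paste(lo, hi)
}

#' Check mesh closedness and manifoldness
#'
#' A closed 2-manifold triangulation has every undirected edge shared by
#' exactly two faces.  Returns a list with the per-edge face counts so
#' callers can report offending edges.
#'
#' @param mesh a `triangle_mesh`.
#' @return list with `closed` (logical), `boundary_vertices` (indices of
#'   vertices on edges used once) and `nonmanifold_edges` (character keys
#'   of edges used more than twice).
#' @export
mesh_topology <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- edge_keys(e)
  cnt <- table(key)
  nonman <- names(cnt)[cnt > 2L]
  bkeys <- names(cnt)[cnt == 1L]
  bverts <- integer(0)
  if (length(bkeys)) {
    parts <- strsplit(bkeys, " ", fixed = TRUE)
    bverts <- sort(unique(as.integer(unlist(parts))))
  }
  list(closed = length(bkeys) == 0L && length(nonman) == 0L,
       boundary_vertices = bverts,
       nonmanifold_edges = nonman)
}

# Euler characteristic V - E + F (undirected edge count).
euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  nE <- length(unique(edge_keys(e)))
  nrow(mesh$vertices) - nE + nrow(mesh$faces)
}

# Per-face unit normals and areas (cross-product based).
face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm * nrm))
  area <- len / 2
  if (any(area <= .Machine$double.eps)) {
    stop(sprintf("zero-area triangle at face %d",
                 which(area <= .Machine$double.eps)[1L]))
  }
  list(normals = nrm / len, areas = area)
}

# Signed volume of a closed mesh (divergence theorem); positive when
# faces are oriented outward.
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
      a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
      a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

#' Orient faces consistently outward
#'
#' Propagates a consistent winding across shared edges (breadth-first over
#' the face-adjacency graph) and flips the whole mesh if the resulting
#' signed volume is negative, so face normals point away from the interior.
#' Closed meshes only; open meshes are returned with consistent winding
#' but no global flip check.
#'
#' @param mesh a `triangle_mesh`.
#' @return the mesh with possibly re-wound faces.
#' @export
orient_outward <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  e <- mesh_edges(mesh)
  key <- edge_keys(e)
  face_of <- rep.int(seq_len(nf), 3L)
  # adjacency: faces sharing an undirected edge
  ord <- order(key)
  key_s <- key[ord]
  face_s <- face_of[ord]
  grp_end <- c(which(key_s[-1L] != key_s[-length(key_s)]), length(key_s))
  grp_start <- c(1L, head(grp_end, -1L) + 1L)
  adj <- vector("list", nf)
  dir_s <- (e[, 1L] < e[, 2L])[ord]  # half-edge direction relative to key
  for (g in seq_along(grp_start)) {
    idx <- grp_start[g]:grp_end[g]
    if (length(idx) == 2L) {
      f1 <- face_s[idx[1L]]; f2 <- face_s[idx[2L]]
      same_dir <- dir_s[idx[1L]] == dir_s[idx[2L]]
      adj[[f1]] <- rbind(adj[[f1]], c(f2, same_dir))
      adj[[f2]] <- rbind(adj[[f2]], c(f1, same_dir))
    }
  }
  flip <- rep(NA, nf)
  for (seed in seq_len(nf)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[cur]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        nxt <- nb[r, 1L]
        # consistently wound neighbours traverse a shared edge in
        # opposite directions; same direction means one must flip
        want <- if (nb[r, 2L] == 1) !flip[cur] else flip[cur]
        if (is.na(flip[nxt])) {
          flip[nxt] <- want
          queue <- c(queue, nxt)
        }
      }
    }
  }
  if (any(flip)) {
    f[flip, ] <- f[flip, c(1L, 3L, 2L)]
    mesh$faces <- f
  }
  topo <- mesh_topology(mesh)
  if (topo$closed && signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  }
  mesh
}

# Angle-weighted outward vertex normals (mesh must be consistently
# oriented; combine with orient_outward()).
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  fg <- face_geometry(mesh)
  n <- matrix(0, nrow(v), 3L)
  ang <- corner_angles(mesh)
  for (k in 1:3) {
    idx <- f[, k]
    w <- ang[, k]
    n[, 1L] <- n[, 1L] + unname(tapply2(w * fg$normals[, 1L], idx, nrow(v)))
    n[, 2L] <- n[, 2L] + unname(tapply2(w * fg$normals[, 2L], idx, nrow(v)))
    n[, 3L] <- n[, 3L] + unname(tapply2(w * fg$normals[, 3L], idx, nrow(v)))
  }
  len <- sqrt(rowSums(n * n))
  len[len == 0] <- 1
  n / len
}

# Fast grouped sum into a length-n vector.
tapply2 <- function(x, index, n) {
  out <- numeric(n)
  s <- rowsum(x, group = index, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Corner angles per face (M x 3), angle at vertex faces[,k] in column k.
corner_angles <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  ang <- function(p, q, r) {
    u <- q - p; w <- r - p
    cu <- sqrt(rowSums(u * u)); cw <- sqrt(rowSums(w * w))
    cosv <- rowSums(u * w) / (cu * cw)
    acos(pmin(1, pmax(-1, cosv)))
  }
  cbind(ang(a, b, c_), ang(b, c_, a), ang(c_, a, b))
}

#' Icosphere triangulation
#'
#' Subdivided icosahedron projected to the unit sphere: the standard
#' near-uniform genus-0 triangulation.  Subdivision level `n` yields
#' `10 * 4^n + 2` vertices (level 5 gives 10242, close to the 10,000-vertex
#' scalp meshes this package targets).
#'
#' @param subdivisions non-negative integer subdivision level.
#' @param radius sphere radius in meters.
#' @return a `triangle_mesh` (frame `"unknown"`).
#' @export
icosphere <- function(subdivisions = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(key)
    mid_id <- match(key, uk) + nrow(v)
    ue <- e[match(uk, key), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids * mids))
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  triangle_mesh(v * radius, f)
}
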