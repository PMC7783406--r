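# Synthetic head phantoms: ellipsoidal scalp meshes with Gaussian
# electrode bumps at montage positions, plus labeled ground truth.
# These stand in for the (undeposited) MR-derived head models so the
# localization and labeling pipeline can be exercised and scored.

#' Phantom generation parameters
#'
#' @param ellipsoid_semiaxes length-3 numeric, semiaxes (a, b, c) of the
#'   head ellipsoid in meters along SCS x (anterior), y (left),
#'   z (superior).  Defaults 0.095, 0.075, 0.080 — adult-head scale.
#' @param semiaxis_scatter relative SD of per-subject semiaxis variation
#'   (default 0.05, i.e. +/-5 percent scale differences between subjects).
#' @param mesh_vertices target vertex count; the generator picks the
#'   icosphere subdivision level whose count is closest (default 10000,
#'   matching a typical scalp mesh resolution).
#' @param bump_height peak outward displacement of an electrode bump in
#'   meters (default 0.003).
#' @param bump_radius Gaussian scale (sigma) of the bump profile in meters
#'   (default 0.005, half the ~1 cm footprint of a gel-filled electrode).
#' @param angular_jitter_sd total SD of per-electrode angular placement
#'   jitter in radians (default 0.02; about 1.7 mm on an adult head).
#' @param jitter_rigid_frac fraction of the jitter variance carried by a
#'   whole-cap rigid rotation (default 0.75): caps mostly shift and twist
#'   as a unit, with a smaller independent slip per electrode.
#' @param n_dummies number of unlabeled spurious bumps — empty holders,
#'   reference/EOG sites (default 15, the count reported for the cap this
#'   phantom emulates).
#' @param dummy_posterior_bias if TRUE (default) dummies are drawn with an
#'   occipital placement bias, mimicking where empty holders cluster.
#' @param posterior_attenuation factor in \[0, 1\] multiplying bump height
#'   at occipital/temporal sites, emulating gel drying at the back of the
#'   head (default 1 = off).
#' @param center_offset superior offset of the ellipsoid center above the
#'   fiducial plane, meters (default 0.015): on real heads the
#'   preauricular axis passes below the widest extent of the cranial
#'   vault, so the scalp continues below z = 0.
#' @param rim_relief_height peak height (meters) of the circumferential
#'   rim relief — a shallow band of extra convexity around brow / temple /
#'   inion level, the scalp's own curvature structure at the cap edge
#'   (default 0.0006; 0 disables).
#' @param rim_relief_center,rim_relief_width center and half-width of the
#'   relief band, radians of polar angle from +z (defaults 1.66 ~ 95 deg
#'   and 0.16 ~ 9 deg).
#' @param seed integer RNG seed.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(ellipsoid_semiaxes = c(0.095, 0.075, 0.080),
                           semiaxis_scatter = 0.05,
                           mesh_vertices = 10000L,
                           bump_height = 0.003,
                           bump_radius = 0.005,
                           angular_jitter_sd = 0.02,
                           jitter_rigid_frac = 0.75,
                           n_dummies = 15L,
                           dummy_posterior_bias = TRUE,
                           posterior_attenuation = 1,
                           center_offset = 0.015,
                           rim_relief_height = 0.0006,
                           rim_relief_center = 1.66,
                           rim_relief_width = 0.16,
                           seed = 1L) {
  stopifnot(length(ellipsoid_semiaxes) == 3L, all(ellipsoid_semiaxes > 0),
            bump_radius < min(ellipsoid_semiaxes),
            posterior_attenuation >= 0, posterior_attenuation <= 1,
            bump_height >= 0, n_dummies >= 0, rim_relief_height >= 0)
  structure(list(ellipsoid_semiaxes = as.numeric(ellipsoid_semiaxes),
                 semiaxis_scatter = semiaxis_scatter,
                 mesh_vertices = as.integer(mesh_vertices),
                 bump_height = bump_height,
                 bump_radius = bump_radius,
                 angular_jitter_sd = angular_jitter_sd,
                 jitter_rigid_frac = jitter_rigid_frac,
                 n_dummies = as.integer(n_dummies),
                 dummy_posterior_bias = isTRUE(dummy_posterior_bias),
                 posterior_attenuation = posterior_attenuation,
                 center_offset = center_offset,
                 rim_relief_height = rim_relief_height,
                 rim_relief_center = rim_relief_center,
                 rim_relief_width = rim_relief_width,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Icosphere level with vertex count 10*4^n+2 closest to the target.
subdiv_for_vertices <- function(n_target) {
  lv <- 0:7
  counts <- 10 * 4^lv + 2
  lv[which.min(abs(counts - n_target))]
}

# Radial scale taking a unit direction onto the ellipsoid surface.
ellipsoid_radius <- function(dirs, semi) {
  1 / sqrt((dirs[, 1L] / semi[1L])^2 + (dirs[, 2L] / semi[2L])^2 +
           (dirs[, 3L] / semi[3L])^2)
}

#' Generate a bare phantom head mesh
#'
#' A closed genus-0 triangulation of the head at roughly the requested
#' vertex count, in the SCS frame.  The shape is an ellipsoid with its
#' center `center_offset` above the fiducial plane plus an optional
#' shallow circumferential rim relief at brow/temple/inion level — the
#' kind of low-amplitude convexity structure real scalps carry at the
#' edge of the cap.
#'
#' @param params a [phantom_params()].
#' @param semiaxes optional explicit semiaxes overriding the params
#'   (used for per-subject scatter).
#' @return a `triangle_mesh` with `frame = "SCS"`.
#' @export
make_head_mesh <- function(params = phantom_params(), semiaxes = NULL) {
  semi <- if (is.null(semiaxes)) params$ellipsoid_semiaxes else semiaxes
  sph <- icosphere(subdiv_for_vertices(params$mesh_vertices), radius = 1)
  dirs <- sph$vertices
  r <- ellipsoid_radius(dirs, semi)
  v <- dirs * r
  if (params$rim_relief_height > 0) {
    rho <- acos(pmin(1, pmax(-1, dirs[, 3L])))
    u <- (rho - params$rim_relief_center) / params$rim_relief_width
    g <- params$rim_relief_height * pmax(0, 1 - u^2)
    v <- v + ellipsoid_normals(v, semi) * g
  }
  v[, 3L] <- v[, 3L] + params$center_offset
  triangle_mesh(v, sph$faces, frame = "SCS")
}

# Surface point (incl. center offset; rim relief is zero in the montage
# zone) for unit directions.
phantom_surface_point <- function(dirs, semi, params) {
  r <- ellipsoid_radius(dirs, semi)
  p <- dirs * r
  p[, 3L] <- p[, 3L] + params$center_offset
  p
}

#' Place a labeled montage on a phantom head
#'
#' Projects the montage's canonical unit-sphere directions onto the
#' ellipsoid surface, optionally applying per-electrode angular jitter
#' (tangent-plane Gaussian perturbation of the direction).  Left/right
#' pairs are exact mirror images and midline labels lie on the x-z plane
#' before jitter.
#'
#' @param montage a [montage_spec()] carrying canonical directions.
#' @param params a [phantom_params()].
#' @param semiaxes optional explicit semiaxes.
#' @param jitter if FALSE, jitter is suppressed regardless of params.
#' @return labeled [electrode_set()] in the SCS frame (ground truth).
#' @export
place_montage <- function(montage, params = phantom_params(),
                          semiaxes = NULL, jitter = TRUE) {
  if (is.null(montage$directions)) {
    stop("montage has no canonical directions; cannot place electrodes")
  }
  semi <- if (is.null(semiaxes)) params$ellipsoid_semiaxes else semiaxes
  labs <- montage$ordered_labels
  dirs <- do.call(rbind, montage$directions[labs])
  if (jitter && params$angular_jitter_sd > 0) {
    sd_rigid <- params$angular_jitter_sd * sqrt(params$jitter_rigid_frac)
    sd_local <- params$angular_jitter_sd * sqrt(1 - params$jitter_rigid_frac)
    dirs <- jitter_directions(dirs, sd_local, sd_rigid)
  }
  electrode_set(phantom_surface_point(dirs, semi, params),
                labels = labs, frame = "SCS")
}

# Cap-placement jitter: a small random rigid rotation of all directions
# (the cap shifting as a unit) plus independent Gaussian perturbations in
# each direction's tangent plane (local slip).  Per-axis angular SDs in
# radians.
jitter_directions <- function(dirs, sd_local, sd_rigid = 0) {
  if (sd_rigid > 0) {
    omega <- stats::rnorm(3L, 0, sd_rigid)
    th <- sqrt(sum(omega^2))
    if (th > 0) {
      k <- omega / th
      K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
      R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      dirs <- dirs %*% t(R)
    }
  }
  if (sd_local <= 0) return(dirs)
  sd <- sd_local
  n <- nrow(dirs)
  # tangent basis per direction
  ref <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  flip <- abs(dirs[, 3L]) > 0.9
  ref[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3L)
  t1 <- cbind(dirs[, 2L] * ref[, 3L] - dirs[, 3L] * ref[, 2L],
              dirs[, 3L] * ref[, 1L] - dirs[, 1L] * ref[, 3L],
              dirs[, 1L] * ref[, 2L] - dirs[, 2L] * ref[, 1L])
  t1 <- t1 / sqrt(rowSums(t1 * t1))
  t2 <- cbind(dirs[, 2L] * t1[, 3L] - dirs[, 3L] * t1[, 2L],
              dirs[, 3L] * t1[, 1L] - dirs[, 1L] * t1[, 3L],
              dirs[, 1L] * t1[, 2L] - dirs[, 2L] * t1[, 1L])
  e1 <- stats::rnorm(n, 0, sd)
  e2 <- stats::rnorm(n, 0, sd)
  out <- dirs + t1 * e1 + t2 * e2
  out / sqrt(rowSums(out * out))
}

#' Add electrode bumps to a head mesh
#'
#' Displaces each vertex outward along the ellipsoid surface normal by the
#' sum of Gaussian bump profiles centered on the given positions:
#' `height * exp(-d^2 / (2 * bump_radius^2))` with `d` the Euclidean
#' distance from the bump center.  Heights may be per-bump (vector) to
#' support posterior attenuation.  Overlapping bumps (centers closer than
#' twice the bump radius) sum their displacements, with a warning.
#'
#' @param mesh a `triangle_mesh` of the bare head.
#' @param positions k x 3 matrix of bump centers on (or near) the surface.
#' @param params a [phantom_params()] providing `bump_radius` and the
#'   default `bump_height`.
#' @param heights optional length-k vector of per-bump peak heights.
#' @return the bumped `triangle_mesh` (still closed; same topology).
#' @export
add_electrode_bumps <- function(mesh, positions, params = phantom_params(),
                                heights = NULL) {
  positions <- as.matrix(positions)
  k <- nrow(positions)
  if (is.null(heights)) heights <- rep(params$bump_height, k)
  stopifnot(length(heights) == k)
  if (k == 0L || all(heights == 0)) return(mesh)
  if (k > 1L) {
    dmin <- min(stats::dist(positions))
    if (dmin < 2 * params$bump_radius) {
      warning(sprintf(
        "bump centers %.1f mm apart overlap (< 2 * bump_radius); %s",
        dmin * 1000, "displacements are summed"))
    }
  }
  v <- mesh$vertices
  # outward normals of the underlying ellipsoid-like surface: use
  # angle-weighted vertex normals of the current mesh
  mesh_o <- orient_outward(mesh)
  nrm <- vertex_normals(mesh_o)
  sigma2 <- 2 * params$bump_radius^2
  disp <- numeric(nrow(v))
  for (i in seq_len(k)) {
    if (heights[i] == 0) next
    d2 <- (v[, 1L] - positions[i, 1L])^2 + (v[, 2L] - positions[i, 2L])^2 +
      (v[, 3L] - positions[i, 3L])^2
    near <- d2 < 9 * sigma2
    disp[near] <- disp[near] + heights[i] * exp(-d2[near] / sigma2)
  }
  mesh_o$vertices <- v + nrm * disp
  mesh_o
}

# Occipital/temporal sites subject to posterior attenuation: posterior
# (x < 0) lateral or occipital rows.
attenuated_labels <- function(labels) {
  grepl("^(O[12Z]|OZ|PO[0-9]+|CB[12]|TP[78]|T[78]|M[12]|I[12Z])$", labels)
}

#' Generate one complete phantom subject
#'
#' Builds the bare head, places the montage with jitter, draws dummy bump
#' positions (random surface sites at least 2 cm from any true electrode,
#' with optional posterior bias), applies all bumps (true sites possibly
#' attenuated posteriorly), and returns mesh plus ground truth.
#'
#' @param montage a [montage_spec()] with canonical directions.
#' @param params a [phantom_params()].
#' @param semiaxes optional per-subject semiaxes.
#' @return object of class `phantom_truth`: list with `mesh`
#'   (bumped `triangle_mesh`), `electrodes` (labeled [electrode_set()] at
#'   bump apices) and `dummy_positions` (k x 3 matrix).
#' @export
make_phantom <- function(montage = quikcap64_montage(),
                         params = phantom_params(), semiaxes = NULL) {
  semi <- if (is.null(semiaxes)) params$ellipsoid_semiaxes else semiaxes
  bare <- make_head_mesh(params, semiaxes = semi)
  truth <- place_montage(montage, params, semiaxes = semi)
  dummies <- draw_dummy_positions(params, semi, truth$points)
  all_pos <- rbind(truth$points, dummies)
  heights <- rep(params$bump_height, nrow(truth$points))
  att <- attenuated_labels(truth$labels)
  heights[att] <- heights[att] * params$posterior_attenuation
  heights <- c(heights, rep(params$bump_height, nrow(dummies)))
  mesh <- add_electrode_bumps(bare, all_pos, params, heights = heights)
  # ground-truth coordinates sit on the bump apex: original surface point
  # displaced by its own bump height along the surface normal
  base <- truth$points
  base[, 3L] <- base[, 3L] - params$center_offset
  nrm <- ellipsoid_normals(base, semi)
  apex <- truth$points + nrm * heights[seq_len(nrow(truth$points))]
  electrodes <- electrode_set(apex, labels = truth$labels, frame = "SCS")
  structure(list(mesh = mesh, electrodes = electrodes,
                 dummy_positions = dummies),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d-vertex mesh, %d labeled electrodes, %d dummies\n",
              nrow(x$mesh$vertices), nrow(x$electrodes$points),
              nrow(x$dummy_positions)))
  invisible(x)
}

# Analytic outward normal of the ellipsoid at surface points.
ellipsoid_normals <- function(pts, semi) {
  n <- cbind(pts[, 1L] / semi[1L]^2, pts[, 2L] / semi[2L]^2,
             pts[, 3L] / semi[3L]^2)
  n / sqrt(rowSums(n * n))
}

# Random dummy bump positions: surface sites in the belt just below the
# montage (the cap edge, where empty holders and reference/EOG electrodes
# sit on real caps), still above the fiducial plane so they intrude on
# the search space; >= 2 cm clear of every true electrode and of each
# other; optionally biased toward the occiput.
draw_dummy_positions <- function(params, semi, true_points) {
  k <- params$n_dummies
  if (k == 0L) return(matrix(numeric(0), 0L, 3L))
  out <- matrix(NA_real_, k, 3L)
  got <- 0L
  tries <- 0L
  while (got < k && tries < 20000L) {
    tries <- tries + 1L
    # polar angle in the cap-edge belt, azimuth free
    rho <- stats::runif(1, 1.60, 1.73)
    phi <- stats::runif(1, -pi, pi)
    if (params$dummy_posterior_bias && cos(phi) > 0 &&
        stats::runif(1) < 0.6) {
      phi <- pi - phi  # reflect to the posterior half most of the time
    }
    u <- c(sin(rho) * cos(phi), sin(rho) * sin(phi), cos(rho))
    p <- drop(phantom_surface_point(matrix(u, 1L), semi, params))
    if (p[3L] < 0.008) next  # stay inside the search space
    d <- sqrt(rowSums((true_points - matrix(p, nrow(true_points), 3L,
                                            byrow = TRUE))^2))
    if (min(d) < 0.024) next
    if (got > 0L) {
      dprev <- sqrt(rowSums((out[seq_len(got), , drop = FALSE] -
                               matrix(p, got, 3L, byrow = TRUE))^2))
      if (min(dprev) < 0.022) next
    }
    got <- got + 1L
    out[got, ] <- p
  }
  out[seq_len(got), , drop = FALSE]
}

#' Generate a phantom cohort
#'
#' Independent subjects sharing a montage, with per-subject semiaxis
#' scatter and placement jitter.  Deterministic given the seed.
#'
#' @param n_subjects number of subjects.
#' @param montage a [montage_spec()] with directions.
#' @param params a [phantom_params()]; its `seed` is the cohort seed.
#' @param meshes if FALSE (default) skip the expensive bumped meshes and
#'   return only ground-truth electrode sets — sufficient for labeling
#'   experiments, which operate on coordinates alone.
#' @return list of `phantom_truth` (or, with `meshes = FALSE`, of lists
#'   with `electrodes` and `semiaxes`).
#' @export
make_cohort <- function(n_subjects, montage = quikcap64_montage(),
                        params = phantom_params(), meshes = FALSE) {
  stopifnot(n_subjects >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  subject_seeds <- sample.int(2^31 - 2L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(subject_seeds[i])
    semi <- params$ellipsoid_semiaxes *
      (1 + stats::rnorm(3L, 0, params$semiaxis_scatter))
    semi <- pmax(semi, 0.5 * params$ellipsoid_semiaxes)
    if (meshes) {
      make_phantom(montage, params, semiaxes = semi)
    } else {
      list(electrodes = place_montage(montage, params, semiaxes = semi),
           semiaxes = semi)
    }
  })
}
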