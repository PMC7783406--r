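# Phantom generation: mesh topology, montage placement, bumps, cohorts.

test_that("phantom head meshes are closed genus-0 at the requested size", {
  mesh <- make_head_mesh(phantom_params(mesh_vertices = 2562))
  expect_equal(nrow(mesh$vertices), 2562L)
  expect_equal(euler_characteristic(mesh), 2L)
  expect_true(mesh_topology(mesh)$closed)
  expect_equal(mesh$frame, "SCS")
})

test_that("equal semiaxes give a sphere of the stated radius", {
  params <- phantom_params(ellipsoid_semiaxes = c(0.1, 0.1, 0.1),
                           mesh_vertices = 642, center_offset = 0,
                           rim_relief_height = 0)
  mesh <- make_head_mesh(params)
  r <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(max(abs(r - 0.1)), 1e-3)
})

test_that("mesh generation is deterministic", {
  p <- phantom_params(mesh_vertices = 642, seed = 9)
  expect_identical(make_head_mesh(p), make_head_mesh(p))
})

test_that("jitter-free montage placement is symmetric with CZ on top", {
  m <- quikcap64_montage()
  params <- phantom_params()
  truth <- place_montage(m, params, jitter = FALSE)
  labs <- truth$labels
  expect_equal(nrow(truth$points), 64L)
  # CZ is the topmost electrode and near the mesh maximum
  i_cz <- match("CZ", labs)
  expect_equal(which.max(truth$points[, 3L]), i_cz)
  mesh <- make_head_mesh(params)
  expect_lt(max(truth$points[, 3L]) - max(mesh$vertices[, 3L]), 0.002)
  # mirror pairs agree up to a sign flip in y
  for (k in seq_len(nrow(m$symmetric_pairs))) {
    a <- truth$points[match(m$symmetric_pairs[k, 1L], labs), ]
    b <- truth$points[match(m$symmetric_pairs[k, 2L], labs), ]
    expect_lt(max(abs(a - b * c(1, -1, 1))), 1e-6)
  }
  # midline labels sit on the x-z plane
  mid <- truth$points[labs %in% m$midline_labels, 2L]
  expect_lt(max(abs(mid)), 1e-6)
  # everything above the fiducial plane
  expect_true(all(truth$points[, 3L] > 0))
})

test_that("seeds control placement reproducibly", {
  m <- quikcap64_montage()
  p <- phantom_params(seed = 4)
  set.seed(4); a <- place_montage(m, p)
  set.seed(4); b <- place_montage(m, p)
  set.seed(5); c_ <- place_montage(m, p)
  expect_identical(a$points, b$points)
  expect_gt(max(abs(a$points - c_$points)), 0)
})

test_that("zero-height bumps leave the mesh unchanged", {
  p <- phantom_params(mesh_vertices = 642, bump_height = 0)
  mesh <- make_head_mesh(p)
  out <- add_electrode_bumps(mesh, matrix(c(0, 0, 0.095), 1L), p)
  expect_equal(out$vertices, mesh$vertices, tolerance = 1e-12)
})

test_that("a single bump raises the apex by the bump height", {
  p <- phantom_params(ellipsoid_semiaxes = c(0.1, 0.1, 0.1),
                      mesh_vertices = 10242, center_offset = 0,
                      rim_relief_height = 0)
  sphere <- make_head_mesh(p)
  apex <- c(0, 0, 0.1)
  out <- add_electrode_bumps(sphere, matrix(apex, 1L), p)
  gain <- max(sqrt(rowSums(out$vertices^2))) - 0.1
  expect_lt(abs(gain - p$bump_height) / p$bump_height, 0.05)
  expect_true(mesh_topology(out)$closed)
})

test_that("overlapping bump centers trigger a warning and sum", {
  p <- phantom_params(ellipsoid_semiaxes = c(0.1, 0.1, 0.1),
                      mesh_vertices = 2562, center_offset = 0,
                      rim_relief_height = 0)
  sphere <- make_head_mesh(p)
  two <- rbind(c(0, 0, 0.1), c(0.004, 0, 0.0998))
  expect_warning(out <- add_electrode_bumps(sphere, two, p), "overlap")
  gain <- max(sqrt(rowSums(out$vertices^2))) - 0.1
  expect_gt(gain, p$bump_height)   # summed displacement exceeds one bump
})

test_that("posterior attenuation halves occipital apex displacement", {
  m <- quikcap64_montage()
  p <- phantom_params(posterior_attenuation = 0.5, n_dummies = 0L,
                      angular_jitter_sd = 0, seed = 6)
  set.seed(6)
  ph <- make_phantom(m, p)
  truth0 <- place_montage(m, p, jitter = FALSE)
  labs <- ph$electrodes$labels
  # apex = surface + height*normal, so attenuated sites sit lower
  d <- sqrt(rowSums((ph$electrodes$points - truth0$points)^2))
  expect_equal(unname(d[match("OZ", labs)]),
               unname(d[match("FZ", labs)]) / 2, tolerance = 1e-6)
})

test_that("cohorts are reproducible, distinct, and complete", {
  m <- quikcap64_montage()
  p <- phantom_params(seed = 12)
  co1 <- make_cohort(4, m, p)
  co2 <- make_cohort(4, m, p)
  for (i in 1:4) {
    expect_identical(co1[[i]]$electrodes$points, co2[[i]]$electrodes$points)
    expect_equal(nrow(co1[[i]]$electrodes$points), 64L)
  }
  expect_gt(max(abs(co1[[1]]$electrodes$points -
                    co1[[2]]$electrodes$points)), 0)
})

test_that("default phantom meshes stay closed with bumps and dummies", {
  ph <- default_phantom(1L)
  expect_true(mesh_topology(ph$mesh)$closed)
  expect_equal(euler_characteristic(ph$mesh), 2L)
  expect_equal(nrow(ph$dummy_positions), 15L)
  expect_true(all(ph$electrodes$points[, 3L] > 0))
})

test_that("ground truth passes montage symmetry within the jitter bound", {
  m <- quikcap64_montage()
  p <- phantom_params(seed = 13)
  set.seed(13)
  truth <- place_montage(m, p)
  labs <- truth$labels
  for (k in seq_len(nrow(m$symmetric_pairs))) {
    a <- truth$points[match(m$symmetric_pairs[k, 1L], labs), ]
    b <- truth$points[match(m$symmetric_pairs[k, 2L], labs), ]
    # mirrored within a few jitter SDs (rigid part cancels only partly)
    expect_lt(sqrt(sum((a - b * c(1, -1, 1))^2)),
              6 * p$angular_jitter_sd * 0.1 + 0.002)
  }
})
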