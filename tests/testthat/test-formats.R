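# Mesh and electrode file formats, SCS transform.

test_that("minimal OFF tetrahedron reads with correct counts", {
  path <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 0",
               "1 1 1", "1 -1 -1", "-1 1 -1", "-1 -1 1",
               "3 0 1 2", "3 0 3 1", "3 0 2 3", "3 1 3 2"), path)
  mesh <- read_mesh(path, "off")
  expect_equal(nrow(mesh$vertices), 4L)
  expect_equal(nrow(mesh$faces), 4L)
  expect_equal(mesh$frame, "unknown")
})

test_that("meshes round-trip through every dialect", {
  mesh <- icosphere(2, radius = 0.1)
  for (d in c("ply", "ply_binary", "off", "stl", "freesurfer")) {
    path <- withr::local_tempfile(fileext = paste0(".", sub("_.*", "", d)))
    write_mesh(mesh, path, d)
    back <- read_mesh(path, switch(d, ply_binary = "ply",
                                   d))
    if (d == "stl") {
      # STL re-derives topology from duplicated vertex triples; compare
      # geometry by nearest-neighbour distance
      expect_equal(nrow(back$vertices), nrow(mesh$vertices))
      dm <- as.matrix(stats::dist(rbind(mesh$vertices, back$vertices)))
      nn <- apply(dm[seq_len(nrow(mesh$vertices)),
                     nrow(mesh$vertices) + seq_len(nrow(back$vertices))],
                  1L, min)
      expect_lt(max(nn), 1e-6)
    } else {
      expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
      expect_equal(back$faces, mesh$faces)
    }
  }
})

test_that("out-of-range face index is rejected with its location", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 10",
               "property float x", "property float y", "property float z",
               "element face 2",
               "property list uchar int vertex_indices",
               "end_header",
               sprintf("%d %d %d", 0:9, 1:10, 2:11),
               "3 0 1 2", "3 0 1 99"), path)
  expect_error(read_mesh(path, "ply"), "face")
})

test_that("degenerate faces are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(triangle_mesh(v, rbind(c(1, 2, 3), c(2, 2, 4))),
               "degenerate")
})

test_that("to_scs maps canonical fiducials to the identity frame", {
  fid <- fiducial_triplet(c(0.1, 0, 0), c(0, 0.07, 0), c(0, -0.07, 0))
  pts <- matrix(rnorm(30), 10L, 3L)
  es <- electrode_set(pts)
  out <- to_scs(es, fid)
  expect_equal(out$points, es$points, tolerance = 1e-12)
  expect_equal(out$frame, "SCS")
})

test_that("to_scs is rigid and puts the preauricular midpoint at origin", {
  set.seed(7)
  for (rep in 1:5) {
    nas <- rnorm(3); lpa <- rnorm(3); rpa <- rnorm(3)
    fid <- tryCatch(fiducial_triplet(nas, lpa, rpa), error = function(e) NULL)
    if (is.null(fid)) next
    pts <- matrix(rnorm(24), 8L, 3L)
    out <- to_scs(electrode_set(pts), fid)
    expect_lt(max(abs(dist(out$points) - dist(pts))), 1e-9)
    mid <- to_scs(electrode_set(rbind((lpa + rpa) / 2, nas)), fid)
    expect_lt(max(abs(mid$points[1L, ])), 1e-12)
    # nasion lands on the +x axis
    expect_lt(max(abs(mid$points[2L, 2:3])), 1e-9)
    expect_gt(mid$points[2L, 1L], 0)
  }
})

test_that("collinear fiducials are rejected", {
  expect_error(fiducial_triplet(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("sfp rows parse as labeled points in meters", {
  path <- withr::local_tempfile(fileext = ".sfp")
  writeLines(c("FPZ 0.08 0.0 0.05", "Cz 0.0 0.0 0.09"), path)
  es <- read_electrodes(path, "sfp")
  expect_equal(nrow(es$points), 2L)
  expect_equal(es$points[1L, ], c(x = 0.08, y = 0, z = 0.05))
  expect_equal(es$labels, c("FPZ", "CZ"))  # stored uppercase
})

test_that("bids electrodes.tsv with 64 rows reads fully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(name = sprintf("E%d", 1:64),
                   x = runif(64), y = runif(64), z = runif(64))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  es <- read_electrodes(path, "bids_tsv")
  expect_equal(nrow(es$points), 64L)
})

test_that("elc honors its unit line (mm value 80 becomes 0.080 m)", {
  path <- withr::local_tempfile(fileext = ".elc")
  writeLines(c("ReferenceLabel avg", "UnitPosition mm",
               "NumberPositions= 2", "Positions",
               "80 0 40", "0 80 40", "Labels", "FPZ", "CZ"), path)
  es <- read_electrodes(path, "elc")
  expect_equal(unname(es$points[1L, 1L]), 0.080, tolerance = 1e-9)
  expect_equal(es$labels, c("FPZ", "CZ"))
})

test_that("duplicate labels are rejected with the offender named", {
  path <- withr::local_tempfile(fileext = ".sfp")
  writeLines(c("CZ 0 0 1", "cz 0 1 0"), path)
  expect_error(read_electrodes(path, "sfp"), "CZ")
})

test_that("malformed electrode rows report a line number", {
  path <- withr::local_tempfile(fileext = ".sfp")
  writeLines(c("CZ 0 0 1", "FPZ 0 bad 0"), path)
  expect_error(read_electrodes(path, "sfp"), "line 2")
})

test_that("electrode sets round-trip through every dialect", {
  set.seed(3)
  es <- electrode_set(matrix(rnorm(64 * 3, sd = 0.05), 64L, 3L),
                      labels = sprintf("E%d", 1:64))
  for (d in c("sfp", "elc", "bids_tsv")) {
    path <- withr::local_tempfile(
      fileext = switch(d, sfp = ".sfp", elc = ".elc", ".tsv"))
    write_electrodes(es, path, d)
    back <- read_electrodes(path, d)
    expect_equal(back$labels, es$labels)
    expect_lt(max(abs(back$points - es$points)), 1e-6)
  }
})

test_that("unlabeled points get E<k> placeholders in sfp output", {
  es <- electrode_set(rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)))
  path <- withr::local_tempfile(fileext = ".sfp")
  expect_warning(write_electrodes(es, path, "sfp"), "placeholder")
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_match(lines[1L], "^E1 ")
})
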