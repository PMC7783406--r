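# Mesh and electrode-table file formats, and the fiducial-based subject
# coordinate system (SCS).

#' Fiducial triplet
#'
#' Nasion and left/right preauricular points, in meters, defining the
#' subject coordinate system.
#'
#' @param nasion,left_preauricular,right_preauricular 3-vectors, meters.
#' @return object of class `fiducial_triplet`.
#' @export
fiducial_triplet <- function(nasion, left_preauricular, right_preauricular) {
  f <- rbind(nasion = as.numeric(nasion),
             lpa = as.numeric(left_preauricular),
             rpa = as.numeric(right_preauricular))
  stopifnot(ncol(f) == 3L, all(is.finite(f)))
  v1 <- f["lpa", ] - f["nasion", ]
  v2 <- f["rpa", ] - f["nasion", ]
  cr <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
          v1[3L] * v2[1L] - v1[1L] * v2[3L],
          v1[1L] * v2[2L] - v1[2L] * v2[1L])
  if (sqrt(sum(cr^2)) < 1e-12) stop("fiducial points are collinear")
  structure(list(nasion = f["nasion", ], left_preauricular = f["lpa", ],
                 right_preauricular = f["rpa", ]),
            class = "fiducial_triplet")
}

#' Transform into the subject coordinate system
#'
#' Rigidly maps a mesh or electrode set into the SCS: origin at the
#' midpoint of the preauricular points, +x through the nasion's
#' projection, +y toward the left preauricular point, +z superior.
#' Pairwise distances are preserved exactly (rotation + translation
#' only).
#'
#' @param x a `triangle_mesh` or [electrode_set()].
#' @param fiducials a [fiducial_triplet()] expressed in the same frame as
#'   `x`.
#' @return `x` transformed, with `frame = "SCS"`.
#' @export
to_scs <- function(x, fiducials) {
  stopifnot(inherits(fiducials, "fiducial_triplet"))
  origin <- (fiducials$left_preauricular + fiducials$right_preauricular) / 2
  xax <- fiducials$nasion - origin
  yraw <- fiducials$left_preauricular - fiducials$right_preauricular
  # orthogonalize y against x, z completes the right-handed frame
  xax <- xax / sqrt(sum(xax^2))
  yax <- yraw - sum(yraw * xax) * xax
  ny <- sqrt(sum(yax^2))
  if (ny < 1e-12) stop("fiducial points are collinear")
  yax <- yax / ny
  zax <- c(xax[2L] * yax[3L] - xax[3L] * yax[2L],
           xax[3L] * yax[1L] - xax[1L] * yax[3L],
           xax[1L] * yax[2L] - xax[2L] * yax[1L])
  R <- rbind(xax, yax, zax)
  tf <- function(p) sweep(p, 2L, origin) %*% t(R)
  if (inherits(x, "triangle_mesh")) {
    triangle_mesh(tf(x$vertices), x$faces, frame = "SCS")
  } else if (inherits(x, "electrode_set")) {
    electrode_set(tf(x$points), labels = x$labels, frame = "SCS")
  } else {
    stop("to_scs() expects a triangle_mesh or electrode_set")
  }
}

# ---- mesh readers/writers -------------------------------------------------

#' Read a triangulated surface mesh
#'
#' Supports ASCII/binary little-endian PLY, OFF, binary STL and the
#' FreeSurfer binary triangle surface format.  Returned meshes carry
#' `frame = "unknown"`; apply [to_scs()] if fiducials are available.
#'
#' @param path file path.
#' @param dialect `"ply"`, `"off"`, `"stl"` or `"freesurfer"`; default
#'   guessed from the file extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, dialect = c("auto", "ply", "off", "stl",
                                        "freesurfer")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, ply = "ply", off = "off", stl = "stl",
                      "freesurfer")
  }
  out <- switch(dialect,
                ply = read_ply(path),
                off = read_off(path),
                stl = read_stl(path),
                freesurfer = read_fs_surface(path))
  tryCatch(triangle_mesh(out$vertices, out$faces),
           error = function(e) {
             stop(sprintf("invalid %s mesh in %s: %s", dialect, path,
                          conditionMessage(e)))
           })
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1L]) != "OFF") stop("parse error (off): missing OFF header")
  counts <- as.integer(strsplit(lines[2L], "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  toks <- strsplit(lines[2L + seq_len(nv)], "\\s+")
  v <- t(vapply(toks, function(x) as.numeric(x[1:3]), numeric(3L)))
  ftoks <- strsplit(lines[2L + nv + seq_len(nf)], "\\s+")
  f <- t(vapply(ftoks, function(x) {
    k <- as.integer(x[1L])
    if (k != 3L) stop("parse error (off): non-triangular face")
    as.integer(x[2:4])
  }, integer(3L)))
  list(vertices = v, faces = f + 1L)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1L,
                   function(r) sprintf("%.9g %.9g %.9g", r[1], r[2], r[3])),
             con)
  writeLines(apply(mesh$faces - 1L, 1L,
                   function(r) sprintf("3 %d %d %d", r[1], r[2], r[3])), con)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ASCII lines up to end_header, even in binary files
  read_hdr_line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (!length(b)) stop("parse error (ply): truncated header")
      if (b == as.raw(10L)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  if (read_hdr_line() != "ply") stop("parse error (ply): missing magic")
  fmt <- NULL
  elements <- list()   # name -> list(count, props = list(name, type, list))
  cur <- NULL
  repeat {
    ln <- read_hdr_line()
    t <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (!length(t)) next
    if (t[1L] == "comment") next
    if (t[1L] == "format") {
      fmt <- t[2L]
    } else if (t[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = t[2L], count = as.integer(t[3L]), props = list())
    } else if (t[1L] == "property") {
      if (t[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = t[5L], type = t[4L], list = TRUE, count_type = t[3L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = t[3L], type = t[2L], list = FALSE)
      }
    } else if (t[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face)) {
    stop("parse error (ply): vertex/face elements missing")
  }
  if (identical(fmt, "ascii")) {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    nv <- elements$vertex$count
    nf <- elements$face$count
    pnames <- vapply(elements$vertex$props, `[[`, "", "name")
    vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    v <- t(vapply(vt, function(x)
      as.numeric(x[match(c("x", "y", "z"), pnames)]), numeric(3L)))
    ft <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    f <- t(vapply(seq_along(ft), function(i) {
      x <- ft[[i]]
      if (as.integer(x[1L]) != 3L) {
        stop(sprintf("parse error (ply): face %d is not a triangle", i))
      }
      as.integer(x[2:4])
    }, integer(3L)))
    list(vertices = v, faces = f + 1L)
  } else if (identical(fmt, "binary_little_endian")) {
    type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)
    read_scalar <- function(type) {
      sz <- type_size[[type]]
      what <- if (type %in% c("float", "float32", "double", "float64"))
        "numeric" else "integer"
      readBin(con, what, 1L, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    nv <- elements$vertex$count
    props <- elements$vertex$props
    v <- matrix(NA_real_, nv, 3L)
    pn <- vapply(props, `[[`, "", "name")
    for (i in seq_len(nv)) {
      vals <- vapply(props, function(p) as.numeric(read_scalar(p$type)), 0)
      v[i, ] <- vals[match(c("x", "y", "z"), pn)]
    }
    nf <- elements$face$count
    fp <- elements$face$props[[1L]]
    f <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      k <- as.integer(read_scalar(fp$count_type))
      if (k != 3L) stop(sprintf("parse error (ply): face %d is not a triangle", i))
      f[i, ] <- vapply(1:3, function(j) as.integer(read_scalar(fp$type)), 0L)
    }
    list(vertices = v, faces = f + 1L)
  } else {
    stop("parse error (ply): unsupported format ", fmt)
  }
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0"
           else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh$vertices, 1L,
                     function(r) sprintf("%.9g %.9g %.9g", r[1], r[2], r[3])),
               con)
    writeLines(apply(mesh$faces - 1L, 1L,
                     function(r) sprintf("3 %d %d %d", r[1], r[2], r[3])),
               con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    v <- t(mesh$vertices)
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
    f <- mesh$faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
    }
  }
}

write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  fg <- face_geometry(mesh)
  v <- mesh$vertices
  for (i in seq_len(nf)) {
    tri <- v[mesh$faces[i, ], , drop = FALSE]
    writeBin(as.numeric(fg$normals[i, ]), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(tri)), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(nf) || nf <= 0L) stop("parse error (stl): bad triangle count")
  tris <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) stop("parse error (stl): truncated file")
    tris[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3L, byrow = TRUE)
    readBin(con, "integer", 1L, size = 2L, endian = "little")
  }
  # merge exactly-duplicated vertices to recover shared topology
  key <- apply(tris, 1L, paste, collapse = " ")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- tris[uk, , drop = FALSE]
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeChar("created by eeglocate\n\n", con, eos = NULL)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4L, endian = "big")
}

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(255L, 255L, 254L))) {
    stop("parse error (freesurfer): bad magic number")
  }
  # comment terminated by \n\n
  prev <- as.raw(0L)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (!length(b)) stop("parse error (freesurfer): truncated header")
    if (b == as.raw(10L) && prev == as.raw(10L)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  v <- matrix(readBin(con, "numeric", nv * 3L, size = 4L, endian = "big"),
              ncol = 3L, byrow = TRUE)
  f <- matrix(readBin(con, "integer", nf * 3L, size = 4L, endian = "big"),
              ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f + 1L)
}

#' Write a triangulated surface mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param dialect `"ply"`, `"ply_binary"`, `"off"`, `"stl"` or
#'   `"freesurfer"`.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, dialect = c("ply", "ply_binary", "off",
                                               "stl", "freesurfer")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         ply = write_ply(mesh, path, binary = FALSE),
         ply_binary = write_ply(mesh, path, binary = TRUE),
         off = write_off(mesh, path),
         stl = write_stl(mesh, path),
         freesurfer = write_fs_surface(mesh, path))
  invisible(path)
}

# ---- electrode readers/writers -------------------------------------------

#' Read an electrode coordinate table
#'
#' Supported dialects: BESA `.sfp` (whitespace label x y z), ASA `.elc`
#' (honoring its `UnitPosition` line) and BIDS `electrodes.tsv`
#' (columns name, x, y, z).  Coordinates are converted to meters; `.sfp`
#' and BIDS files are assumed to be in meters unless `unit` says
#' otherwise.  Labels are stored uppercase.
#'
#' @param path file path.
#' @param dialect `"sfp"`, `"elc"` or `"bids_tsv"`; default guessed from
#'   the extension.
#' @param unit unit override for sfp/bids dialects: `"m"`, `"cm"` or
#'   `"mm"`.
#' @return an [electrode_set()] with `frame = "unknown"`.
#' @export
read_electrodes <- function(path, dialect = c("auto", "sfp", "elc",
                                              "bids_tsv"),
                            unit = c("m", "cm", "mm")) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("electrode file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, sfp = "sfp", elc = "elc", tsv = "bids_tsv",
                      stop("cannot guess electrode dialect from: ", path))
  }
  scale <- c(m = 1, cm = 0.01, mm = 0.001)[[unit]]
  out <- switch(dialect,
                sfp = read_sfp(path, scale),
                elc = read_elc(path),
                bids_tsv = read_bids_tsv(path, scale))
  electrode_set(out$points, labels = out$labels)
}

read_sfp <- function(path, scale) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad)) stop(sprintf("malformed row at line %d of %s",
                                bad[1L], path))
  labels <- vapply(toks, `[[`, "", 1L)
  xyz <- suppressWarnings(
    t(vapply(toks, function(x) as.numeric(x[2:4]), numeric(3L))))
  if (anyNA(xyz)) {
    stop(sprintf("malformed row at line %d of %s",
                 which(rowSums(is.na(xyz)) > 0L)[1L], path))
  }
  list(points = xyz * scale, labels = labels)
}

read_elc <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  unit_ln <- grep("^UnitPosition", lines, value = TRUE)
  scale <- 0.001  # elc defaults to millimeters
  if (length(unit_ln)) {
    u <- tolower(trimws(sub("^UnitPosition\\s*", "", unit_ln[1L])))
    scale <- switch(u, mm = 0.001, cm = 0.01, m = 1,
                    stop("unknown UnitPosition in elc: ", u))
  }
  pos_at <- grep("^Positions", lines)
  lab_at <- grep("^Labels", lines)
  if (!length(pos_at)) stop("parse error (elc): no Positions section")
  pos_lines <- lines[(pos_at[1L] + 1L):
                     (if (length(lab_at)) lab_at[1L] - 1L else length(lines))]
  pos_lines <- pos_lines[nzchar(pos_lines)]
  # rows may be "label : x y z" or plain "x y z"
  labels_inline <- rep(NA_character_, length(pos_lines))
  has_colon <- grepl(":", pos_lines, fixed = TRUE)
  labels_inline[has_colon] <- trimws(sub(":.*$", "", pos_lines[has_colon]))
  coords <- sub("^.*:", "", pos_lines)
  toks <- strsplit(trimws(coords), "\\s+")
  xyz <- suppressWarnings(
    t(vapply(toks, function(x) as.numeric(x[1:3]), numeric(3L))))
  if (anyNA(xyz)) {
    stop(sprintf("malformed row at line %d of %s",
                 pos_at[1L] + which(rowSums(is.na(xyz)) > 0L)[1L], path))
  }
  labels <- labels_inline
  if (length(lab_at)) {
    lab_lines <- lines[(lab_at[1L] + 1L):length(lines)]
    lab_lines <- lab_lines[nzchar(lab_lines)]
    labs <- unlist(strsplit(lab_lines, "\\s+"))
    if (length(labs) >= nrow(xyz)) labels <- labs[seq_len(nrow(xyz))]
  }
  list(points = xyz * scale, labels = labels)
}

read_bids_tsv <- function(path, scale) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("bids electrodes.tsv must have columns name, x, y, z")
  }
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (anyNA(xyz)) {
    stop(sprintf("malformed row at line %d of %s",
                 which(rowSums(is.na(xyz)) > 0L)[1L] + 1L, path))
  }
  list(points = xyz * scale, labels = df$name)
}

#' Write an electrode coordinate table
#'
#' Round-trips with [read_electrodes()] to within 1e-6 m.  Unlabeled
#' points in dialects that require names are written with `E<k>`
#' placeholders and a warning.
#'
#' @param set an [electrode_set()].
#' @param path output path.
#' @param dialect `"sfp"`, `"elc"` or `"bids_tsv"`; default guessed from
#'   the extension.
#' @return the path, invisibly.
#' @export
write_electrodes <- function(set, path, dialect = c("auto", "sfp", "elc",
                                                    "bids_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, sfp = "sfp", elc = "elc", tsv = "bids_tsv",
                      stop("cannot guess electrode dialect from: ", path))
  }
  labels <- set$labels
  n <- nrow(set$points)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (anyNA(labels)) {
    warning("unlabeled points written with E<k> placeholder labels")
    k <- which(is.na(labels))
    labels[k] <- paste0("E", seq_along(k))
  }
  p <- set$points
  if (dialect == "sfp") {
    writeLines(sprintf("%s %.9g %.9g %.9g", labels,
                       p[, 1L], p[, 2L], p[, 3L]), path)
  } else if (dialect == "elc") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# ASA electrode file", "ReferenceLabel avg",
                 "UnitPosition mm",
                 sprintf("NumberPositions= %d", n), "Positions"), con)
    writeLines(sprintf("%.6f %.6f %.6f",
                       p[, 1L] * 1000, p[, 2L] * 1000, p[, 3L] * 1000), con)
    writeLines("Labels", con)
    writeLines(labels, con)
  } else {
    df <- data.frame(name = labels, x = p[, 1L], y = p[, 2L], z = p[, 3L])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
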