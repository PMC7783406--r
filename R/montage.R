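# Montage specification: ordered label sequence, midline labels, symmetric
# left/right pairs, and canonical unit-sphere directions used by the
# phantom generator.

#' Montage specification
#'
#' Describes an electrode montage: the vendor channel sequence (used as the
#' tie-break order during label voting), the midline labels, the symmetric
#' left/right label pairs used for hemisphere disambiguation, and optional
#' canonical unit-sphere directions for phantom placement.
#'
#' @param ordered_labels character vector, the full channel sequence.
#' @param midline_labels subset of `ordered_labels` lying on the sagittal
#'   midline.
#' @param symmetric_pairs two-column character matrix (left, right).
#' @param anterior_midline,posterior_midline the two midline labels that
#'   define the midplane (defaults FPZ and OZ).
#' @param directions optional named list of unit 3-vectors (canonical
#'   directions on the unit sphere, SCS axes) for each label.
#' @return object of class `montage_spec`.
#' @export
montage_spec <- function(ordered_labels, midline_labels, symmetric_pairs,
                         anterior_midline = "FPZ", posterior_midline = "OZ",
                         directions = NULL) {
  ordered_labels <- toupper(ordered_labels)
  midline_labels <- toupper(midline_labels)
  symmetric_pairs <- matrix(toupper(symmetric_pairs), ncol = 2L,
                            dimnames = list(NULL, c("left", "right")))
  if (anyDuplicated(ordered_labels)) stop("duplicate labels in sequence")
  paired <- c(symmetric_pairs)
  if (any(paired %in% midline_labels)) {
    stop("symmetric pairs must be disjoint from midline labels")
  }
  missing <- setdiff(c(paired, midline_labels), ordered_labels)
  if (length(missing)) {
    stop("labels not in ordered sequence: ", paste(missing, collapse = ", "))
  }
  anterior_midline <- toupper(anterior_midline)
  posterior_midline <- toupper(posterior_midline)
  if (!all(c(anterior_midline, posterior_midline) %in% midline_labels)) {
    stop("midplane anchor labels must be midline labels")
  }
  if (!is.null(directions)) {
    names(directions) <- toupper(names(directions))
    bad <- setdiff(ordered_labels, names(directions))
    if (length(bad)) {
      stop("missing canonical direction for label(s): ",
           paste(bad, collapse = ", "))
    }
    directions <- lapply(directions, function(d) {
      d <- as.numeric(d)
      d / sqrt(sum(d^2))
    })
  }
  structure(list(ordered_labels = ordered_labels,
                 midline_labels = midline_labels,
                 symmetric_pairs = symmetric_pairs,
                 anterior_midline = anterior_midline,
                 posterior_midline = posterior_midline,
                 directions = directions),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("montage_spec: %d labels (%d midline, %d symmetric pairs)\n",
              length(x$ordered_labels), length(x$midline_labels),
              nrow(x$symmetric_pairs)))
  cat(sprintf("  midplane anchors: %s (anterior) / %s (posterior)\n",
              x$anterior_midline, x$posterior_midline))
  if (!is.null(x$directions)) cat("  canonical directions: present\n")
  invisible(x)
}

# For a label, the other member of its symmetric pair (or NA).
pair_partner <- function(montage, label) {
  p <- montage$symmetric_pairs
  i <- match(label, p[, "left"])
  if (!is.na(i)) return(p[i, "right"])
  i <- match(label, p[, "right"])
  if (!is.na(i)) return(p[i, "left"])
  NA_character_
}

# TRUE for the left member of a pair; NA for unpaired labels.
is_left_label <- function(montage, label) {
  p <- montage$symmetric_pairs
  if (label %in% p[, "left"]) return(TRUE)
  if (label %in% p[, "right"]) return(FALSE)
  NA
}

#' Read a montage from a JSON config
#'
#' The JSON carries keys `ordered_labels`, `midline_labels`,
#' `symmetric_pairs` (array of two-element arrays, left then right),
#' `anterior_midline`, `posterior_midline` and optionally `directions`
#' (label -> unit 3-vector).
#'
#' @param path path to the JSON file.
#' @return a [montage_spec()].
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dirs <- NULL
  if (!is.null(j$directions)) {
    dirs <- if (is.data.frame(j$directions)) {
      as.list(as.data.frame(t(j$directions)))
    } else if (is.matrix(j$directions)) {
      stats::setNames(lapply(seq_len(nrow(j$directions)),
                             function(i) j$directions[i, ]),
                      rownames(j$directions))
    } else {
      lapply(j$directions, as.numeric)
    }
  }
  pairs <- j$symmetric_pairs
  if (!is.matrix(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) as.character(p)))
  }
  montage_spec(j$ordered_labels, j$midline_labels, pairs,
               anterior_midline = j$anterior_midline %||% "FPZ",
               posterior_midline = j$posterior_midline %||% "OZ",
               directions = dirs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged 64-channel cap montage
#'
#' The montage shipped with the package: a 64-channel layout in the style
#' of an MR-compatible Quik-Cap (8 midline labels, 28 symmetric pairs
#' including the mastoids M1/M2 and cerebellar CB1/CB2 sites), with
#' canonical unit-sphere directions built from standard 10-10 angular
#' coordinates compressed toward the vertex so every site sits above the
#' fiducial plane.  The channel sequence is the standard vendor order and
#' can be overridden with a user montage JSON.
#'
#' @return a [montage_spec()] with canonical directions.
#' @export
quikcap64_montage <- function() {
  path <- system.file("extdata", "quikcap64.json", package = "eeglocate")
  if (path == "" || !file.exists(path)) {
    # during development (package not installed) fall back to source tree
    path <- file.path("inst", "extdata", "quikcap64.json")
  }
  read_montage(path)
}
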