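# Electrode coordinate sets.

#' Electrode coordinate set
#'
#' A set of electrode positions in meters, optionally labeled, tagged with
#' a coordinate-frame label.  Labels are stored uppercase so matching is
#' case-insensitive; duplicate non-empty labels are rejected.
#'
#' @param points n x 3 numeric matrix of coordinates in meters.
#' @param labels optional character vector of length n; `NA` or `""`
#'   marks an unlabeled point.
#' @param frame `"SCS"` or `"unknown"`.
#' @return object of class `electrode_set`.
#' @export
electrode_set <- function(points, labels = NULL,
                          frame = c("unknown", "SCS")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(points) < 1L) stop("electrode set must contain at least 1 point")
  if (!all(is.finite(points))) stop("electrode coordinates must be finite")
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(points))
    labels <- toupper(as.character(labels))
    labels[labels == ""] <- NA_character_
    nonempty <- labels[!is.na(labels)]
    dup <- unique(nonempty[duplicated(nonempty)])
    if (length(dup)) {
      stop("duplicate electrode labels: ", paste(dup, collapse = ", "))
    }
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, labels = labels, frame = frame),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  n <- nrow(x$points)
  nl <- if (is.null(x$labels)) 0L else sum(!is.na(x$labels))
  cat(sprintf("electrode_set: %d points (%d labeled), frame=%s\n",
              n, nl, x$frame))
  invisible(x)
}

#' @export
as.data.frame.electrode_set <- function(x, ...) {
  data.frame(label = if (is.null(x$labels)) NA_character_ else x$labels,
             x = x$points[, 1L], y = x$points[, 2L], z = x$points[, 3L],
             stringsAsFactors = FALSE)
}
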