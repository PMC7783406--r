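# Distance-profile electrode labeling: match an unlabeled electrode set
# against labeled templates by Pearson correlation of sorted
# inter-electrode distance vectors, vote across templates, then resolve
# left/right ambiguity against the FPZ-OZ midplane.

#' Distance profile of one electrode
#'
#' The Euclidean distances from electrode `i` to every other electrode,
#' sorted in descending order.  Because sorting discards identity, the
#' profile is invariant under any rigid motion of the whole set — it is
#' the coordinate-free fingerprint used for labeling.
#'
#' @param points n x 3 coordinate matrix (n >= 2).
#' @param i electrode index.
#' @return object of class `distance_profile`: list with `values`
#'   (length n-1, non-increasing) and `owner_index`.
#' @export
distance_profile <- function(points, i) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 2, i >= 1, i <= n)
  d <- sqrt(colSums((t(points[-i, , drop = FALSE]) - points[i, ])^2))
  if (any(d == 0)) {
    j <- setdiff(seq_len(n), i)[which(d == 0)[1L]]
    stop(sprintf("electrodes %d and %d are coincident", i, j))
  }
  structure(list(values = sort(d, decreasing = TRUE),
                 owner_index = as.integer(i)),
            class = "distance_profile")
}

# All n profiles as an n x (n-1) matrix of descending-sorted distances.
profile_matrix <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  dm <- as.matrix(stats::dist(points))
  if (any(dm[upper.tri(dm)] == 0)) {
    idx <- which(dm == 0 & upper.tri(dm), arr.ind = TRUE)[1L, ]
    stop(sprintf("electrodes %d and %d are coincident", idx[1L], idx[2L]))
  }
  out <- matrix(0, n, n - 1L)
  for (i in seq_len(n)) {
    out[i, ] <- sort(dm[i, -i], decreasing = TRUE)
  }
  out
}

#' Pearson correlation of two distance profiles
#'
#' @param a,b `distance_profile` objects (or bare numeric vectors) of
#'   equal length.
#' @return Pearson r in \[-1, 1\]; 0 (with a warning) if either profile
#'   has zero variance.
#' @export
profile_correlation <- function(a, b) {
  av <- if (inherits(a, "distance_profile")) a$values else as.numeric(a)
  bv <- if (inherits(b, "distance_profile")) b$values else as.numeric(b)
  if (length(av) != length(bv)) stop("profile length mismatch")
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    warning("zero-variance distance profile; correlation set to 0")
    return(0)
  }
  stats::cor(av, bv)
}

#' Match an unlabeled set against one labeled template
#'
#' For every unlabeled electrode, proposes the label of the template
#' electrode whose distance profile correlates best with its own.
#' Different unlabeled electrodes may receive the same proposal at this
#' stage; conflicts are resolved later by voting and symmetry rules.
#' Correlation ties are broken by the earlier label in the montage's
#' sequential order.
#'
#' @param unlabeled an [electrode_set()] (labels ignored).
#' @param template a fully labeled [electrode_set()] of the same size.
#' @param montage a [montage_spec()] (for the tie-break order).
#' @return list with `labels` (proposed label per unlabeled electrode)
#'   and `correlations` (the winning r per electrode).
#' @export
match_single_template <- function(unlabeled, template, montage) {
  n <- nrow(unlabeled$points)
  if (nrow(template$points) != n) {
    stop(sprintf("template has %d electrodes but unlabeled set has %d",
                 nrow(template$points), n))
  }
  if (is.null(template$labels) || anyNA(template$labels)) {
    stop("template must be fully labeled")
  }
  pu <- profile_matrix(unlabeled$points)
  pt <- profile_matrix(template$points)
  r <- stats::cor(t(pu), t(pt))   # n x n: r[i, j] = cor(unlabeled i, template j)
  seq_pos <- match(template$labels, montage$ordered_labels)
  seq_pos[is.na(seq_pos)] <- length(montage$ordered_labels) + 1L
  labels <- character(n)
  best_r <- numeric(n)
  for (i in seq_len(n)) {
    ri <- r[i, ]
    top <- max(ri)
    cand <- which(ri >= top - 1e-12)
    j <- cand[which.min(seq_pos[cand])]
    labels[i] <- template$labels[j]
    best_r[i] <- ri[j]
  }
  list(labels = labels, correlations = best_r)
}

#' Define the sagittal midplane from FPZ and OZ
#'
#' The vertical plane through the electrodes labeled with the montage's
#' anterior and posterior midline anchors (FPZ and OZ by default).  Its
#' unit normal is `(OZ - FPZ) x z-hat` normalized, so the positive side
#' is the subject's left (+y in SCS).
#'
#' @param labels current label assignment (character, NA = unlabeled).
#' @param points n x 3 coordinates.
#' @param montage a [montage_spec()].
#' @return list with `point` (on the plane) and `normal` (unit 3-vector).
#' @export
define_midplane <- function(labels, points, montage) {
  a <- which(labels == montage$anterior_midline)
  p <- which(labels == montage$posterior_midline)
  if (length(a) != 1L || length(p) != 1L) {
    stop(sprintf(
      "midplane undefined: need exactly one %s and one %s (found %d and %d)",
      montage$anterior_midline, montage$posterior_midline,
      length(a), length(p)))
  }
  fpz <- points[a, ]
  oz <- points[p, ]
  ax <- oz - fpz
  nrm <- c(ax[2L], -ax[1L], 0)   # (ax x zhat)
  len <- sqrt(sum(nrm^2))
  if (len == 0) stop("midplane undefined: anchors are vertically aligned")
  # ensure positive side is +y (subject's left) for an anterior anchor
  nrm <- nrm / len
  if (nrm[2L] < 0) nrm <- -nrm
  list(point = fpz, normal = nrm)
}

#' Side of the midplane
#'
#' @param points n x 3 coordinates (or a single 3-vector).
#' @param midplane from [define_midplane()].
#' @return integer vector: +1 left, -1 right, 0 exactly on the plane.
#' @export
midplane_side <- function(points, midplane) {
  points <- matrix(as.numeric(points), ncol = 3L)
  s <- (points[, 1L] - midplane$point[1L]) * midplane$normal[1L] +
       (points[, 2L] - midplane$point[2L]) * midplane$normal[2L] +
       (points[, 3L] - midplane$point[3L]) * midplane$normal[3L]
  s[abs(s) < 1e-12] <- 0
  as.integer(sign(s))
}

#' Resolve left/right label ambiguity against the midplane
#'
#' Symmetric pair members have nearly identical distance profiles, so a
#' proposal of, say, C1 may really be C2.  Resolution: (1) every electrode
#' carrying a paired label is re-labeled to the pair member matching its
#' side of the midplane; (2) if two electrodes then share a label, they
#' are mapped one per side (the farther-left keeps the left label);
#' (3) if `duplicate_unlabel_threshold` or more electrodes share a label,
#' all of them are unlabeled.  Midline labels are never flipped, but
#' midline duplicates beyond the best-supported one are unlabeled so the
#' final assignment stays unique.
#'
#' @param labels proposed labels (character, NA allowed).
#' @param points n x 3 coordinates.
#' @param midplane from [define_midplane()].
#' @param montage a [montage_spec()].
#' @param duplicate_unlabel_threshold duplicate count at which all
#'   carriers are unlabeled (default 3).
#' @param support optional numeric support per electrode (vote counts or
#'   correlations) used to rank duplicate midline claims.
#' @return list with `labels` (corrected, NA where unresolved) and
#'   `unresolved` (data.frame index/reason).
#' @export
resolve_symmetry <- function(labels, points, midplane, montage,
                             duplicate_unlabel_threshold = 3L,
                             support = NULL) {
  n <- length(labels)
  if (is.null(support)) support <- rep(0, n)
  side <- midplane_side(points, midplane)
  out <- toupper(labels)
  unresolved <- data.frame(index = integer(0), reason = character(0))
  # step 0: a proposal shared by >= threshold electrodes cannot be mapped
  # onto a two-member pair at all — unlabel all carriers up front
  tal <- table(out[!is.na(out)])
  for (lb in names(tal)[tal >= duplicate_unlabel_threshold]) {
    idx <- which(out == lb)
    out[idx] <- NA
    unresolved <- rbind(unresolved,
                        data.frame(index = idx,
                                   reason = "triple_duplicate"))
  }
  # step 1: flip paired labels to the member matching the electrode's side
  for (i in seq_len(n)) {
    lb <- out[i]
    if (is.na(lb)) next
    partner <- pair_partner(montage, lb)
    if (is.na(partner)) next
    left <- isTRUE(is_left_label(montage, lb))
    want_left <- side[i] > 0
    if (side[i] == 0) next
    if (left != want_left) out[i] <- partner
  }
  # steps 2-3: duplicates remaining after the side flip
  dup_labels <- unique(out[!is.na(out)][duplicated(out[!is.na(out)])])
  for (lb in dup_labels) {
    idx <- which(out == lb)
    k <- length(idx)
    if (k >= duplicate_unlabel_threshold) {
      out[idx] <- NA
      unresolved <- rbind(unresolved,
                          data.frame(index = idx,
                                     reason = "triple_duplicate"))
      next
    }
    partner <- pair_partner(montage, lb)
    if (!is.na(partner) && k == 2L && !(partner %in% out)) {
      # map one per side: farther-left keeps the left member
      left_member <- if (isTRUE(is_left_label(montage, lb))) lb else partner
      right_member <- if (left_member == lb) partner else lb
      s <- midplane_signed(points[idx, , drop = FALSE], midplane)
      lefti <- idx[which.max(s)]
      righti <- idx[which.min(s)]
      out[lefti] <- left_member
      out[righti] <- right_member
    } else {
      # midline (or blocked pair) duplicate: keep the best-supported claim
      keep <- idx[order(-support[idx], idx)][1L]
      lose <- setdiff(idx, keep)
      out[lose] <- NA
      unresolved <- rbind(unresolved,
                          data.frame(index = lose,
                                     reason = "no_majority_conflict"))
    }
  }
  list(labels = out, unresolved = unresolved)
}

# Signed distance from the midplane (positive = left).
midplane_signed <- function(points, midplane) {
  points <- matrix(as.numeric(points), ncol = 3L)
  (points[, 1L] - midplane$point[1L]) * midplane$normal[1L] +
    (points[, 2L] - midplane$point[2L]) * midplane$normal[2L] +
    (points[, 3L] - midplane$point[3L]) * midplane$normal[3L]
}

#' Label an electrode set by multi-template voting
#'
#' Runs [match_single_template()] against every template, tallies the
#' proposed labels per electrode, and assigns the plurality winner (ties
#' broken by the montage's sequential order).  The voted assignment is
#' then passed once through midplane symmetry resolution
#' ([resolve_symmetry()]).
#'
#' @param unlabeled an [electrode_set()].
#' @param templates list of labeled [electrode_set()]s (>= 1), all the
#'   same size as `unlabeled`.
#' @param montage a [montage_spec()].
#' @param duplicate_unlabel_threshold see [resolve_symmetry()].
#' @return object of class `labeling_result`: list with `assigned`
#'   (character, NA = unlabeled), `votes` (list of tally tables),
#'   `correlations` (n x n_templates matrix of winning r), `unresolved`
#'   (data.frame index/reason) and `n_templates`.
#' @export
vote_labels <- function(unlabeled, templates, montage,
                        duplicate_unlabel_threshold = 3L) {
  if (inherits(templates, "electrode_set")) templates <- list(templates)
  stopifnot(length(templates) >= 1L)
  n <- nrow(unlabeled$points)
  props <- matrix(NA_character_, n, length(templates))
  cors <- matrix(NA_real_, n, length(templates))
  for (t in seq_along(templates)) {
    m <- match_single_template(unlabeled, templates[[t]], montage)
    props[, t] <- m$labels
    cors[, t] <- m$correlations
  }
  seq_pos <- function(lb) {
    p <- match(lb, montage$ordered_labels)
    ifelse(is.na(p), length(montage$ordered_labels) + 1L, p)
  }
  assigned <- rep(NA_character_, n)
  votes <- vector("list", n)
  support <- numeric(n)
  for (i in seq_len(n)) {
    pi <- props[i, !is.na(props[i, ])]
    if (length(pi) == 0L) next
    tal <- table(pi)
    votes[[i]] <- tal
    top <- max(tal)
    cand <- names(tal)[tal == top]
    assigned[i] <- cand[which.min(seq_pos(cand))]
    support[i] <- top
  }
  never <- which(is.na(assigned))
  midplane <- define_midplane(assigned, unlabeled$points, montage)
  res <- resolve_symmetry(assigned, unlabeled$points, midplane, montage,
                          duplicate_unlabel_threshold,
                          support = support)
  unresolved <- res$unresolved
  if (length(never)) {
    unresolved <- rbind(unresolved,
                        data.frame(index = never,
                                   reason = "never_proposed"))
  }
  unresolved <- unresolved[order(unresolved$index), , drop = FALSE]
  rownames(unresolved) <- NULL
  structure(list(assigned = res$labels, votes = votes,
                 correlations = cors, unresolved = unresolved,
                 n_templates = length(templates)),
            class = "labeling_result")
}

#' @export
print.labeling_result <- function(x, ...) {
  n <- length(x$assigned)
  cat(sprintf("labeling_result: %d electrodes, %d templates, %d labeled, %d unresolved\n",
              n, x$n_templates, sum(!is.na(x$assigned)),
              nrow(x$unresolved)))
  if (nrow(x$unresolved)) {
    tab <- table(x$unresolved$reason)
    cat("  unresolved:", paste(sprintf("%s x%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.labeling_result <- function(object, ...) {
  df <- data.frame(index = seq_along(object$assigned),
                   label = object$assigned,
                   mean_r = rowMeans(object$correlations, na.rm = TRUE))
  df
}
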