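# Scoring: detection rate of localization against ground truth, TP/FP/FN
# of labeling, and the multi-template cohort experiment.

#' Detection metrics for localized candidates
#'
#' Matches candidates to true electrode positions one-to-one by greedy
#' nearest pairing (smallest distances first) under a tolerance, then
#' reports the detection rate (matched / true) and the count of extra
#' (unmatched) candidates.
#'
#' @param cands a `candidate_set` (or an [electrode_set()]).
#' @param truth a labeled or unlabeled [electrode_set()] of true
#'   positions.
#' @param tolerance matching tolerance in meters (default 0.005, about
#'   half an electrode diameter — a numeric surrogate for the visual
#'   inspection that usually defines ground truth).
#' @return object of class `detection_report`: list with
#'   `detection_rate`, `n_detected`, `n_true`, `n_extra`,
#'   `match_tolerance` and `matches` (data.frame candidate_index,
#'   true_index, true_label, distance).
#' @export
detection_metrics <- function(cands, truth, tolerance = 0.005) {
  stopifnot(tolerance > 0)
  cp <- cands$points
  tp <- truth$points
  nc <- nrow(cp)
  nt <- nrow(tp)
  matches <- data.frame(candidate_index = integer(0), true_index = integer(0),
                        true_label = character(0), distance = numeric(0))
  if (nc > 0L && nt > 0L) {
    d <- outer(seq_len(nc), seq_len(nt),
               Vectorize(function(i, j) sqrt(sum((cp[i, ] - tp[j, ])^2))))
    ord <- order(d)
    used_c <- logical(nc)
    used_t <- logical(nt)
    for (k in ord) {
      if (d[k] > tolerance) break
      i <- (k - 1L) %% nc + 1L
      j <- (k - 1L) %/% nc + 1L
      if (used_c[i] || used_t[j]) next
      used_c[i] <- TRUE
      used_t[j] <- TRUE
      matches <- rbind(matches, data.frame(
        candidate_index = i, true_index = j,
        true_label = if (!is.null(truth$labels)) truth$labels[j]
                     else NA_character_,
        distance = d[k]))
    }
  }
  n_det <- nrow(matches)
  structure(list(detection_rate = n_det / nt,
                 n_detected = n_det,
                 n_true = nt,
                 n_extra = nc - n_det,
                 match_tolerance = tolerance,
                 matches = matches),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: %d/%d detected (%.2f%%), %d extra, tol %.1f mm\n",
              x$n_detected, x$n_true, 100 * x$detection_rate, x$n_extra,
              1000 * x$match_tolerance))
  invisible(x)
}

#' Labeling accuracy metrics
#'
#' TP = labeled and correct, FP = labeled but wrong, FN = unlabeled.
#' Percentages are over the full electrode count.
#'
#' @param result a `labeling_result` (or a bare character vector of
#'   assigned labels, NA = unlabeled).
#' @param truth_labels character vector of true labels.
#' @return object of class `labeling_report`: list with `tp_pct`,
#'   `fp_pct`, `fn_pct`, counts, and `per_electrode` (data.frame).
#' @export
labeling_metrics <- function(result, truth_labels) {
  assigned <- if (inherits(result, "labeling_result")) result$assigned
              else as.character(result)
  truth_labels <- toupper(truth_labels)
  n <- length(truth_labels)
  if (length(assigned) != n) stop("assigned and truth lengths differ")
  assigned <- toupper(assigned)
  tp <- sum(!is.na(assigned) & assigned == truth_labels)
  fn <- sum(is.na(assigned))
  fp <- n - tp - fn
  per <- data.frame(label = truth_labels,
                    assigned = assigned,
                    correct = !is.na(assigned) & assigned == truth_labels,
                    stringsAsFactors = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, n = n,
                 tp_pct = 100 * tp / n,
                 fp_pct = 100 * fp / n,
                 fn_pct = 100 * fn / n,
                 per_electrode = per),
            class = "labeling_report")
}

#' @export
print.labeling_report <- function(x, ...) {
  cat(sprintf("labeling_report: TP %.2f%%  FP %.2f%%  FN %.2f%% (n=%d)\n",
              x$tp_pct, x$fp_pct, x$fn_pct, x$n))
  invisible(x)
}

#' Multi-template labeling experiment over a cohort
#'
#' Leave-one-out evaluation of multi-template labeling over a cohort:
#' every subject in turn is treated as unlabeled and labeled using
#' combinations of the remaining subjects as templates; TP/FP/FN are
#' aggregated per subject.  All single-template pairs are evaluated; for
#' larger template counts a seeded random sample of `n_combos`
#' combinations per subject is drawn, since the combination count grows
#' combinatorially.  Runs whose midplane cannot be defined (no unique
#' FPZ/OZ) are excluded and counted, and the excluded fraction is
#' reported alongside the aggregates.
#'
#' @param cohort list of subjects, each with an `electrodes` element
#'   (labeled [electrode_set()]), e.g. from [make_cohort()].
#' @param n_templates templates per labeling run (typically 1, 3 or 5).
#' @param montage a [montage_spec()].
#' @param n_combos maximum template combinations per subject for
#'   `n_templates > 1` (default 20).
#' @param seed RNG seed for combination sampling.
#' @return object of class `cohort_experiment`: list with `per_subject`
#'   (data.frame subject, n_runs, tp_pct, fp_pct, fn_pct), overall
#'   `mean_tp`, `mean_fp`, `mean_fn`, `sd_tp`, `n_runs`, `n_excluded`
#'   and `excluded_pct`.
#' @export
cohort_experiment <- function(cohort, n_templates = 1L,
                              montage = quikcap64_montage(),
                              n_combos = 20L, seed = 1L) {
  ns <- length(cohort)
  stopifnot(ns > n_templates)
  sets <- lapply(cohort, function(s) s$electrodes)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  per <- data.frame()
  n_runs <- 0L
  n_excluded <- 0L
  for (s in seq_len(ns)) {
    truth <- sets[[s]]
    unlab <- electrode_set(truth$points, frame = truth$frame)
    others <- setdiff(seq_len(ns), s)
    combos <- if (n_templates == 1L) {
      lapply(others, function(o) o)
    } else {
      all_n <- choose(length(others), n_templates)
      if (all_n <= n_combos) {
        asplit(t(utils::combn(others, n_templates)), 1L)
      } else {
        lapply(seq_len(n_combos), function(k) sort(sample(others, n_templates)))
      }
    }
    tps <- fps <- fns <- numeric(0)
    for (cmb in combos) {
      res <- tryCatch(
        vote_labels(unlab, sets[cmb], montage),
        error = function(e) {
          if (grepl("midplane undefined", conditionMessage(e))) NULL
          else stop(e)
        })
      if (is.null(res)) {
        n_excluded <- n_excluded + 1L
        next
      }
      n_runs <- n_runs + 1L
      m <- labeling_metrics(res, truth$labels)
      tps <- c(tps, m$tp_pct); fps <- c(fps, m$fp_pct); fns <- c(fns, m$fn_pct)
    }
    per <- rbind(per, data.frame(subject = s, n_runs = length(tps),
                                 tp_pct = mean(tps), fp_pct = mean(fps),
                                 fn_pct = mean(fns)))
  }
  total <- n_runs + n_excluded
  structure(list(per_subject = per,
                 n_templates = n_templates,
                 mean_tp = mean(per$tp_pct, na.rm = TRUE),
                 mean_fp = mean(per$fp_pct, na.rm = TRUE),
                 mean_fn = mean(per$fn_pct, na.rm = TRUE),
                 sd_tp = stats::sd(per$tp_pct, na.rm = TRUE),
                 n_runs = n_runs, n_excluded = n_excluded,
                 excluded_pct = if (total) 100 * n_excluded / total else 0),
            class = "cohort_experiment")
}

#' @export
print.cohort_experiment <- function(x, ...) {
  cat(sprintf(
    "cohort_experiment: %d templates, %d runs (%d excluded, %.3f%%)\n",
    x$n_templates, x$n_runs, x$n_excluded, x$excluded_pct))
  cat(sprintf("  mean TP %.2f%% (SD %.2f)  FP %.2f%%  FN %.2f%%\n",
              x$mean_tp, x$sd_tp, x$mean_fp, x$mean_fn))
  invisible(x)
}
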