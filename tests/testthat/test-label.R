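# Distance-profile labeling: profiles, correlation, template matching,
# midplane symmetry resolution, and voting.

test_that("distance profiles are descending-sorted hand-checked vectors", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  p <- distance_profile(pts, 1L)
  expect_equal(p$values, c(3, 1))
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  for (i in 1:4) {
    expect_equal(distance_profile(sq, i)$values, c(sqrt(2), 1, 1))
  }
})

test_that("profiles are invariant under rigid motion", {
  set.seed(9)
  pts <- matrix(rnorm(30), 10L, 3L)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- pts %*% R + matrix(c(5, -2, 1), 10L, 3L, byrow = TRUE)
  for (i in 1:10) {
    expect_equal(distance_profile(moved, i)$values,
                 distance_profile(pts, i)$values, tolerance = 1e-9)
  }
})

test_that("coincident electrodes are reported by index", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_error(distance_profile(pts, 2L), "2 and 3")
})

test_that("profile correlation handles linear and degenerate cases", {
  a <- distance_profile(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)), 1L)
  expect_equal(profile_correlation(a, a), 1)
  expect_equal(profile_correlation(c(3, 2, 1), -2 * c(3, 2, 1) + 5), -1)
  expect_equal(profile_correlation(c(3, 2, 1), c(6, 4, 2)), 1)
  expect_error(profile_correlation(c(1, 2), c(1, 2, 3)), "length mismatch")
  expect_warning(r0 <- profile_correlation(c(1, 1, 1), c(3, 2, 1)),
                 "zero-variance")
  expect_equal(r0, 0)
})

test_that("matching a set against itself is exact up to pair ambiguity", {
  m <- toy_montage()
  pts <- toy_points()
  tmpl <- electrode_set(pts, labels = m$ordered_labels)
  unlab <- electrode_set(pts)
  got <- match_single_template(unlab, tmpl, m)
  expect_equal(got$correlations, rep(1, 8))
  # mirror twins have identical profiles, so ties resolve to the earlier
  # (left) member; symmetry resolution later restores the right-side ones
  expect_equal(got$labels, c("FPZ", "F1", "F1", "C1", "C1", "P1", "P1",
                             "OZ"))
  res <- vote_labels(unlab, list(tmpl), m)
  expect_equal(res$assigned, m$ordered_labels)
})

test_that("matching is invariant to rigid motion of the unlabeled set", {
  m <- quikcap64_montage()
  params <- phantom_params(seed = 5)
  set.seed(5)
  tmpl <- place_montage(m, params)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- electrode_set(tmpl$points %*% R +
                           matrix(c(0.02, 0.01, -0.03), 64L, 3L,
                                  byrow = TRUE))
  got <- match_single_template(moved, tmpl, m)
  expect_equal(got$labels, tmpl$labels)
})

test_that("per-electrode proposals agree with the exhaustive assignment oracle", {
  # 8-electrode sub-montage, jittered subject vs template: compare the
  # greedy per-electrode argmax against the best global one-to-one
  # assignment maximizing summed correlation
  m <- toy_montage()
  tmpl_pts <- toy_points_perturbed()
  set.seed(21)
  subj_pts <- tmpl_pts + matrix(rnorm(24, sd = 0.001), 8L, 3L)
  tmpl <- electrode_set(tmpl_pts, labels = m$ordered_labels)
  unlab <- electrode_set(subj_pts)
  got <- match_single_template(unlab, tmpl, m)

  pu <- t(sapply(1:8, function(i) distance_profile(subj_pts, i)$values))
  pt <- t(sapply(1:8, function(i) distance_profile(tmpl_pts, i)$values))
  r <- stats::cor(t(pu), t(pt))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_s <- -Inf
  for (p in perms(1:8)) {
    s <- sum(r[cbind(1:8, p)])
    if (s > best_s) { best_s <- s; best <- p }
  }
  oracle_labels <- tmpl$labels[best]
  expect_equal(got$labels, oracle_labels)
})

test_that("midplane construction follows the cross-product arithmetic", {
  labels <- c("FPZ", "OZ", NA)
  pts <- rbind(c(0.1, 0, 0.02), c(-0.1, 0, 0.02), c(0, 0.05, 0))
  m <- toy_montage()
  mp <- define_midplane(labels, pts, m)
  expect_equal(mp$normal, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(midplane_side(pts[3L, ], mp), 1L)
  expect_equal(midplane_side(c(0.05, 0, 0.1), mp), 0L)
  expect_equal(midplane_side(c(0, -0.02, 0), mp), -1L)
})

test_that("missing or duplicated midplane anchors abort labeling", {
  m <- toy_montage()
  pts <- toy_points()
  expect_error(define_midplane(c("FPZ", rep(NA, 7)), pts, m),
               "midplane undefined")
  expect_error(define_midplane(c("FPZ", "OZ", "OZ", rep(NA, 5)), pts, m),
               "midplane undefined")
})

test_that("wrong-side proposals are flipped to the pair partner", {
  m <- toy_montage()
  pts <- toy_points()
  labs <- m$ordered_labels
  i_c2 <- match("C2", labs)
  prop <- labs
  prop[i_c2] <- "C1"   # right-side electrode proposed with the left label
  prop[match("C1", labs)] <- NA
  mp <- define_midplane(prop, pts, m)
  res <- resolve_symmetry(prop, pts, mp, m)
  expect_equal(res$labels[i_c2], "C2")
})

test_that("a duplicated pair label splits one per side", {
  m <- toy_montage()
  pts <- toy_points()
  labs <- m$ordered_labels
  prop <- labs
  prop[match("C1", labs)] <- "C1"
  prop[match("C2", labs)] <- "C1"   # both proposed C1, one per side
  mp <- define_midplane(prop, pts, m)
  res <- resolve_symmetry(prop, pts, mp, m)
  expect_equal(res$labels[match("C1", labs)], "C1")
  expect_equal(res$labels[match("C2", labs)], "C2")
  expect_equal(nrow(res$unresolved), 0L)
})

test_that("three electrodes sharing a proposal all become unlabeled", {
  m <- toy_montage()
  pts <- toy_points()
  labs <- m$ordered_labels
  prop <- labs
  idx <- match(c("F1", "F2", "P1"), labs)
  prop[idx] <- "F1"
  mp <- define_midplane(prop, pts, m)
  res <- resolve_symmetry(prop, pts, mp, m)
  expect_true(all(is.na(res$labels[idx])))
  expect_setequal(res$unresolved$index, idx)
  expect_true(all(res$unresolved$reason == "triple_duplicate"))
})

test_that("midline labels are never flipped", {
  m <- toy_montage()
  pts <- toy_points()
  prop <- m$ordered_labels
  mp <- define_midplane(prop, pts, m)
  res <- resolve_symmetry(prop, pts, mp, m)
  expect_equal(res$labels[match("FPZ", prop)], "FPZ")
  expect_equal(res$labels[match("OZ", prop)], "OZ")
})

test_that("plurality voting follows the worked scenarios", {
  m <- toy_montage()
  pts <- toy_points_perturbed()
  tmpl <- electrode_set(pts, labels = m$ordered_labels)

  # 5 templates, proposals FPZ x3 / F1 x2 for the FPZ electrode: build
  # templates that reproduce this by swapping labels on two of them
  swap_labels <- function(es, a, b) {
    l <- es$labels
    ia <- match(a, l); ib <- match(b, l)
    l[c(ia, ib)] <- l[c(ib, ia)]
    electrode_set(es$points, labels = l)
  }
  bad <- swap_labels(tmpl, "FPZ", "F1")
  res <- vote_labels(electrode_set(pts),
                     list(tmpl, tmpl, tmpl, bad, bad), m)
  i_fpz <- match("FPZ", m$ordered_labels)
  expect_equal(res$assigned[i_fpz], "FPZ")
  expect_equal(unname(res$votes[[i_fpz]]["FPZ"]), 3L)

  # 3-way tie resolves to the earliest label in the sequence: the F1
  # electrode receives F1, P1 and P2 from the three templates
  t2 <- swap_labels(tmpl, "F1", "P1")
  t3 <- swap_labels(tmpl, "F1", "P2")
  res2 <- vote_labels(electrode_set(pts), list(tmpl, t2, t3), m)
  i_f1 <- match("F1", m$ordered_labels)
  expect_equal(sort(names(res2$votes[[i_f1]])), c("F1", "P1", "P2"))
  expect_equal(res2$assigned[i_f1], "F1")
  expect_equal(res2$assigned, m$ordered_labels)
})

test_that("one template degenerates to single matching plus symmetry", {
  m <- quikcap64_montage()
  params <- phantom_params(seed = 8)
  set.seed(8)
  tmpl <- place_montage(m, params)
  unlab <- electrode_set(tmpl$points)
  res <- vote_labels(unlab, list(tmpl), m)
  expect_equal(res$assigned, tmpl$labels)
  expect_equal(nrow(res$unresolved), 0L)
  rep <- labeling_metrics(res, tmpl$labels)
  expect_equal(rep$tp_pct, 100)
})

test_that("no label is assigned twice and results are deterministic", {
  m <- quikcap64_montage()
  params <- phantom_params(angular_jitter_sd = 0.035, seed = 31)
  co <- make_cohort(4, m, params)
  unlab <- electrode_set(co[[1]]$electrodes$points)
  tms <- lapply(co[2:4], `[[`, "electrodes")
  r1 <- vote_labels(unlab, tms, m)
  r2 <- vote_labels(unlab, tms, m)
  expect_identical(r1$assigned, r2$assigned)
  lab <- r1$assigned[!is.na(r1$assigned)]
  expect_false(anyDuplicated(lab) > 0L)
})
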