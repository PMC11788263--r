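test_that("skeleton points are classified by 8-neighbour counts", {
  m <- line_mask(16, 16, row = 8, cols = 4:13)   # 10-px line
  lab <- classify_skeleton_points(m)
  expect_equal(sum(lab == 1L), 2)    # two free ends
  expect_equal(sum(lab == 2L), 8)    # interior connections
  expect_equal(sum(lab == 3L), 0)

  # plus sign: two 9-px lines crossing centrally.  In-test oracle: count
  # positive 8-neighbours directly.  (Note the four arm pixels adjacent to
  # the crossing also have 3 neighbours under 8-adjacency, so the crossing
  # yields 5 junction-labeled pixels, not 1.)
  p <- matrix(0, 17, 17)
  p[9, 5:13] <- 1
  p[5:13, 9] <- 1
  labp <- classify_skeleton_points(p)
  oracle <- matrix(0L, 17, 17)
  for (r in 1:17) for (c in 1:17) {
    if (p[r, c] == 0) next
    nb <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= 17 && cc >= 1 && cc <= 17) nb <- nb + p[rr, cc]
    }
    oracle[r, c] <- if (nb <= 1) 1L else if (nb == 2) 2L else 3L
  }
  expect_equal(unname(labp), oracle, ignore_attr = TRUE)
  expect_equal(sum(labp == 1L), 4)

  iso <- matrix(0, 5, 5); iso[3, 3] <- 1
  expect_equal(classify_skeleton_points(iso)[3, 3], 1L)  # free, 0 neighbours

  expect_error(classify_skeleton_points(matrix(0.3, 4, 4)), "binary")
})

test_that("tracing produces ordered, covering, deterministic lists", {
  m <- line_mask(16, 16, row = 8, cols = 4:13)
  lists <- trace_edge_lists(m)
  expect_length(lists, 1)
  expect_equal(nrow(lists[[1]]$points), 10)
  expect_equal(unname(lists[[1]]$points[1, ]), c(8, 4))   # left-to-right
  expect_equal(unname(lists[[1]]$points[10, ]), c(8, 13))

  # plus sign: each free point starts one walk that terminates at a
  # junction-labeled pixel; traced lists cover the whole positive set
  p <- matrix(0, 17, 17)
  p[9, 5:13] <- 1
  p[5:13, 9] <- 1
  lp <- trace_edge_lists(p)
  labp <- classify_skeleton_points(p)
  from_free <- Filter(function(e) {
    ends <- e$points[c(1, nrow(e$points)), , drop = FALSE]
    any(labp[ends] == 1L)
  }, lp)
  expect_length(from_free, 4)
  for (e in from_free) {
    ends <- e$points[c(1, nrow(e$points)), , drop = FALSE]
    expect_true(any(labp[ends] == 3L))   # other end is a junction point
  }
  # coverage: union of traced pixels equals the positive set
  cov <- matrix(0, 17, 17)
  for (e in lp) cov[e$points] <- 1
  expect_identical(cov, p)

  expect_length(trace_edge_lists(matrix(0, 8, 8)), 0)

  # determinism
  expect_identical(trace_edge_lists(p), trace_edge_lists(p))

  # pure cycle opened at its topmost-leftmost pixel, fully covered
  ring <- matrix(0, 12, 12)
  ring[4, 4:8] <- 1; ring[8, 4:8] <- 1; ring[4:8, 4] <- 1; ring[4:8, 8] <- 1
  ring <- ribsep:::thin_skeleton(ring)
  lr <- trace_edge_lists(ring)
  cov2 <- matrix(0, 12, 12)
  for (e in lr) cov2[e$points] <- 1
  expect_identical(cov2, ring)
})

test_that("merging joins collinear gaps and rejects misaligned pairs", {
  # DERIVED: endpoint distance 3 < 10 and angle 0 < 30 -> merged
  a <- edge_list(cbind(rep(10, 20), 1:20))
  b <- edge_list(cbind(rep(10, 20), 24:43))
  merged <- merge_edge_lists(list(a, b))
  expect_length(merged, 1)
  pts <- merged[[1]]$points
  expect_true(all(diff(pts[, 2]) > 0))
  expect_true(all(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2) <= 2))

  # DERIVED: perpendicular segments 3 px apart (angle 90 > 30) -> not merged
  v <- edge_list(cbind(13:32, rep(20, 20)))
  expect_length(merge_edge_lists(list(a, v)), 2)

  # parallel lines 9 px apart vertically: gap direction perpendicular to
  # the tangents -> not merged (prevents welding neighbouring bone edges)
  c2 <- edge_list(cbind(rep(19, 20), 20:39))
  expect_length(merge_edge_lists(list(a, c2)), 2)

  # single list is a fixpoint
  expect_identical(merge_edge_lists(list(a)), list(a))

  # explicit plan reproduces the interactive mode regardless of tolerances
  far <- edge_list(cbind(rep(10, 10), 60:69))
  planned <- merge_edge_lists(list(a, far), plan = cbind(1, 2))
  expect_length(planned, 1)
})

test_that("pairing selects nearest parallel edges and builds centerlines", {
  mk <- function(row) edge_list(cbind(rep(row, 40), 1:40))
  pairs <- pair_upper_lower(list(mk(10), mk(20)))
  expect_length(pairs, 1)
  expect_equal(unname(pairs[[1]]$upper$points[1, 1]), 10)
  expect_equal(unname(pairs[[1]]$lower$points[1, 1]), 20)
  expect_equal(unname(pairs[[1]]$centerline$points[, 1]),
               rep(15, nrow(pairs[[1]]$centerline$points)))

  # DERIVED: four parallel lines, nearest pairs (10,20) and (40,50)
  p4 <- pair_upper_lower(list(mk(10), mk(20), mk(40), mk(50)))
  expect_length(p4, 2)
  rows <- sort(vapply(p4, function(p) p$upper$points[1, 1], numeric(1)))
  expect_equal(rows, c(10, 40))

  expect_warning(p1 <- pair_upper_lower(list(mk(10))), "unpaired")
  expect_length(p1, 0)
})

test_that("phantom edge masks decode to the ground-truth pairing", {
  # non-overlapping bones only (posterior + clavicle scene)
  sc <- generate_phantom(phantom_config(seed = 6, n_anterior = 0,
                                        n_corruptors = 0))
  n_true <- length(sc$edge_lists)
  pairs <- list()
  for (cat in names(sc$edge_masks)) {
    mask <- sc$edge_masks[[cat]]
    if (!any(mask > 0)) next
    sk <- ribsep:::thin_skeleton(mask)
    traced <- trace_edge_lists(sk)
    traced <- lapply(traced, function(e) { e$category <- cat; e })
    merged <- merge_edge_lists(traced)
    pairs <- c(pairs, suppressWarnings(pair_upper_lower(merged)))
  }
  expect_equal(length(pairs), n_true)
  cats <- sort(vapply(pairs, function(p) p$category, character(1)))
  expect_equal(cats, sort(vapply(sc$edge_lists, function(e) e$category,
                                 character(1))))
})
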