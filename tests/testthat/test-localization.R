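# The cross-product localizer, its equivalence to the point-to-ray
# distance minimizer, continuity-restricted sequences, and the sampling
# and radial-offset error bounds.

test_that("a projected centerline point localizes back to itself", {
  set.seed(301)
  tree <- random_curve_tree()
  g <- pose_to_geometry(random_pose())
  pts <- as.data.frame(tree)
  for (k in sample(nrow(pts), 10L)) {
    px <- project_point(g, as.numeric(pts[k, c("x", "y", "z")]))
    res <- localize(g, px, tree)
    expect_equal(res$index, pts$index[k])
    expect_lt(res$perp_dist_mm, 1e-8)
    expect_lt(res$objective, 1e-10)
  }
})

test_that("the cross-product argmin agrees with the point-to-ray distance oracle", {
  set.seed(302)
  for (rep in 1:200) {
    tree <- random_curve_tree(n = 80)
    g <- pose_to_geometry(random_pose())
    p2d <- c(stats::runif(1, 100, 411), stats::runif(1, 100, 411))
    cand <- as.data.frame(tree)
    res <- localize(g, p2d, tree)
    orc <- oracle_localize_index(g, p2d, cand)
    expect_equal(res$index, cand$index[orc$index])
    # identity: objective = ||w||^2 * d^2 with w = p'_2D - s
    w <- pixel_to_detector_point(g, p2d) - g$source_mm
    expect_equal(res$objective, sum(w^2) * orc$dist^2, tolerance = 1e-6)
    expect_equal(res$perp_dist_mm, orc$dist, tolerance = 1e-9)
  }
})

test_that("ties are broken toward the lower branch/index and flagged ambiguous", {
  # two branches containing the same point: exact projection hits both
  b1 <- centerline_branch(cbind(0, 0, seq(-10, 10, 1)), "alpha")
  b2 <- centerline_branch(rbind(c(5, 5, 0), c(0, 0, 0), c(-5, 5, 0)),
                          "beta")
  tree <- centerline_tree(list(b1, b2))
  g <- pose_to_geometry(carm_pose(0, 0))
  px <- project_point(g, c(0, 0, 0))
  res <- localize(g, px, tree)
  expect_equal(res$branch_id, "alpha")     # declared first, same objective
  expect_true(res$ambiguous)
})

test_that("superimposed branches trigger wrong-branch picks that the continuity restriction repairs", {
  sc <- make_superimposed_scene()
  truth <- rep(sc$true_branch, nrow(sc$points2d))
  free <- vapply(seq_len(nrow(sc$points2d)), function(i)
    localize(sc$geom, sc$points2d[i, ], sc$tree)$branch_id, "")
  expect_gte(sum(free != truth), 1L)
  restricted <- localize_sequence(sc$geom, sc$points2d, sc$tree,
                                  window_mm = 10, init = sc$init)
  expect_equal(branch_accuracy(restricted, truth), 1.0)
  # with markers exactly on the sampled points both branches tie
  amb <- make_superimposed_scene(marker_node_offset_mm = 0)
  expect_true(localize(amb$geom, amb$points2d[1, ], amb$tree)$ambiguous)
})

test_that("a single-point sequence without init equals full-tree localization", {
  set.seed(303)
  tree <- random_curve_tree()
  g <- pose_to_geometry(random_pose())
  p2d <- matrix(c(250.3, 261.7), 1L)
  seq1 <- localize_sequence(g, p2d, tree, window_mm = 5)
  single <- localize(g, p2d[1, ], tree)
  expect_equal(seq1$index, single$index)
  expect_equal(seq1$branch_id, single$branch_id)
  expect_equal(seq1$n_candidates, single$n_candidates)
})

test_that("a monotone pull-through yields monotone arc-length positions", {
  set.seed(304)
  sc <- straight_vessel_scene(n_frames = 40, radial_offset_mm = 0,
                              step_mm = 0.7)
  g <- pose_to_geometry(carm_pose(10, 5))
  px <- project_points(g, sc$trajectory_mm)
  res <- localize_sequence(g, px, sc$tree, window_mm = 10)
  expect_true(all(diff(res$arclen_mm) >= 0))
  expect_true(all(res$branch_id == "vessel"))
})

test_that("markers on the resampled centerline localize within half the spacing", {
  ph <- make_phantom(phantom_spec(marker_radial_offset_mm = 0))
  tree <- resample_centerline(ph$tree, 0.5)
  pose <- carm_pose(30, 0)
  g <- pose_to_geometry(pose)
  px <- project_markers(g, ph$markers_mm)
  for (i in seq_len(nrow(px))) {
    res <- localize(g, px[i, ], tree)
    expect_equal(res$branch_id, "carotid")
    expect_lte(ed3d(matrix(res$point_mm, 1L),
                    ph$markers_mm[i, , drop = FALSE]), 0.25 + 1e-9)
  }
  # integer-quantized picks add at most the pixel footprint term
  pxq <- project_markers(g, ph$markers_mm, quantize = TRUE)
  for (i in seq_len(nrow(pxq))) {
    res <- localize(g, pxq[i, ], tree)
    expect_lte(ed3d(matrix(res$point_mm, 1L),
                    ph$markers_mm[i, , drop = FALSE]),
               0.25 + quantization_bound_mm(pose) + 1e-9)
  }
})

test_that("radially offset markers localize within the vessel-radius bound", {
  pose <- carm_pose(30, 0)
  g <- pose_to_geometry(pose)
  r <- 3.2
  for (seed in 1:5) {
    ph <- make_phantom(phantom_spec(marker_radial_offset_mm = r,
                                    seed = seed))
    tree <- resample_centerline(ph$tree, 0.5)
    pxq <- project_markers(g, ph$markers_mm, quantize = TRUE)
    for (i in seq_len(nrow(pxq))) {
      res <- localize(g, pxq[i, ], tree)
      expect_lte(ed3d(matrix(res$point_mm, 1L),
                      ph$markers_mm[i, , drop = FALSE]),
                 r + 0.25 + quantization_bound_mm(pose) + 1e-9)
    }
  }
})

test_that("refining the sampling never increases the oracle minimum distance", {
  set.seed(305)
  tree <- random_curve_tree(n = 60)
  g <- pose_to_geometry(random_pose())
  p2d <- c(240.8, 270.2)
  dists <- vapply(c(2, 1, 0.5, 0.25), function(sp) {
    rs <- resample_centerline(tree, sp)
    oracle_localize_index(g, p2d, as.data.frame(rs))$dist
  }, 0)
  expect_true(all(diff(dists) <= 1e-9))
})

test_that("empty candidate sets and length mismatches are rejected", {
  tree <- make_y_tree()
  g <- pose_to_geometry(carm_pose(0, 0))
  expect_error(localize(g, c(100, 100), tree,
                        candidates = data.frame(branch_id = character(0),
                                                index = integer(0))),
               "empty candidate")
  expect_error(branch_accuracy(character(0), character(0)), "non-empty")
  expect_error(branch_accuracy(c("a", "b"), "a"), "equal length")
})

test_that("branch accuracy is the fraction of correct-branch results", {
  expect_equal(branch_accuracy(rep("carotid", 5), rep("carotid", 5)), 1.0)
  # 320 points with 8 assigned to the wrong vessel
  truth <- rep("carotid", 320)
  got <- truth
  got[101:108] <- "subclavian"
  expect_equal(branch_accuracy(got, truth), 0.975)
})
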