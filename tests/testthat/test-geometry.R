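# C-arm camera model: frame construction, projection, back-projection,
# and the iso-center evaluation plane.

test_that("identity angulation places source and detector on the anterior axis", {
  g <- pose_to_geometry(carm_pose(0, 0, sod_mm = 750, sid_mm = 1000))
  expect_equal(g$source_mm, c(0, -750, 0))
  expect_equal(g$detector_origin_mm, c(0, 250, 0))
  expect_equal(g$normal, c(0, 1, 0))
})

test_that("pure primary rotation moves the source about the patient long axis", {
  g <- pose_to_geometry(carm_pose(90, 0, sod_mm = 750, sid_mm = 1000))
  expect_equal(sqrt(sum(g$source_mm^2)), 750, tolerance = 1e-12)
  expect_equal(g$source_mm[3], 0, tolerance = 1e-9)   # stays in the axial plane
  g2 <- pose_to_geometry(carm_pose(0, 30, sod_mm = 750, sid_mm = 1000))
  expect_equal(g2$source_mm[1], 0, tolerance = 1e-9)  # secondary keeps x
})

test_that("detector frames are orthonormal and reproduce SOD/SID (random poses)", {
  set.seed(11)
  for (i in 1:100) {
    pose <- random_pose()
    g <- pose_to_geometry(pose)
    for (v in list(g$u_axis, g$v_axis, g$normal))
      expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
    expect_lt(abs(sum(g$u_axis * g$v_axis)), 1e-9)
    expect_lt(abs(sum(g$u_axis * g$normal)), 1e-9)
    expect_lt(abs(sum(g$v_axis * g$normal)), 1e-9)
    expect_equal(sqrt(sum((g$source_mm - g$isocenter_mm)^2)), pose$sod_mm,
                 tolerance = 1e-9)
    # distance from source to the detector plane along its normal
    expect_equal(sum((g$detector_origin_mm - g$source_mm) * g$normal),
                 pose$sid_mm, tolerance = 1e-9)
  }
})

test_that("invalid pose values raise errors naming the field", {
  expect_error(carm_pose(0, 0, sod_mm = -5), "sod_mm")
  expect_error(carm_pose(0, 0, sod_mm = 800, sid_mm = 700), "sid_mm")
  expect_error(carm_pose(0, 0, pixel_spacing_mm = c(0, 0.4)),
               "pixel_spacing_mm")
  expect_error(carm_pose(0, 0, detector_size_px = c(1, 512)),
               "detector_size_px")
})

test_that("iso-center projects to the detector center and magnification follows SID/SOD", {
  pose <- carm_pose(25, -10, sod_mm = 750, sid_mm = 1000)
  g <- pose_to_geometry(pose)
  ctr <- project_point(g, c(0, 0, 0))
  expect_equal(ctr$row_px, (pose$detector_size_px[1] - 1) / 2, tolerance = 1e-9)
  expect_equal(ctr$col_px, (pose$detector_size_px[2] - 1) / 2, tolerance = 1e-9)
  d <- 7.3                                  # mm along u at the iso-center
  off <- project_point(g, d * g$u_axis)
  expect_equal(off$col_px - ctr$col_px,
               d * (pose$sid_mm / pose$sod_mm) / pose$pixel_spacing_mm[2],
               tolerance = 1e-9)
  expect_equal(off$row_px, ctr$row_px, tolerance = 1e-9)
})

test_that("project/lift round trip recovers the original point (real and quantized pixels)", {
  set.seed(21)
  for (i in 1:1000) {
    pose <- random_pose()
    g <- pose_to_geometry(pose)
    p <- c(stats::runif(2, -60, 60), stats::runif(1, -60, 60))
    px <- project_point(g, p)
    r <- pixel_to_ray(g, px)
    expect_lt(oracle_ray_distance(r$origin_mm, r$direction,
                                  matrix(p, 1L)), 1e-6)
    rq <- pixel_to_ray(g, working_point(round(px$row_px), round(px$col_px)))
    bound <- max(pose$pixel_spacing_mm) * pose$sid_mm /
      (2 * pose$sod_mm) * sqrt(2) + 1e-9
    expect_lt(oracle_ray_distance(rq$origin_mm, rq$direction,
                                  matrix(p, 1L)), bound)
  }
})

test_that("points at or behind the source are rejected", {
  g <- pose_to_geometry(carm_pose(0, 0, 750, 1000))
  expect_error(project_point(g, c(0, -750, 0)), "degenerate")
  expect_error(project_point(g, c(0, -900, 0)), "degenerate")
  expect_error(project_point(g, c(0, 260, 0)), "degenerate") # behind detector
})

test_that("pixel-to-detector embedding matches the detector frame", {
  pose <- carm_pose(40, 15)
  g <- pose_to_geometry(pose)
  cen <- (pose$detector_size_px - 1) / 2
  expect_equal(pixel_to_detector_point(g, working_point(cen[1], cen[2])),
               g$detector_origin_mm, tolerance = 1e-12)
  expect_equal(pixel_to_detector_point(g, working_point(cen[1], cen[2] + 1)),
               g$detector_origin_mm + pose$pixel_spacing_mm[2] * g$u_axis,
               tolerance = 1e-12)
  # detector points lie on the detector plane and round-trip through
  # projection
  set.seed(5)
  for (i in 1:50) {
    p2 <- c(stats::runif(1, 0, 511), stats::runif(1, 0, 511))
    dp <- pixel_to_detector_point(g, p2)
    expect_lt(abs(sum((dp - g$detector_origin_mm) * g$normal)), 1e-9)
    back <- project_point(g, g$source_mm +
                            0.6 * (dp - g$source_mm))  # a point on the ray
    expect_equal(c(back$row_px, back$col_px), p2, tolerance = 1e-8)
  }
})

test_that("rays pass through their detector point and distinct pixels give non-parallel rays", {
  g <- pose_to_geometry(carm_pose(-35, 20))
  set.seed(9)
  for (i in 1:25) {
    a <- c(stats::runif(1, 0, 511), stats::runif(1, 0, 511))
    b <- a + c(stats::runif(1, 1, 30), stats::runif(1, 1, 30))
    ra <- pixel_to_ray(g, a)
    expect_equal(sqrt(sum(ra$direction^2)), 1, tolerance = 1e-12)
    dp <- pixel_to_detector_point(g, a)
    expect_lt(oracle_ray_distance(ra$origin_mm, ra$direction,
                                  matrix(dp, 1L)), 1e-12)
    rb <- pixel_to_ray(g, b)
    cross_norm <- sqrt(sum((c(
      ra$direction[2] * rb$direction[3] - ra$direction[3] * rb$direction[2],
      ra$direction[3] * rb$direction[1] - ra$direction[1] * rb$direction[3],
      ra$direction[1] * rb$direction[2] - ra$direction[2] * rb$direction[1]))^2))
    expect_gt(cross_norm, 1e-8)
  }
})

test_that("iso-center plane mapping is consistent between 3D points and their pixels", {
  pose <- carm_pose(20, -25, sod_mm = 780, sid_mm = 1050)
  g <- pose_to_geometry(pose)
  expect_equal(to_isocenter_plane(g, working_point(255.5, 255.5)), c(0, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(31)
  for (i in 1:25) {
    p <- stats::runif(3, -50, 50)
    px <- project_point(g, p)
    expect_equal(to_isocenter_plane(g, p), to_isocenter_plane(g, px),
                 tolerance = 1e-9)
  }
  # a detector offset of k mm maps to k * SOD/SID in the plane
  k_mm <- 11.1
  p2 <- working_point(255.5, 255.5 + k_mm / pose$pixel_spacing_mm[2])
  expect_equal(sqrt(sum(to_isocenter_plane(g, p2)^2)),
               k_mm * pose$sod_mm / pose$sid_mm, tolerance = 1e-9)
})

test_that("geometry JSON config round-trips", {
  pose <- carm_pose(12.5, -7.25, sod_mm = 765, sid_mm = 1080,
                    pixel_spacing_mm = c(0.308, 0.308),
                    detector_size_px = c(1024L, 1024L))
  path <- temp_path(".json")
  write_geometry(pose, path)
  back <- read_geometry(path)
  expect_equal(unclass(back), unclass(pose), tolerance = 1e-12)
  expect_error(read_geometry({
    p2 <- temp_path(".json")
    jsonlite::write_json(list(sod_mm = 750), p2, auto_unbox = TRUE)
    p2
  }), "missing field")
})
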