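# Centerline trees: construction, resampling, geodesic neighborhoods,
# and file round trips.

test_that("branch and tree validation rejects malformed input", {
  expect_error(centerline_branch(matrix(1:3, 1L), "b"), "at least 2")
  expect_error(centerline_branch(rbind(c(0, 0, 0), c(0, 0, 0)), "b"),
               "zero-length")
  expect_error(centerline_branch(cbind(0, 0, 0:3), "b",
                                 radius_mm = c(1, 2)), "radius_mm")
  b <- centerline_branch(cbind(0, 0, 0:3), "b")
  expect_error(centerline_tree(list(b, b)), "unique")
  c1 <- centerline_branch(cbind(1, 0, 0:3), "c",
                          parent = list(branch_id = "missing", index = 1L))
  expect_error(centerline_tree(list(b, c1)), "unknown parent")
  c2 <- centerline_branch(cbind(1, 0, 0:3), "c",
                          parent = list(branch_id = "b", index = 9L))
  expect_error(centerline_tree(list(b, c2)), "out of range")
})

test_that("resampling a straight 10 mm segment at 1 mm gives 11 points at integer arc lengths", {
  tree <- centerline_tree(centerline_branch(rbind(c(0, 0, 0), c(10, 0, 0)),
                                            "seg"))
  rs <- resample_centerline(tree, 1)
  b <- rs$branches$seg
  expect_equal(nrow(b$points_mm), 11L)
  expect_equal(b$cum_arclen_mm, 0:10, tolerance = 1e-12)
  expect_equal(b$points_mm[, 1], 0:10, tolerance = 1e-12)
})

test_that("resampling preserves endpoints and is idempotent when nodes hit the kinks", {
  # segment lengths are integer multiples of the spacing, so resampled
  # nodes land on the kink vertices and a second pass reproduces them
  P <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 3, 0), c(4, 3, 6))
  tree <- centerline_tree(centerline_branch(P, "kinked"))
  r1 <- resample_centerline(tree, 0.5)
  r2 <- resample_centerline(r1, 0.5)
  expect_equal(r2$branches$kinked$points_mm, r1$branches$kinked$points_mm,
               tolerance = 1e-9)
  expect_equal(r1$branches$kinked$points_mm[1, ], P[1, ])
  expect_equal(r1$branches$kinked$points_mm[nrow(r1$branches$kinked$points_mm), ],
               P[4, ])
  # arc-length parameter spacing is uniform except the last segment
  d <- diff(r1$branches$kinked$cum_arclen_mm)
  expect_true(all(abs(d[-length(d)] - 0.5) < 1e-9))
})

test_that("quarter-circle arc length approaches the closed form under fine resampling", {
  th <- seq(0, pi / 2, length.out = 2000)
  tree <- centerline_tree(centerline_branch(cbind(20 * cos(th),
                                                  20 * sin(th), 0), "arc"))
  rs <- resample_centerline(tree, 0.1)
  expect_equal(max(rs$branches$arc$cum_arclen_mm), 10 * pi,
               tolerance = 1e-3)
})

test_that("radii are linearly interpolated through resampling", {
  tree <- centerline_tree(centerline_branch(rbind(c(0, 0, 0), c(10, 0, 0)),
                                            "seg", radius_mm = c(2, 4)))
  rs <- resample_centerline(tree, 2.5)
  expect_equal(rs$branches$seg$radius_mm, c(2, 2.5, 3, 3.5, 4),
               tolerance = 1e-12)
})

test_that("geodesic neighborhood matches a shortest-path oracle on a Y tree", {
  tree <- make_y_tree(1)
  orc <- oracle_geodesic(tree)
  set.seed(17)
  for (rep in 1:20) {
    i <- sample(nrow(orc$points), 1L)
    w <- stats::runif(1, 0, 25)
    nb <- centerline_neighborhood(tree, orc$points$branch_id[i],
                                  orc$points$index[i], w)
    expected <- which(orc$dist[i, ] <= w + 1e-9)
    got <- match(paste(nb$branch_id, nb$index), orc$key)
    expect_setequal(got, expected)
  }
  # window 0 returns only the query; a huge window returns everything
  nb0 <- centerline_neighborhood(tree, "trunk", 3L, 0)
  expect_equal(nrow(nb0), 1L)
  expect_equal(nb0$index, 3L)
  nball <- centerline_neighborhood(tree, "trunk", 3L, 1e6)
  expect_equal(nrow(nball), nrow(orc$points))
  # sibling-branch points are reached only through the junction
  nb <- centerline_neighborhood(tree, "trunk", 9L, 4)   # point at z = 8
  side_pts <- nb[nb$branch_id == "side", ]
  expect_true(all(side_pts$geodesic_mm >= 2))  # 2 mm up to the junction first
  expect_error(centerline_neighborhood(tree, "trunk", 999L, 5), "no point")
})

test_that("neighborhood membership is symmetric", {
  tree <- make_y_tree(2)
  pts <- as.data.frame(tree)
  set.seed(23)
  for (rep in 1:15) {
    ij <- sample(nrow(pts), 2L)
    w <- stats::runif(1, 0, 30)
    in_a <- function(i, j) {
      nb <- centerline_neighborhood(tree, pts$branch_id[i], pts$index[i], w)
      any(nb$branch_id == pts$branch_id[j] & nb$index == pts$index[j])
    }
    expect_equal(in_a(ij[1], ij[2]), in_a(ij[2], ij[1]))
  }
})

test_that("CSV, JSON and VTK round trips reproduce the tree", {
  tree <- make_y_tree(1)
  # attach radii to exercise the Radius array
  tree$branches$trunk$radius_mm <- seq(2, 4, length.out = 21)
  tree$branches$side$radius_mm <- rep(1.5, 15)
  for (fmt in c("csv", "json", "vtk")) {
    path <- temp_path(paste0(".", fmt))
    write_centerline(tree, path, fmt)
    back <- read_centerline(path, fmt)
    expect_equal(length(back$branches), 2L)
    expect_equal(do.call(rbind, lapply(back$branches, `[[`, "points_mm")),
                 do.call(rbind, lapply(tree$branches, `[[`, "points_mm")),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(unlist(lapply(back$branches, `[[`, "radius_mm")),
                 unlist(lapply(tree$branches, `[[`, "radius_mm")),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # JSON keeps topology
  pj <- temp_path(".json")
  write_centerline(tree, pj)
  back <- read_centerline(pj)
  expect_equal(back$branches$side$parent,
               list(branch_id = "trunk", index = 11L))
  # VTK file has two polyline cells read back in order
  pv <- temp_path(".vtk")
  write_centerline(tree, pv)
  backv <- read_centerline(pv)
  expect_equal(vapply(backv$branches, function(b) nrow(b$points_mm), 0L),
               c(branch_01 = 21L, branch_02 = 15L))
})

test_that("malformed centerline files fail with located parse errors", {
  p <- temp_path(".csv")
  writeLines(c("branch_id,x,y,z", "a,0,0,0", "a,1,,0", "a,2,0,0"), p)
  expect_error(read_centerline(p), "row 2")
  p2 <- temp_path(".csv")
  writeLines(c("branch_id,x,y", "a,0,0"), p2)
  expect_error(read_centerline(p2), "missing column")
  p3 <- temp_path(".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "t", "ASCII",
               "DATASET POLYDATA", "POINTS 2 double", "0 0 0", "1 0 0",
               "LINES 1 3", "2 0 5"), p3)
  expect_error(read_centerline(p3), "out of range")
})
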