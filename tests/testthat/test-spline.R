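dims_small <- c(40, 30, 20)

test_that("a constant control grid gives a constant surface", {
  grid <- control_point_grid(matrix(10, 4, 4), dims_small)
  s <- fit_spline_surface(grid)
  f <- surface_field(s)
  expect_equal(f, matrix(10, 40, 30), tolerance = 1e-9)
})

test_that("planes are reproduced exactly (linear precision)", {
  w <- 40; h <- 30; d <- 20
  plane <- function(x, y) 2 + 0.05 * x + 0.03 * y
  for (g in 3:5) {
    xk <- seq(0, w - 1, length.out = g)
    yn <- seq(0, h - 1, length.out = g)
    depths <- outer(xk, yn, plane)
    s <- fit_spline_surface(control_point_grid(depths, c(w, h, d)))
    set.seed(g)
    xs <- runif(1000, 0, w - 1); ys <- runif(1000, 0, h - 1)
    expect_lt(max(abs(s$at(xs, ys) - plane(xs, ys))), 1e-6)
  }
})

test_that("the surface interpolates every control node", {
  for (seed in 1:6) {
    set.seed(seed)
    g <- sample(3:5, 1)
    depths <- matrix(runif(g * g, 1, dims_small[3]), g, g)
    grid <- control_point_grid(depths, dims_small)
    s <- fit_spline_surface(grid)
    nodes <- expand.grid(k = seq_len(g), n = seq_len(g))
    vals <- s$at(grid$xnodes[nodes$k], grid$ynodes[nodes$n])
    expect_lt(max(abs(vals - depths[cbind(nodes$k, nodes$n)])), 1e-6)
  }
})

test_that("tensor evaluation matches a dense independent spline oracle, and a
           parabolic sheet is tracked closely", {
  w <- 512; h <- 512; d <- 50
  a <- (d - 1) / (w - 1)^2
  xk <- seq(0, w - 1, length.out = 5)
  depths <- matrix(rep(1 + a * xk^2, 5), 5, 5)
  grid <- control_point_grid(depths, c(w, h, d))
  s <- fit_spline_surface(grid)
  f <- surface_field(s)
  # oracle: interpolate in y first, then x, with stats::spline directly
  ys <- seq(0, h - 1)
  oracle <- matrix(0, w, h)
  m <- sapply(seq_len(5), function(n) {
    stats::spline(grid$ynodes, depths[n, ], method = "natural", xout = ys)$y
  })  # h x g
  for (j in seq_len(h)) {
    oracle[, j] <- stats::spline(xk, m[j, ], method = "natural",
                                 xout = seq(0, w - 1))$y
  }
  expect_lt(max(abs(f - oracle)), 1e-8)
  # regression bound: max deviation from the true parabola, relative to depth
  true_surface <- matrix(rep(1 + a * seq(0, w - 1)^2, h), w, h)
  expect_lt(max(abs(f - true_surface)) / d, 0.035)
})

test_that("half-space masks cut at the surface with <= to the lower side", {
  # constant surface at 1-based depth 25 in a d = 50 volume
  dims <- c(8, 6, 50)
  s <- fit_spline_surface(control_point_grid(matrix(25, 3, 3), dims))
  lower <- spline_mask(dims, s, side = "lower")
  upper <- spline_mask(dims, s, side = "upper")
  # kept planes are 25..50 (1-based): 26 planes per column
  expect_equal(sum(lower), 8 * 6 * 26)
  expect_true(all(lower[, , 25:50]))
  expect_false(any(lower[, , 1:24]))
  # upper is the voxelwise complement
  expect_true(all(xor(unclass(lower), unclass(upper))))
})

test_that("a tilted plane mask matches exhaustive per-voxel evaluation", {
  w <- 16; h <- 16; d <- 8
  plane <- function(x, y) 1.7 + 0.25 * x + 0.12 * y  # 1-based depth
  xk <- seq(0, w - 1, length.out = 4)
  yn <- seq(0, h - 1, length.out = 4)
  s <- fit_spline_surface(control_point_grid(outer(xk, yn, plane), c(w, h, d)))
  lower <- spline_mask(c(w, h, d), s, side = "lower")
  for (x in 0:(w - 1)) {
    for (y in 0:(h - 1)) {
      expected <- plane(x, y) - 1 <= 0:(d - 1)
      expect_identical(unclass(lower)[x + 1, y + 1, ], expected)
      # first kept index is the ceiling of the 0-based plane depth
      first_kept <- which(expected)[1] - 1
      expect_equal(first_kept, max(ceiling(plane(x, y) - 1), 0))
    }
  }
})

test_that("raising all control depths by one never lowers a column cut, and
           shifts it by at most one plane", {
  set.seed(21)
  depths <- matrix(runif(16, 2, dims_small[3] - 2), 4, 4)
  s1 <- fit_spline_surface(control_point_grid(depths, dims_small))
  s2 <- fit_spline_surface(control_point_grid(depths + 1, dims_small))
  m1 <- spline_mask(dims_small, s1, side = "lower")
  m2 <- spline_mask(dims_small, s2, side = "lower")
  first_kept <- function(col) {  # fully peeled column: cut beyond the last plane
    i <- which(col)[1]
    if (is.na(i)) dims_small[3] + 1 else i
  }
  cut1 <- apply(unclass(m1), c(1, 2), first_kept)
  cut2 <- apply(unclass(m2), c(1, 2), first_kept)
  expect_true(all(cut2 >= cut1))
  expect_true(all(cut2 - cut1 <= 1))
})

test_that("control depths interpolate linearly across time", {
  g1 <- control_point_grid(matrix(10, 3, 3), dims_small, frame = 1)
  g2 <- control_point_grid(matrix(20, 3, 3), dims_small, frame = 11)
  surfaces <- interpolate_grids_over_time(list(g1, g2), t_total = 11)
  expect_length(surfaces, 11)
  expect_equal(surfaces[[6]]$at(5, 5), 15, tolerance = 1e-9)   # linear midpoint
  expect_equal(surfaces[[1]]$at(5, 5), 10, tolerance = 1e-9)   # annotated frames exact
  expect_equal(surfaces[[11]]$at(5, 5), 20, tolerance = 1e-9)

  # identical grids at two frames give identical surfaces at every frame
  g2b <- control_point_grid(matrix(10, 3, 3), dims_small, frame = 7)
  same <- interpolate_grids_over_time(list(g1, g2b), t_total = 9)
  for (s in same) expect_equal(surface_field(s), matrix(10, 40, 30), tolerance = 1e-9)

  # three annotated frames: piecewise-linear node trajectories with constant
  # extrapolation, verified against a per-node 1-D interpolation oracle
  set.seed(31)
  d1 <- matrix(runif(9, 1, 20), 3, 3)
  d2 <- matrix(runif(9, 1, 20), 3, 3)
  d3 <- matrix(runif(9, 1, 20), 3, 3)
  grids <- list(control_point_grid(d1, dims_small, frame = 2),
                control_point_grid(d2, dims_small, frame = 5),
                control_point_grid(d3, dims_small, frame = 9))
  surfaces <- interpolate_grids_over_time(grids, t_total = 10)
  gnodes <- grids[[1]]
  for (k in 1:3) {
    for (n in 1:3) {
      oracle <- approx(c(2, 5, 9), c(d1[k, n], d2[k, n], d3[k, n]),
                       xout = 1:10, rule = 2)$y
      got <- vapply(surfaces, function(s) s$at(gnodes$xnodes[k], gnodes$ynodes[n]),
                    numeric(1))
      expect_equal(got, oracle, tolerance = 1e-6)
    }
  }
})

test_that("temporal interpolation validates its inputs", {
  g1 <- control_point_grid(matrix(10, 3, 3), dims_small, frame = 1)
  g2 <- control_point_grid(matrix(10, 4, 4), dims_small, frame = 5)
  expect_error(interpolate_grids_over_time(list(g1, g2), 5), "mismatched grid sizes")
  g3 <- control_point_grid(matrix(10, 3, 3), dims_small, frame = 1)
  expect_error(interpolate_grids_over_time(list(g1, g3), 5), "duplicate frame")
  expect_error(interpolate_grids_over_time(list(g1), 5), "at least two frames")
  g4 <- control_point_grid(matrix(10, 3, 3), dims_small, frame = 9)
  expect_error(interpolate_grids_over_time(list(g1, g4), 5), "within")
})

test_that("control grids validate size and depth range", {
  expect_error(control_point_grid(matrix(10, 2, 2), dims_small), "g in \\{3, 4, 5\\}")
  expect_error(control_point_grid(matrix(10, 3, 4), dims_small), "g in \\{3, 4, 5\\}")
  expect_error(control_point_grid(matrix(0.5, 3, 3), dims_small), "within \\[1")
  expect_error(control_point_grid(matrix(21, 3, 3), dims_small), "within \\[1")
})

test_that("control points round-trip through JSON and load from CSV", {
  set.seed(41)
  d1 <- matrix(runif(16, 1, 20), 4, 4)
  d2 <- matrix(runif(16, 1, 20), 4, 4)
  grids <- list(control_point_grid(d1, dims_small, frame = 1),
                control_point_grid(d2, dims_small, frame = 6))
  p <- withr::local_tempfile(fileext = ".json")
  write_control_points(grids, p)
  back <- read_control_points(p)
  expect_length(back, 2)
  expect_equal(back[[1]]$depths, d1, tolerance = 1e-12)
  expect_equal(back[[2]]$depths, d2, tolerance = 1e-12)
  expect_equal(back[[2]]$frame, 6L)
  expect_equal(back[[1]]$dims, grids[[1]]$dims)

  # the same grid expressed as CSV (frame, row, col, z; row along y)
  tab <- expand.grid(row = 1:4, col = 1:4)
  tab$frame <- 1L
  tab$z <- d1[cbind(tab$col, tab$row)]
  pc <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[, c("frame", "row", "col", "z")], pc, row.names = FALSE)
  from_csv <- read_control_points(pc, dims = dims_small)
  expect_equal(from_csv[[1]]$depths, d1, tolerance = 1e-12)

  expect_error(read_control_points(withr::local_tempfile(fileext = ".txt")), "no such file")
})
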