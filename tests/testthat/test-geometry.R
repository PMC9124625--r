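test_that("polygon_area matches hand values and is orientation-independent", {
  sq <- contour(0, cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  expect_equal(polygon_area(sq), 1.0)
  sq_rev <- contour(0, cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))[4:1, ])
  expect_equal(polygon_area(sq_rev), 1.0)
  # regular 360-gon at vertex radius 50 mm: within 0.1% of the circle area
  circ <- circle_contour(0, 50, 360)
  expect_equal(polygon_area(circ), pi * 25, tolerance = 1e-3)
})

test_that("polygon_area is invariant under vertex rotation and translation", {
  set.seed(42)
  th <- sort(runif(12, 0, 2 * pi))
  p <- cbind(20 * cos(th), 14 * sin(th))   # star-free convex-ish polygon
  a0 <- polygon_area(contour(0, p))
  for (k in c(3, 7)) {
    rot <- p[c(k:nrow(p), 1:(k - 1)), ]
    expect_equal(polygon_area(contour(0, rot)), a0)
  }
  shifted <- sweep(p, 2, c(123.4, -56.7), "+")
  expect_equal(polygon_area(contour(0, shifted)), a0)
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(contour(0, cbind(c(0, 1), c(0, 1))), "3 vertices")
  bowtie <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))
  expect_error(contour(0, bowtie), "self-intersecting")
})

test_that("region_ssa takes the median over in-region slices", {
  mk <- function(areas, ys) rt_structure("ext", mapply(function(a, y)
    square_contour(y, side = 10 * sqrt(a)), areas, ys, SIMPLIFY = FALSE))
  expect_equal(region_ssa(mk(c(100, 120, 140), c(1, 2, 3)), c(0, 10)), 120)
  expect_equal(region_ssa(mk(171.4, 5), c(0, 10)), 171.4)
  # even slice count: mean of the two central values
  expect_equal(region_ssa(mk(c(100, 110, 130, 200), 1:4), c(0, 10)), 120)
  expect_error(region_ssa(mk(100, 5), c(20, 30)), "no contour slices")
})

test_that("contour_change is the fractional SSA reduction", {
  expect_equal(contour_change(100, 100), 0)
  expect_equal(contour_change(192.7, 179.8), (192.7 - 179.8) / 192.7)
  expect_equal(contour_change(192.7, 179.8), 0.06694, tolerance = 1e-4)
  expect_equal(contour_change(100, 110), -0.10)
  expect_error(contour_change(0, 50), "positive")
  expect_error(contour_change(-5, 50), "positive")
})

test_that("three_d_error is the Euclidean norm with norm axioms", {
  expect_equal(three_d_error(shift_vector(0, 0, 0)), 0)
  expect_equal(three_d_error(shift_vector(1, 2, 2)), 3)
  expect_equal(three_d_error(shift_vector(-8, 0, 0)), 8)
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(3, 0, 4); b <- rnorm(3, 0, 4)
    expect_gte(three_d_error(a), 0)
    expect_equal(three_d_error(-a), three_d_error(a))
    expect_lte(three_d_error(a + b),
               three_d_error(a) + three_d_error(b) + 1e-12)
  }
  expect_error(three_d_error(c(1, Inf, 0)), "finite")
})

test_that("rasterized cylinder volume approximates the analytic volume", {
  # axis off the lattice so no voxel centre sits exactly on the surface
  cyl <- cylinder_structure(10, seq(0.5, 49.5, by = 1), cx = 0.3, cz = 0.37)
  g <- dose_grid(array(0, c(31, 50, 31)), origin = c(-15, 0.5, -15),
                 spacing = c(1, 1, 1))
  ras <- rasterize_structure(cyl, g)
  expect_equal(ras$volume_cc, pi * 100 * 50 / 1000, tolerance = 0.02)
  expect_equal(ras$volume_cc, ras$n_voxels * voxel_volume_cc(g))
})

test_that("rasterized volume converges towards the analytic volume with finer grids", {
  vol_at <- function(sp) {
    ys <- seq(sp / 2, 50 - sp / 2, by = sp)
    cyl <- cylinder_structure(10, ys, cx = 0.3, cz = 0.37)
    n <- 2 * ceiling(12 / sp) + 1
    g <- dose_grid(array(0, c(n, length(ys), n)),
                   origin = c(-(n - 1) / 2 * sp, ys[1], -(n - 1) / 2 * sp),
                   spacing = rep(sp, 3))
    rasterize_structure(cyl, g)$volume_cc
  }
  truth <- pi * 100 * 50 / 1000
  err2 <- abs(vol_at(2) - truth)
  err05 <- abs(vol_at(0.5) - truth)
  expect_lt(err05, err2)
  expect_lt(err05 / truth, 0.01)
})

test_that("rasterize handles degenerate and full-coverage cases", {
  # polygon smaller than a voxel, centred between voxel centres
  tiny <- rt_structure("tiny", list(square_contour(0.5, side = 0.2,
                                                   cx = 0.5, cz = 0.5)))
  g <- dose_grid(array(0, c(4, 1, 4)), origin = c(0, 0.5, 0),
                 spacing = c(1, 1, 1))
  expect_warning(ras <- rasterize_structure(tiny, g), "empty mask")
  expect_equal(ras$n_voxels, 0L)
  # rectangle covering the whole grid
  big <- rt_structure("big", list(square_contour(0.5, side = 100, cx = 1.5,
                                                 cz = 1.5)))
  ras2 <- rasterize_structure(big, g)
  expect_true(all(ras2$mask))
})

test_that("multi-island slices are rejected at construction", {
  c1 <- square_contour(5, 10, cx = -20)
  c2 <- square_contour(5, 10, cx = 20)
  expect_error(rt_structure("s", list(c1, c2)), "more than one polygon")
})

test_that("split_by_region partitions contours with half-open boundaries", {
  part <- region_partition(C6_C7 = c(0, 40), C4_C5 = c(40, 75),
                           C1_C3 = c(75, 135))
  ys <- c(10, 39.9, 40, 74.9, 75, 100)
  s <- rt_structure("sc", lapply(ys, square_contour, side = 8))
  parts <- split_by_region(s, part)
  got <- lapply(parts, function(p) if (is.null(p)) numeric() else
    structure_slices(p))
  expect_equal(got$C6_C7, c(10, 39.9))
  expect_equal(got$C4_C5, c(40, 74.9))     # boundary slice goes to its y_min owner
  expect_equal(got$C1_C3, c(75, 100))
  # every in-window contour lands in exactly one region
  expect_equal(sort(as.numeric(unlist(got))), sort(ys))
  # structure confined to one window leaves the others empty
  s_top <- rt_structure("sc", lapply(c(80, 90), square_contour, side = 8))
  parts_top <- split_by_region(s_top, part)
  expect_null(parts_top$C6_C7)
  expect_null(parts_top$C4_C5)
  expect_length(parts_top$C1_C3$contours, 2L)
})

test_that("clip_external scales areas exactly and reproduces the requested shrink", {
  part <- region_partition(C6_C7 = c(0, 40), C4_C5 = c(40, 75),
                           C1_C3 = c(75, 135))
  ext <- rt_structure("ext", lapply(seq(5, 130, by = 10), function(y)
    circle_contour(y, 50, 72)), role = "external")
  expect_equal(clip_external(ext, 0)$contours[[3]]$points,
               ext$contours[[3]]$points)
  shrunk <- clip_external(ext, 0.19)
  expect_equal(polygon_area(shrunk$contours[[1]]),
               0.81 * polygon_area(ext$contours[[1]]), tolerance = 1e-9)
  # per-region shrink touches only that region; SSA ratio identity to 1e-6
  f <- c(C6_C7 = 0.179)
  shr <- clip_external(ext, f, part)
  for (reg in c("C6_C7", "C4_C5", "C1_C3")) {
    expected <- if (reg == "C6_C7") 1 - 0.179 else 1
    expect_equal(region_ssa(shr, reg, part) / region_ssa(ext, reg, part),
                 expected, tolerance = 1e-6)
  }
  expect_equal(
    contour_change(region_ssa(ext, "C6_C7", part),
                   region_ssa(shr, "C6_C7", part)),
    0.179, tolerance = 1e-6)
  # endpoint area ratio of the study's most inferior region
  expect_equal(171.4 * (1 - 0.179) / 171.4, 140.7 / 171.4, tolerance = 2e-3)
  expect_error(clip_external(ext, 1.0), "\\[0, 1\\)")
})

test_that("clip then measure commutes with the shrink for random fractions", {
  ext <- rt_structure("ext", lapply(1:5, function(y)
    circle_contour(y, 40, 60)), role = "external")
  set.seed(3)
  for (f in runif(10, 0, 0.6)) {
    shr <- clip_external(ext, f)
    expect_equal(region_ssa(shr, c(0, 10)), (1 - f) * region_ssa(ext, c(0, 10)),
                 tolerance = 1e-9)
  }
})
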