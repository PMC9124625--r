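# closed-form distance from an interior point to a circle of radius R along
# unit direction u (toward the surface)
.circle_exit <- function(p, u, R) {
  pu <- sum(p * u)
  -pu + sqrt(pu^2 + R^2 - sum(p^2))
}

test_that("a single beam on a flat surface gives an exponential depth dose", {
  body <- rt_structure("ext", list(
    contour(0, cbind(c(0, 100, 100, 0), c(-50, -50, 50, 50)))),
    role = "external")
  params <- toy_engine_params(n_beams = 1, partition = NULL)
  params$norm <- 1
  d <- engine_dose_points(cbind(c(10, 20, 40), 0, 0), body, params)
  expect_equal(d[2] / d[1], exp(-params$mu * 10), tolerance = 1e-9)
  expect_equal(d[1] / d[3], exp(params$mu * 30), tolerance = 1e-9)
  # halving the depth multiplies dose by exp(mu * depth/2)
  expect_equal(d[2], d[3] * exp(params$mu * 20), tolerance = 1e-9)
})

test_that("points outside the body receive zero dose", {
  body <- rt_structure("ext", lapply(c(0, 2), function(y)
    contour(y, cbind(c(0, 100, 100, 0), c(-50, -50, 50, 50)))),
    role = "external")
  params <- toy_engine_params(n_beams = 4, partition = NULL)
  params$norm <- 1
  d <- engine_dose_points(rbind(c(-10, 0, 0), c(50, 0, 60), c(50, 40, 0)),
                          body, params)
  expect_equal(d[1], 0)   # outside in-plane
  expect_equal(d[2], 0)   # outside in-plane (posterior)
  expect_equal(d[3], 0)   # no contour slice near that y
})

test_that("36 beams on a circular body give a radially symmetric dose", {
  body <- rt_structure("ext", list(circle_contour(0, 80, 144)),
                       role = "external")
  params <- toy_engine_params(n_beams = 36, partition = NULL)
  params$norm <- 1
  set.seed(9)
  th <- runif(8, 0, 2 * pi)
  pts <- cbind(30 * cos(th), 0, 30 * sin(th))
  d <- engine_dose_points(pts, body, params)
  expect_lt((max(d) - min(d)) / mean(d), 0.01)
})

test_that("shrinking the body increases the dose at fixed interior points", {
  body <- rt_structure("ext", list(circle_contour(0, 80, 144)),
                       role = "external")
  params <- toy_engine_params(n_beams = 36, partition = NULL)
  params$norm <- 1
  pts <- rbind(c(0, 0, -25), c(10, 0, 5), c(-20, 0, -10))
  set.seed(31)
  fs <- sort(runif(6, 0, 0.3))
  doses <- vapply(fs, function(f)
    engine_dose_points(pts, clip_external(body, f), params), numeric(3))
  for (r in 1:3) expect_true(all(diff(doses[r, ]) > 0))
})

test_that("the shrink dose effect matches the first-order depth prediction", {
  R <- 80
  body <- rt_structure("ext", list(circle_contour(0, R, 288)),
                       role = "external")
  params <- toy_engine_params(n_beams = 36, partition = NULL)
  params$norm <- 1
  p <- c(0, -25)
  f <- 0.05
  s <- sqrt(1 - f)
  d0 <- engine_dose_points(cbind(p[1], 0, p[2]), body, params)
  d1 <- engine_dose_points(cbind(p[1], 0, p[2]), clip_external(body, f),
                           params)
  # independent first-order oracle: mean over beams of the analytic depth
  # reduction of a circle scaled about its centre
  th <- 2 * pi * (seq_len(36) - 1) / 36
  ddepth <- vapply(th, function(a) {
    u <- -c(cos(a), sin(a))                     # toward the source
    .circle_exit(p, u, R) - .circle_exit(p, u, s * R)
  }, numeric(1))
  predicted <- params$mu * mean(ddepth)
  observed <- d1 / d0 - 1
  expect_equal(observed, predicted, tolerance = 0.2 * predicted / observed)
  expect_lt(abs(observed - predicted) / predicted, 0.2)
})

test_that("full-grid engine evaluation equals point evaluation at voxel centres", {
  body <- rt_structure("ext", lapply(c(1, 3, 5), function(y)
    circle_contour(y, 40, 72)), role = "external")
  params <- toy_engine_params(n_beams = 12, partition = NULL)
  params$norm <- 1
  g <- dose_grid(array(0, c(21, 3, 21)), origin = c(-20, 1, -20),
                 spacing = c(2, 2, 2))
  full <- toy_dose_engine(body, grid = g, params = params)
  ax <- grid_axes(g)
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  d_pts <- engine_dose_points(pts, body, params)
  expect_equal(as.vector(full$values), as.vector(array(d_pts, c(21, 3, 21))))
})

test_that("the engine demands calibration and anatomy shifts move the dose", {
  body <- rt_structure("ext", list(circle_contour(0, 80, 144)),
                       role = "external")
  params <- toy_engine_params(n_beams = 12, partition = NULL)
  expect_error(engine_dose_points(cbind(0, 0, 0), body, params),
               "not calibrated")
  params <- calibrate_engine(params, body, y_ref = 0)
  # reference point receives the per-fraction prescription
  ref <- engine_dose_points(cbind(params$target_center[1], 0,
                                  params$target_center[2]), body, params)
  expect_equal(ref, params$prescription_gy / params$n_fractions,
               tolerance = 1e-9)
})

test_that("the phantom calibrates its planned regional D0.1cc to the targets", {
  ph <- cached_phantom()
  for (reg in names(ph$spec$planned_dmax_gy))
    expect_equal(ph$planned[[reg]], ph$spec$planned_dmax_gy[[reg]],
                 tolerance = 1 / ph$spec$planned_dmax_gy[[reg]])  # +/- 1 Gy
  # the planned grid reproduces the same regional Dmax (same voxel centres)
  for (reg in names(ph$planned)) {
    ras <- rasterize_structure(ph$sc_regions[[reg]], ph$plan)
    expect_equal(dmax_vol(ph$plan, ras, 0.1), ph$planned[[reg]],
                 tolerance = 1e-9)
  }
})

test_that("the phantom geometry is deterministic and self-consistent", {
  ph <- cached_phantom()
  ph2 <- make_phantom(compute_plan = FALSE)
  expect_identical(ph2$planned, ph$planned)
  expect_identical(ph2$params$notch_depth, ph$params$notch_depth)
  expect_identical(structure_slices(ph2$external),
                   structure_slices(ph$external))
  # cord cylinder strictly inside the body on every shared slice
  for (ct in ph$sc$contours) {
    k <- which(abs(structure_slices(ph$external) - ct$y_slice) < 1e-9)
    expect_true(all(point_in_polygon(ct$points[, 1], ct$points[, 2],
                                     ph$external$contours[[k]]$points)))
  }
  # planning SSA per region sits near the configured anchors
  for (reg in names(ph$spec$body_area_cm2))
    expect_equal(region_ssa(ph$external, reg, ph$partition),
                 unname(ph$spec$body_area_cm2[reg]), tolerance = 0.05)
  expect_error(phantom_spec(cord_center = c(0, -70)), "inside the")
})
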