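test_that("displace_structure is rigid and invertible", {
  s <- cylinder_structure(8, seq(0.5, 19.5, by = 1), n = 36)
  expect_equal(displace_structure(s, c(0, 0, 0)), s)
  sh <- c(3.2, -1.5, 2.7)
  back <- displace_structure(displace_structure(s, sh), -sh)
  for (i in seq_along(s$contours)) {
    expect_equal(back$contours[[i]]$points, s$contours[[i]]$points,
                 tolerance = 1e-12)
    expect_equal(polygon_area(displace_structure(s, sh)$contours[[i]]),
                 polygon_area(s$contours[[i]]))
  }
  # pure posterior shift moves every vertex 8 mm posterior (negative z)
  post <- displace_structure(s, c(0, 0, -8))
  expect_equal(post$contours[[1]]$points[, 2],
               s$contours[[1]]$points[, 2] - 8)
  expect_equal(post$contours[[1]]$points[, 1], s$contours[[1]]$points[, 1])
})

test_that("zero shift reproduces the planned Dmax exactly", {
  g <- ramp_grid(g = 0.4, offset = 30)
  s <- cylinder_structure(5, seq(-10.5, 10.5, by = 1), n = 36)
  est <- dmax_displaced(g, s, c(0, 0, 0))
  expect_identical(est$dmax_displaced, est$dmax_planned)
  expect_equal(est$percent_change, 0)
})

test_that("on a linear ramp the Dmax change equals gradient times shift", {
  grad <- 0.5                                   # Gy/mm along z
  g <- ramp_grid(g = grad, offset = 50)
  s <- cylinder_structure(5, seq(-10.5, 10.5, by = 1), n = 36)
  base <- dmax_displaced(g, s, c(0, 0, 0))$dmax_planned
  for (dz in c(-6, -1.3, 0.6, 4)) {
    est <- dmax_displaced(g, s, c(0, 0, dz))
    expect_equal(est$dmax_displaced - est$dmax_planned, grad * dz,
                 tolerance = 1e-6)
    expect_equal(est$dmax_planned, base)
  }
  # shifts along the flat directions change nothing
  est_x <- dmax_displaced(g, s, c(3, 0, 0))
  expect_equal(est_x$dmax_displaced, base, tolerance = 1e-9)
})

test_that("displacing the structure equals counter-displacing the grid", {
  g <- radial_grid(base = 25, amp = 12, s = 10)
  s <- cylinder_structure(4, seq(-8.5, 8.5, by = 1), n = 36, cx = 2, cz = 3)
  for (sh in list(c(2.4, 0, -1.2), c(-3, 1, 2), c(0.7, -2, 0))) {
    via_structure <- dmax_displaced(g, s, sh)$dmax_displaced
    g_moved <- dose_grid(g$values, g$origin - sh, g$spacing)
    via_grid <- dmax_displaced(g_moved, s, c(0, 0, 0))$dmax_displaced
    expect_equal(via_structure, via_grid, tolerance = 0.1)
  }
})

test_that("the estimate converges to the planned Dmax as the shift vanishes", {
  g <- radial_grid(base = 25, amp = 12, s = 10)
  s <- cylinder_structure(4, seq(-8.5, 8.5, by = 1), n = 36)
  planned <- dmax_displaced(g, s, c(0, 0, 0))$dmax_planned
  shifts <- 8 / 2^(0:6)
  errs <- vapply(shifts, function(m)
    abs(dmax_displaced(g, s, m * c(1, 0, 1) / sqrt(2))$dmax_displaced -
          planned),
    numeric(1))
  # the field gradient at the cord edge bounds the true change:
  # |d'(r)| <= amp * r/s^2 * exp(-r^2/2s^2) ~ 0.44 Gy/mm at r = 4
  expect_true(all(errs <= 0.65 * shifts + 1e-9))
  expect_lt(errs[length(errs)], errs[1])
})

test_that("estimates on a radial field depend only on the shift magnitude", {
  g <- radial_grid(base = 25, amp = 12, s = 10)
  s <- cylinder_structure(4, seq(-8.5, 8.5, by = 1), n = 36)
  m <- 4
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1), c(0, 0, -1),
               c(1, 0, 1) / sqrt(2), c(-1, 0, 1) / sqrt(2))
  ests <- vapply(dirs, function(u)
    dmax_displaced(g, s, m * u)$dmax_displaced, numeric(1))
  expect_lt(max(ests) - min(ests), 0.5)
})

test_that("out-of-extent displacements raise a named error", {
  g <- ramp_grid(n = 21)
  s <- cylinder_structure(5, seq(-5.5, 5.5, by = 1), n = 36,
                          name = "C1_C3")
  expect_error(dmax_displaced(g, s, c(100, 0, 0)), "C1_C3")
  expect_error(dmax_displaced(g, s, c(0, 0, 9)), "C1_C3")
})

test_that("fit_displaced_vs_setup recovers exact linear relations", {
  x <- c(30, 32, 35, 36, 38, 40)
  f <- fit_displaced_vs_setup(x, 2 + 0.9 * x)
  expect_equal(f$slope, 0.9)
  expect_equal(f$intercept, 2)
  expect_equal(f$r_squared, 1)
  ident <- fit_displaced_vs_setup(x, x)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$residual_sd, 0)
  expect_error(fit_displaced_vs_setup(rep(35, 5), rnorm(5)), "zero variance")
  expect_error(fit_displaced_vs_setup(1:2, 1:2), "3 pairs")
  by_reg <- fit_displaced_vs_setup(c(x, x), c(x, 1 + x),
                                   region = rep(c("a", "b"), each = 6),
                                   mode = "by_region")
  expect_equal(by_reg$a$intercept, 0)
  expect_equal(by_reg$b$intercept, 1)
})

test_that("trigger_replan flags constraint violations deterministically", {
  est <- data.frame(region = c("C1_C3", "C4_C5", "C6_C7"),
                    dmax_displaced = c(39.5, 38.0, 33.0),
                    percent_change = c(5, 4, -1))
  rep0 <- trigger_replan(est, 40)
  expect_false(rep0$any_flag)
  expect_equal(rep0$worst_region, "C1_C3")
  est$dmax_displaced[1] <- 40.1
  rep1 <- trigger_replan(est, 40)
  expect_true(rep1$any_flag)
  expect_equal(rep1$table$flag, c(TRUE, FALSE, FALSE))
  # PRV-style constraint at 45 Gy flags only true excursions above 45
  est$dmax_displaced <- c(44.9, 45.2, 40)
  rep2 <- trigger_replan(est, 45)
  expect_equal(rep2$table$flag[rep2$table$region == "C4_C5"], TRUE)
  expect_equal(sum(rep2$table$flag), 1L)
  expect_error(trigger_replan(est[0, ], 40), "no estimates")
})
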