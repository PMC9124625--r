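# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# The default synthetic phantom (with its planned dose grid). ~30 s to build,
# shared by every test that needs realistic geometry.
cached_phantom <- function() {
  if (is.null(.fixture_cache$phantom))
    .fixture_cache$phantom <- make_phantom()
  .fixture_cache$phantom
}

# A small default-model course on the cached phantom (2 patients).
cached_small_course <- function() {
  if (is.null(.fixture_cache$small_course))
    .fixture_cache$small_course <- sample_course(
      uncertainty_model(), cached_phantom(), n_patients = 2, seed = 11)
  .fixture_cache$small_course
}

# Square contour of side `side` mm centred at (cx, cz).
square_contour <- function(y, side = 10, cx = 0, cz = 0) {
  h <- side / 2
  contour(y, cbind(c(cx - h, cx + h, cx + h, cx - h),
                   c(cz - h, cz - h, cz + h, cz + h)))
}

# Regular n-gon approximating a circle of radius r. With `match_area` the
# vertex radius is inflated so the polygon area equals pi * r^2 exactly.
circle_contour <- function(y, r, n = 360, cx = 0, cz = 0,
                           match_area = FALSE) {
  if (match_area) r <- r / sqrt((n / (2 * pi)) * sin(2 * pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour(y, cbind(cx + r * cos(th), cz + r * sin(th)), check = FALSE)
}

# Cylinder structure along y: area-matched circles at every slice position.
cylinder_structure <- function(r, y_slices, n = 90, cx = 0, cz = 0,
                               name = "cyl") {
  rt_structure(name, lapply(y_slices, function(y)
    circle_contour(y, r, n, cx, cz, match_area = TRUE)))
}

# Dose grid with a linear ramp g Gy/mm along z (plus offset), on a cube.
ramp_grid <- function(g = 0.5, offset = 50, n = 41, spacing = 1) {
  half <- (n - 1) / 2 * spacing
  z <- seq(-half, half, by = spacing)
  vals <- array(rep(offset + g * z, each = n * n), c(n, n, n))
  dose_grid(vals, origin = c(-half, -half, -half), spacing = rep(spacing, 3))
}

# Smooth radially symmetric dose field centred on the (cx, cz) axis:
# d(r) = base + amp * (1 - exp(-r^2 / (2 * s^2))). Gradient-free at the axis.
radial_grid <- function(base = 30, amp = 10, s = 12, n = 61, spacing = 1,
                        cx = 0, cz = 0) {
  half <- (n - 1) / 2 * spacing
  ax <- seq(-half, half, by = spacing)
  r2 <- outer((ax - cx)^2, (ax - cz)^2, "+")
  slab <- base + amp * (1 - exp(-r2 / (2 * s^2)))
  vals <- aperm(array(rep(slab, n), c(n, n, n)), c(1, 3, 2))
  dose_grid(vals, origin = c(-half, -half, -half), spacing = rep(spacing, 3))
}
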