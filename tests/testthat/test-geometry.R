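test_that("packaged presets carry the documented construction parameters", {
  g <- mlc_preset("hd120")
  expect_length(g$leaf_widths_iso, 60)
  expect_equal(g$physical_thickness, 6.9)
  expect_equal(g$tip_radius, 16)
  expect_equal(g$tip_angle, 0)
  expect_equal(g$density, 18.9)
  expect_equal(projected_field_length(g), 22.0)
  expect_equal(sum(g$leaf_widths_iso == 0.25), 32)
  expect_equal(sum(g$leaf_widths_iso == 0.5), 28)

  m <- mlc_preset("millennium120")
  expect_equal(m$tip_radius, 8)
  expect_equal(m$tip_angle, 11.3)
  expect_equal(m$physical_thickness, 6.7)
  expect_equal(projected_field_length(m), 40.0)
})

test_that("a toy table round-trips exactly through the config files", {
  dir <- tempfile("mlc")
  tb <- synthesize_mlc_tables("hd120", tg_width = 0.05, air_gap = 0.01)
  write_mlc_config(tb, dir)
  g <- load_mlc_config(file.path(dir, "upperhalf.table"),
                       file.path(dir, "lowerhalf.table"),
                       file.path(dir, "particledmlc.config"))
  expect_equal(g$upper_table$y, tb$upper$y, tolerance = 1e-6)
  expect_equal(g$upper_table$thickness, tb$upper$thickness, tolerance = 1e-6)
  expect_equal(g$lower_table$leaf, tb$lower$leaf)
  expect_equal(g$density, tb$config$density)
  expect_equal(g$leaf_widths_iso, tb$widths_iso)
})

test_that("malformed and inconsistent config files are rejected with context", {
  dir <- tempfile("bad")
  dir.create(dir)
  up <- file.path(dir, "up.table"); lo <- file.path(dir, "lo.table")
  cf <- file.path(dir, "c.config")
  writeLines(c("# ok", "1 0.0 3.0", "1 1.0 oops"), up)
  writeLines(c("1 0.0 3.0", "1 1.0 0"), lo)
  writeLines(c("density = 18", "tip_radius = 16", "z_upper = 50.9",
               "physical_thickness = 6.9", "inner_leaves = 1",
               "inner_width = 1", "outer_leaves = 0", "outer_width = 1"), cf)
  expect_error(load_mlc_config(up, lo, cf), "line 3")
  writeLines(c("1 0.0 3.0", "1 0.5 0", "2 0.5 3.0", "2 1.0 0"), up)
  expect_error(load_mlc_config(up, lo, cf), "leaf count")
  expect_error(load_mlc_config("nope.table", lo, cf), "not found")
})

test_that("leaf indexing is half-open and consistent with cumulative widths", {
  g <- mlc_preset("hd120")
  # the beam axis lies in the central quarter-cm section
  li <- leaf_index_at(g, 0.0)
  expect_equal(g$leaf_widths_iso[li$leaf_index], 0.25)
  # 5 cm off-axis lies in the outer half-cm section
  expect_equal(g$leaf_widths_iso[leaf_index_at(g, 5.0)$leaf_index], 0.5)
  # boundaries belong to the higher-index leaf with zero offset
  b <- cumsum(g$leaf_widths_iso) - 11
  i <- 17
  li <- leaf_index_at(g, b[i])
  expect_equal(li$leaf_index, i + 1L)
  expect_equal(li$offset_within_leaf, 0)
  expect_error(leaf_index_at(g, 11.5), "outside")
  # cumulative-width consistency across every leaf midpoint
  mids <- b - g$leaf_widths_iso[seq_along(b)] / 2 + 1e-9
  expect_equal(leaf_index_at(g, mids)$leaf_index, seq_len(60))
})

test_that("thickness profile matches a naive table walk and flags steps", {
  g <- mlc_preset("hd120")
  rng <- range(g$upper_table$y)
  set.seed(5)
  y <- runif(300, rng[1], rng[2])
  tp <- thickness_profile(g, y)
  expect_equal(tp$upper, thickness_walk(g$upper_table, y))
  expect_equal(tp$lower, thickness_walk(g$lower_table, y))
  expect_true(all(tp$upper + tp$lower <= g$physical_thickness + 1e-9))
  # mid-leaf body is full height; tongue-and-groove steps are strictly less
  tp0 <- thickness_profile(g, 0.06)
  expect_equal(tp0$upper + tp0$lower, 6.9)
  # inside the tongue/groove overlap at the first interior leaf boundary
  step_y <- g$upper_table$y[3] - 0.009
  tps <- thickness_profile(g, step_y)
  expect_lt(tps$upper + tps$lower, 6.9)
  expect_error(thickness_profile(g, rng[2] + 1), "outside")
})

test_that("tip chords match a dense ray-circle intersection to <0.1%", {
  g <- mlc_preset("hd120")
  for (off in c(0.05, 0.1, 0.2)) {
    got <- tip_thickness(g, off, 0)
    # dense numeric intersection with the tip circle (center at R, radius R)
    s <- seq(-g$physical_thickness / 2, g$physical_thickness / 2,
             length.out = 400001)
    inside <- off >= g$tip_radius - sqrt(pmax(g$tip_radius^2 - s^2, 0))
    ref <- mean(inside) * g$physical_thickness
    expect_equal(got, ref, tolerance = 1e-3)
  }
  # beyond the tip arc on the open side
  expect_equal(tip_thickness(g, -0.1, 0), 0)
  # deep in the body: full thickness
  expect_equal(tip_thickness(g, 8.2, 0), g$physical_thickness)
  # monotone non-decreasing into the leaf
  ch <- tip_thickness(g, seq(-0.5, 9, by = 0.01), 0)
  expect_true(all(diff(ch) >= -1e-12))
})

test_that("radiological path reproduces the closed-body and open values", {
  g <- mlc_preset("hd120")
  closed <- aperture_state(rep(2, 60), rep(2.3, 60))
  open <- aperture_state(rep(-5, 60), rep(5, 60))
  # near-axial ray through a leaf mid-body
  expect_equal(radiological_path(g, closed, ray_at_iso(0, 0.06)),
               6.9 * 18.9, tolerance = 1e-4)
  expect_identical(radiological_path(g, open, ray_at_iso(0, 0.06)), 0)
  expect_error(radiological_path(g, open, ray(c(0, 0, 60), c(1, 0, 0))),
               "parallel")
})

test_that("radiological path agrees with the dense-step volume oracle", {
  g <- mlc_preset("hd120")
  set.seed(11)
  n <- 120
  ap <- aperture_state(runif(60, -4, 0.5), runif(60, 0.6, 5))
  rays <- lapply(seq_len(n), function(i)
    ray_at_iso(runif(1, -5, 5), runif(1, -5, 5)))
  got <- radiological_path(g, ap, rays, n_steps = 256L)
  ref <- path_oracle(g, ap, rays, step = 0.004)
  # agreement within 1% of the full closed-body path
  expect_lt(max(abs(got - ref)), 0.01 * 6.9 * 18.9)
  nz <- ref > 1
  expect_lt(max(abs(got[nz] - ref[nz]) / ref[nz]), 0.015)
})

test_that("path scales exactly with density and is mirror-symmetric", {
  g <- toy_geometry()
  ap <- aperture_state(rep(0.5, 4), rep(1.5, 4))
  rays <- lapply(list(c(0.2, 0.3), c(-1, 1.4), c(2, -0.7)), function(p)
    ray_at_iso(p[1], p[2]))
  p1 <- radiological_path(g, ap, rays)
  g2 <- g; g2$density <- g$density * 2.5
  expect_equal(radiological_path(g2, ap, rays), 2.5 * p1)
  # mirror aperture and rays across the leaf-motion axis (y -> -y)
  n <- 4
  ap_m <- aperture_state(ap$bank_a[n:1], ap$bank_b[n:1])
  rays_m <- lapply(rays, function(r)
    ray(r$origin * c(1, -1, 1), r$direction * c(1, -1, 1)))
  expect_equal(radiological_path(g, ap_m, rays_m), p1, tolerance = 1e-9)
})

test_that("aperture and ray validation enforce the documented invariants", {
  expect_error(aperture_state(c(0, 2), c(1, 1)), "closed-pair")
  expect_error(aperture_state(0, 1, jaw_x1 = 2, jaw_x2 = -2), "jaw")
  expect_error(aperture_state(c(0, 0), 0), "same number")
  expect_error(ray(c(0, 0, 0), c(1, 1, 0)), "unit length")
  r <- ray(c(0, 0, 0), c(3, 4, 0), normalize = TRUE)
  expect_equal(sum(r$direction^2), 1, tolerance = 1e-15)
})
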