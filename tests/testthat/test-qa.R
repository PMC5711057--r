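# vectorized brute-force gamma oracle: evaluates every subgrid offset for
# every ROI voxel (no early termination), trilinear interpolation via
# shifted-slice combination on an NA-padded array
gamma_oracle_fast <- function(ref, eval, vox, dcrit, dta, roi_abs, cap, sub) {
  d <- dim(ref)
  rmax <- cap * dta
  m <- ceiling(rmax / min(vox)) + 2L
  pd <- d + 2L * m
  pad <- array(NA_real_, pd)
  pad[m + seq_len(d[1]), m + seq_len(d[2]), m + seq_len(d[3])] <- eval
  mx <- if (d[1] > 1) floor(rmax / sub) else 0
  my <- if (d[2] > 1) floor(rmax / sub) else 0
  mz <- if (d[3] > 1) floor(rmax / sub) else 0
  offs <- expand.grid(ox = (-mx:mx) * sub, oy = (-my:my) * sub,
                      oz = (-mz:mz) * sub)
  offs <- offs[offs$ox^2 + offs$oy^2 + offs$oz^2 <= rmax^2, ]
  best <- array(Inf, d)
  ii <- m + seq_len(d[1]); jj <- m + seq_len(d[2]); kk <- m + seq_len(d[3])
  for (o in seq_len(nrow(offs))) {
    f <- c(offs$ox[o], offs$oy[o], offs$oz[o]) / vox
    i0 <- floor(f); tf <- f - i0
    e <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, tf, 1 - tf))
      if (w == 0) next
      e <- e + w * pad[ii + i0[1] + cx, jj + i0[2] + cy, kk + i0[3] + cz]
    }
    g2 <- ((e - ref) / dcrit)^2 +
      (offs$ox[o]^2 + offs$oy[o]^2 + offs$oz[o]^2) / dta^2
    g2[is.na(g2)] <- Inf
    best <- pmin(best, g2)
  }
  out <- sqrt(best)
  out[ref <= roi_abs] <- NA_real_
  out
}

test_that("absolute dose conversion is the prescribed linear factor", {
  b <- seq(0, 2, by = 0.5)
  raw <- dose_grid(array(2e-16, c(4, 4, 4)), b, b, b,
                   relerr = array(0.01, c(4, 4, 4)))
  cal <- dose_calibration(d_cal_measured = 0.01, d_cal_mc = 1e-16)
  out <- absolute_dose(raw, cal, U = 100)
  expect_equal(out$dose, array(2.0, c(4, 4, 4)))
  expect_equal(out$relerr, raw$relerr)       # relative errors unchanged
  # zero dose stays zero; doubling U doubles the output
  raw0 <- dose_grid(array(0, c(4, 4, 4)), b, b, b)
  expect_true(all(absolute_dose(raw0, cal, 50)$dose == 0))
  expect_equal(absolute_dose(raw, cal, 200)$dose, 2 * out$dose)
  expect_error(dose_calibration(-1, 1), "positive")
  expect_error(dose_calibration(0.01, 1e-16, d_chback = 0.1), "zero")
  expect_error(absolute_dose(raw, cal, 0), "positive")
})

test_that("adaptive SG filter reproduces a noiseless quadratic exactly", {
  n <- 12
  b <- seq(0, n * 0.5, by = 0.5)
  cc <- (b[-1] + b[-length(b)]) / 2
  q <- function(x, y, z) 10 + 0.5 * x + 0.3 * y - 0.2 * z +
    0.05 * x^2 - 0.04 * y * z + 0.03 * x * y
  dose <- array(0, c(n, n, n))
  for (k in seq_len(n)) dose[, , k] <- outer(cc, cc, q, z = cc[k])
  g <- dose_grid(dose, b, b, b, relerr = array(0.02, c(n, n, n)))
  out <- sg_denoise(g)
  expect_equal(out$dose, dose, tolerance = 1e-10)
  expect_true(all(out$meta$sg_window == 4))
})

test_that("SG filter cuts 2% noise below 1% in the high-dose region", {
  fx <- make_noisy_gaussian_grid(n = 34, rel_noise = 0.02, seed = 7)
  hi <- fx$truth > 0.5
  pre <- sqrt(mean(((fx$grid$dose[hi] - fx$truth[hi]) / fx$truth[hi])^2))
  expect_gt(pre, 0.018)
  out <- sg_denoise(fx$grid)
  post <- sqrt(mean(((out$dose[hi] - fx$truth[hi]) / fx$truth[hi])^2))
  expect_lte(post, 0.01)
  # reported uncertainties shrink accordingly
  expect_lt(median(out$relerr[hi]), 0.01)
  # no bias: the mean over the flat top is preserved within statistics
  flat <- fx$truth > 0.95
  expect_equal(mean(out$dose[flat]), mean(fx$truth[flat]),
               tolerance = 3 * 0.02 / sqrt(sum(flat)))
})

test_that("SG filter leaves sharp steps unsmoothed where a fixed window blurs", {
  n <- 16
  b <- seq(0, n * 0.5, by = 0.5)
  dose <- array(1, c(n, 8, 8))
  dose[(n / 2 + 1):n, , ] <- 2
  g <- dose_grid(dose, b, seq(0, 4, 0.5), seq(0, 4, 0.5),
                 relerr = array(0.001, c(n, 8, 8)))
  adaptive <- sg_denoise(g)
  fixed <- sg_denoise(g, half_widths = 2, chi_mult = 1e12)
  step_rows <- (n / 2 - 1):(n / 2 + 2)
  dev_a <- max(abs(adaptive$dose[step_rows, , ] - dose[step_rows, , ]))
  dev_f <- max(abs(fixed$dose[step_rows, , ] - dose[step_rows, , ]))
  expect_lt(dev_a, 1e-6)      # adaptive window collapses at the step
  expect_gt(dev_f, 0.05)      # forced fixed window blurs it
  expect_error(sg_denoise(dose_grid(dose, b, seq(0, 4, 0.5),
                                    seq(0, 4, 0.5))), "uncertainty")
})

test_that("absolute dose conversion commutes with SG denoising", {
  fx <- make_noisy_gaussian_grid(n = 16, rel_noise = 0.02, seed = 9)
  g <- fx$grid
  g$dose <- g$dose * 1e-16
  cal <- dose_calibration(0.008, 1.1e-16)
  a <- sg_denoise(absolute_dose(g, cal, 250))
  b <- absolute_dose(sg_denoise(g), cal, 250)
  expect_equal(a$dose, b$dose, tolerance = 1e-9)
})

test_that("gamma is zero for identical grids and 1 at the 3% boundary", {
  set.seed(3)
  n <- 10
  b <- seq(0, n * 0.3, by = 0.3)
  base <- array(0.3 + runif(n^3), c(n, n, n))
  g <- dose_grid(base, b, b, b)
  r <- gamma_3d(g, g)
  expect_true(all(r$gamma[r$roi] == 0))
  expect_equal(r$pass_fraction, 1)
  # uniform +3% offset in a gradient-free region: gamma exactly 1
  flat <- dose_grid(array(1, c(n, n, n)), b, b, b)
  up <- dose_grid(array(1.03, c(n, n, n)), b, b, b)
  rf <- gamma_3d(flat, up, gamma_criteria(3, 3, 20))
  expect_equal(max(abs(rf$gamma[rf$roi] - 1)), 0, tolerance = 1e-12)
  # just under the criterion passes everywhere
  under <- dose_grid(array(1.029, c(n, n, n)), b, b, b)
  expect_equal(gamma_3d(flat, under)$pass_fraction, 1)
  expect_error(gamma_3d(g, dose_grid(base, b + 1, b, b)), "common")
})

test_that("gamma matches the exhaustive brute-force oracle on random grids", {
  set.seed(14)
  n <- 12
  vox <- 0.3
  b <- seq(0, n * vox, by = vox)
  ref <- array(0.2 + runif(n^3), c(n, n, n))
  eva <- ref * (1 + 0.03 * rnorm(n^3))
  gr <- dose_grid(ref, b, b, b)
  ge <- dose_grid(eva, b, b, b)
  crit <- gamma_criteria(3, 3, 80)
  res <- gamma_3d(gr, ge, crit, subsample_mm = 0.3, cap = 1.0)
  oracle <- gamma_oracle_fast(ref, eva, rep(vox, 3),
                              0.03 * max(ref), 0.3, 0.8 * max(ref),
                              1.0, 0.03)
  expect_equal(res$gamma, oracle, tolerance = 1e-9)
})

test_that("gamma comparison is asymmetric under grid exchange", {
  set.seed(8)
  n <- 10
  b <- seq(0, n * 0.3, by = 0.3)
  ref <- array(0.2 + runif(n^3), c(n, n, n))
  eva <- ref * (1 + 0.05 * rnorm(n^3)) * 1.05
  g1 <- dose_grid(ref, b, b, b); g2 <- dose_grid(eva, b, b, b)
  p12 <- gamma_3d(g1, g2)$pass_fraction
  p21 <- gamma_3d(g2, g1)$pass_fraction
  expect_false(isTRUE(all.equal(p12, p21)))
})

test_that("mean transmission reduces to the trivial and closed-form cases", {
  b <- seq(-7, 7, by = 0.5)
  one <- dose_grid(array(1, c(28, 28, 1)), b, b,
                   relerr = array(0, c(28, 28, 1)))
  expect_equal(mean_transmission(one, one), 1.0)
  # monoenergetic slab: ratio equals exp(-mu t) exactly
  tab <- attenuation_table()
  mu <- mu_lookup(tab, "tungsten", 2)$mu_over_rho
  att <- exp(-mu * 100)
  blocked <- dose_grid(array(att, c(28, 28, 1)), b, b)
  expect_equal(mean_transmission(blocked, one), att)
  zero <- dose_grid(array(0, c(28, 28, 1)), b, b)
  expect_error(mean_transmission(one, zero), "open")
})

test_that("density calibration is a fixed point and recovers a shifted density", {
  g <- mlc_preset("hd120")
  src <- beam_preset("6X")
  # simulate the transmission at a shifted density, then calibrate to it
  rho_star <- 16.5
  g2 <- g; g2$density <- rho_star
  fields <- make_transmission_fields(g2)
  grid <- plane_grid(xlim = c(-8, 8), ylim = c(-9, 9), voxel = 0.2,
                     depth_cm = 5)
  open <- simulate_delivery(fields$open, g2, src, grid, n_histories = 6e4,
                            seed = 5)
  blk <- simulate_delivery(fields$blocked, g2, src, grid, n_histories = 6e4,
                           seed = 5)
  t_star <- mean_transmission(blk, open)
  rho_hat <- calibrate_density(g, src, t_star, n_histories = 6e4, seed = 5,
                               bracket = c(10, 26))
  expect_equal(rho_hat, rho_star, tolerance = 0.01)
  expect_error(calibrate_density(g, src, 0.5), "0.1")
})

test_that("output factors are unity-anchored and near-unity in this model", {
  g <- mlc_preset("hd120")
  src <- beam_preset("6X")
  grid <- plane_grid(xlim = c(-2, 2), ylim = c(-2, 2), voxel = 0.5,
                     depth_cm = 10)
  sq <- function(hw) {
    ap <- aperture_state(rep(-hw, 60), rep(hw, 60), jaw_x1 = -hw,
                         jaw_x2 = hw, jaw_y1 = -hw, jaw_y2 = hw)
    simulate_delivery(ap, g, src, grid, n_histories = 3e4, seed = 13)
  }
  d10 <- sq(5)
  expect_equal(output_factor(d10, d10), 1.0)
  # linearity: a half-weight copy gives exactly 0.5
  half <- d10; half$dose <- d10$dose / 2
  expect_equal(output_factor(half, d10), 0.5)
  # no head scatter in the model: a 5x5 field stays close to the reference
  d5 <- sq(2.5)
  of <- output_factor(d5, d10)
  expect_gt(of, 0.9); expect_lt(of, 1.1)
  zero <- d10; zero$dose <- d10$dose * 0
  expect_error(output_factor(d10, zero), "zero")
})
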