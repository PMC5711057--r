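# Independent oracles and small fixture builders used across the suite.

# A minimal geometry with uniform-thickness leaves, no tongue-and-groove and
# no interleaf gap: each half-table row spans one leaf at full half height.
toy_geometry <- function(n_leaves = 4, width_iso = 1, h = 6, tip_radius = 8,
                         density = 10, z_upper = 50, tip_angle = 0) {
  z_mid <- z_upper + h / 2
  b <- (cumsum(c(0, rep(width_iso, n_leaves))) -
          n_leaves * width_iso / 2) * z_mid / 100
  tab <- data.frame(leaf = c(seq_len(n_leaves), n_leaves),
                    y = b,
                    thickness = c(rep(h / 2, n_leaves), 0))
  mlc_geometry("toy", rep(width_iso, n_leaves), tab, tab,
               physical_thickness = h, tip_radius = tip_radius,
               tip_angle = tip_angle, density = density,
               leaf_offset = 0, z_upper = z_upper)
}

# ray from the source point aimed at an isocenter-plane coordinate
ray_at_iso <- function(xi, yi, sad = 100) {
  d <- c(xi, yi, -sad)
  ray(c(0, 0, sad), d / sqrt(sum(d^2)))
}

# naive row-walk thickness lookup (independent of findInterval-based code)
thickness_walk <- function(tab, y) {
  vapply(y, function(yy) {
    t <- 0
    for (r in seq_len(nrow(tab) - 1)) {
      if (tab$y[r] <= yy && yy < tab$y[r + 1]) { t <- tab$thickness[r]; break }
    }
    t
  }, numeric(1))
}

leaf_walk <- function(tab, y) {
  vapply(y, function(yy) {
    lf <- NA_integer_
    for (r in seq_len(nrow(tab) - 1)) {
      if (tab$y[r] <= yy && yy < tab$y[r + 1]) { lf <- tab$leaf[r]; break }
    }
    lf
  }, integer(1))
}

# dense-step radiological path oracle: walks the leaf assembly in fine steps
# with occupancy logic written directly against the raw geometry fields
path_oracle <- function(geometry, aperture, rays, step = 0.005) {
  if (inherits(rays, "mlc_ray")) rays <- list(rays)
  h <- geometry$physical_thickness
  z_u <- geometry$z_upper
  z_mid <- z_u + h / 2
  R <- geometry$tip_radius
  alpha <- geometry$tip_angle * pi / 180
  ucap <- min(geometry$tip_max_thickness, h) / 2
  face_b <- function(pos_iso, s) {
    m <- pos_iso / geometry$sad
    xc <- m * z_mid + R * sqrt(1 + m^2) + geometry$leaf_offset / 2
    u <- pmin(abs(s - z_mid), ucap)
    if (alpha > 0) {
      ut <- R * sin(alpha)
      arc <- ifelse(u <= ut, sqrt(pmax(R^2 - u^2, 0)),
                    R * cos(alpha) - (u - ut) * tan(alpha))
    } else arc <- sqrt(pmax(R^2 - pmin(u, R)^2, 0))
    xc - arc
  }
  vapply(rays, function(rr) {
    o <- rr$origin; d <- rr$direction
    if (d[3] > 0) d <- -d
    os <- geometry$sad - o[3]
    dx <- -d[1] / d[3]; dy <- -d[2] / d[3]
    slant <- sqrt(1 + dx^2 + dy^2)
    s <- seq(z_u + step / 2, z_u + h - step / 2, by = step)
    s <- s[s >= os]
    x <- o[1] + dx * (s - os)
    y <- o[2] + dy * (s - os)
    yt <- y * z_mid / s
    up <- s < z_mid
    th <- numeric(length(s)); lf <- integer(length(s))
    th[up] <- thickness_walk(geometry$upper_table, yt[up])
    lf[up] <- leaf_walk(geometry$upper_table, yt[up])
    th[!up] <- thickness_walk(geometry$lower_table, yt[!up])
    lf[!up] <- leaf_walk(geometry$lower_table, yt[!up])
    occ_z <- ifelse(up, s >= z_mid - th, s < z_mid + th) & th > 0 &
      !is.na(lf)
    occ <- rep(FALSE, length(s))
    ok <- which(occ_z)
    if (length(ok)) {
      pa <- aperture$bank_a[lf[ok]]
      pb <- aperture$bank_b[lf[ok]]
      fa <- -face_b(-pa, s[ok])
      fb <- face_b(pb, s[ok])
      occ[ok] <- x[ok] <= fa | x[ok] >= fb
    }
    sum(occ) * step * slant * geometry$density
  }, numeric(1))
}

# Klein-Nishina quadrature: mean scattered-to-incident energy ratio
kn_mean_ratio <- function(e_mev) {
  k <- e_mev / 0.51099895
  w <- function(theta) {
    eps <- 1 / (1 + k * (1 - cos(theta)))
    sin(theta) * eps^2 * (eps + 1 / eps - sin(theta)^2)
  }
  num <- stats::integrate(function(t) w(t) / (1 + k * (1 - cos(t))),
                          0, pi, rel.tol = 1e-10)$value
  den <- stats::integrate(w, 0, pi, rel.tol = 1e-10)$value
  num / den
}

# brute-force gamma oracle: full scan of the subsampled neighborhood with
# trilinear interpolation, no early termination
gamma_oracle <- function(ref, eval, vox, dcrit, dta, roi_abs, cap, sub) {
  d <- dim(ref)
  trilin <- function(x, y, z) {
    if (x < 0 || y < 0 || z < 0 || x > d[1] - 1 || y > d[2] - 1 ||
        z > d[3] - 1) return(NA_real_)
    i0 <- if (d[1] == 1) 0 else min(floor(x), d[1] - 2)
    j0 <- if (d[2] == 1) 0 else min(floor(y), d[2] - 2)
    k0 <- if (d[3] == 1) 0 else min(floor(z), d[3] - 2)
    fx <- if (d[1] == 1) 0 else x - i0
    fy <- if (d[2] == 1) 0 else y - j0
    fz <- if (d[3] == 1) 0 else z - k0
    i1 <- min(i0 + 1, d[1] - 1); j1 <- min(j0 + 1, d[2] - 1)
    k1 <- min(k0 + 1, d[3] - 1)
    at <- function(i, j, k) eval[i + 1, j + 1, k + 1]
    c00 <- at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx
    c10 <- at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx
    c01 <- at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx
    c11 <- at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx
    (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
  }
  rmax <- cap * dta
  mx <- if (d[1] > 1) floor(rmax / sub) else 0
  my <- if (d[2] > 1) floor(rmax / sub) else 0
  mz <- if (d[3] > 1) floor(rmax / sub) else 0
  offs <- expand.grid(ox = (-mx:mx) * sub, oy = (-my:my) * sub,
                      oz = (-mz:mz) * sub)
  offs <- offs[offs$ox^2 + offs$oy^2 + offs$oz^2 <= rmax^2, ]
  g <- array(NA_real_, d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        dr <- ref[i, j, k]
        if (dr <= roi_abs) next
        best <- Inf
        for (o in seq_len(nrow(offs))) {
          de <- trilin(i - 1 + offs$ox[o] / vox[1],
                       j - 1 + offs$oy[o] / vox[2],
                       k - 1 + offs$oz[o] / vox[3])
          if (is.na(de)) next
          g2 <- ((de - dr) / dcrit)^2 +
            (offs$ox[o]^2 + offs$oy[o]^2 + offs$oz[o]^2) / dta^2
          if (g2 < best) best <- g2
        }
        g[i, j, k] <- sqrt(best)
      }
  g
}

# smooth 3D phantom dose with matched noise, for denoising tests
make_noisy_gaussian_grid <- function(n = 50, rel_noise = 0.02, seed = 42) {
  set.seed(seed)
  cc <- seq(-6, 6, length.out = n)
  xb <- seq(-6.12, 6.12, length.out = n + 1)
  truth <- array(0, c(n, n, n))
  for (k in seq_len(n))
    truth[, , k] <- outer(cc, cc, function(x, y)
      exp(-((sqrt(x^2 + y^2)) / 4)^8)) * exp(-0.07 * (cc[k] + 6))
  truth <- truth / max(truth)
  noisy <- pmax(truth * (1 + stats::rnorm(n^3, 0, rel_noise)), 0)
  list(truth = truth,
       grid = dose_grid(noisy, xb, xb, xb,
                        relerr = array(rel_noise, c(n, n, n))))
}
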