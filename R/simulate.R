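#' Grid specifications for simulation scoring
#'
#' `plane_grid()` scores on a plane through the isocenter perpendicular to
#' the beam axis at a stated water-equivalent depth (the usual film-plane
#' setup). `grid3d()` scores collision kerma in a water box fixed in the room
#' frame with a track-length estimator; the water-equivalent depth of each
#' deposition is measured from where the ray enters the box.
#'
#' @param xlim,ylim,zlim extents (cm at the isocenter plane).
#' @param voxel voxel size (cm); scalar or per-axis.
#' @param depth_cm water-equivalent depth of the scoring plane (cm).
#' @return a grid specification list.
#' @export
plane_grid <- function(xlim = c(-10, 10), ylim = c(-10, 10), voxel = 0.2,
                       depth_cm = 5) {
  voxel <- rep_len(voxel, 2)
  list(type = "plane",
       xb = seq(xlim[1], xlim[2], by = voxel[1]),
       yb = seq(ylim[1], ylim[2], by = voxel[2]),
       depth_cm = depth_cm)
}

#' @rdname plane_grid
#' @export
grid3d <- function(xlim = c(-8, 8), ylim = c(-8, 8), zlim = c(-8, 8),
                   voxel = 0.5) {
  voxel <- rep_len(voxel, 3)
  list(type = "box",
       xb = seq(xlim[1], xlim[2], by = voxel[1]),
       yb = seq(ylim[1], ylim[2], by = voxel[2]),
       zb = seq(zlim[1], zlim[2], by = voxel[3]))
}

# beam frame -> room frame rotation about +y (IEC gantry angle)
.gantry_rotate <- function(x, y, z, theta_deg) {
  th <- theta_deg * pi / 180
  list(x = x * cos(th) + z * sin(th), y = y,
       z = -x * sin(th) + z * cos(th))
}

# accumulate box-kerma batch sums; gantry is a per-photon angle vector
.score_box_acc <- function(acc, photons, gantry, spec, table, batch) {
  xb <- spec$xb; yb <- spec$yb; zb <- spec$zb
  nx <- length(xb) - 1L; ny <- length(yb) - 1L; nz <- length(zb) - 1L
  nvox <- nx * ny * nz
  p <- .gantry_rotate(photons$x, photons$y, photons$z, gantry)
  d <- .gantry_rotate(photons$ux, photons$uy, photons$uz, gantry)
  t0 <- rep(-Inf, nrow(photons)); t1 <- rep(Inf, nrow(photons))
  for (ax in list(list(p$x, d$x, range(xb)), list(p$y, d$y, range(yb)),
                  list(p$z, d$z, range(zb)))) {
    o <- ax[[1]]; dd <- ax[[2]]; r <- ax[[3]]
    safe <- abs(dd) > 1e-12
    tt1 <- ifelse(safe, (r[1] - o) / dd, -Inf)
    tt2 <- ifelse(safe, (r[2] - o) / dd, Inf)
    lo <- pmin(tt1, tt2); hi <- pmax(tt1, tt2)
    out_par <- !safe & (o < r[1] | o > r[2])
    lo[out_par] <- Inf
    t0 <- pmax(t0, lo); t1 <- pmin(t1, hi)
  }
  hit <- t1 > t0 & is.finite(t0) & t1 > 0
  if (!any(hit)) return(acc)
  t0 <- pmax(t0, 0)
  step <- min(diff(xb)[1], diff(yb)[1], diff(zb)[1])
  lk <- mu_lookup(table, "water", photons$energy)
  conv <- photons$weight * photons$energy * lk$muen_over_rho *
    .MEV_PER_G_TO_GY
  idx <- which(hit)
  nsteps <- ceiling(max((t1[idx] - t0[idx]) / step))
  for (k in seq_len(nsteps)) {
    tk <- t0[idx] + (k - 0.5) * step
    live <- tk < t1[idx]
    if (!any(live)) break
    ii <- idx[live]
    px <- p$x[ii] + d$x[ii] * tk[live]
    py <- p$y[ii] + d$y[ii] * tk[live]
    pz <- p$z[ii] + d$z[ii] * tk[live]
    ix <- .voxel_index(px, xb); iy <- .voxel_index(py, yb)
    iz <- .voxel_index(pz, zb)
    ok <- !is.na(ix) & !is.na(iy) & !is.na(iz)
    if (!any(ok)) next
    j <- ii[ok]
    depth <- tk[live][ok] - t0[j]
    w <- conv[j] * exp(-lk$mu_over_rho[j] * depth) * step
    vox <- (iz[ok] - 1L) * nx * ny + (iy[ok] - 1L) * nx + ix[ok]
    key <- (batch[j] - 1L) * nvox + vox
    sums <- rowsum(w, key)
    keys <- as.integer(rownames(sums))
    pos <- cbind((keys - 1L) %% nvox + 1L, (keys - 1L) %/% nvox + 1L)
    acc[pos] <- acc[pos] + sums[, 1]
  }
  acc
}

#' Run a full Monte Carlo delivery simulation
#'
#' The complete pipeline per history: draw a meterset fraction, interpolate
#' the machine state (gantry, jaws, leaves), sample a source photon inside
#' the jaw-defined field, transport it through the MLC (deterministic
#' primary attenuation plus one forced first-Compton scatter), and score
#' collision kerma on the requested grid with batch uncertainties. Results
#' are bitwise reproducible for a fixed seed.
#'
#' Plane scoring is performed in the beam frame (the scoring plane follows
#' the gantry, as a film fixed in a gantry-mounted phantom would); box
#' scoring is performed in the room frame, so a rotating delivery
#' accumulates dose from all directions.
#'
#' @param plan an [mlc_plan()] or a static [aperture_state()].
#' @param geometry an [mlc_geometry()].
#' @param source a [source_model()]; defaults to the plan's beam preset.
#' @param grid a [plane_grid()] or [grid3d()] specification.
#' @param n_histories number of source histories (>= 1).
#' @param seed integer seed controlling all sampling.
#' @param n_batch batches for uncertainty estimation.
#' @param scatter carry first-Compton MLC scatter (default TRUE).
#' @param n_steps MLC tracer integration steps.
#' @param chunk histories per processing chunk.
#' @return a [dose_grid()] in Gy per source particle, with `meta` recording
#'   seed, histories and the plan name.
#' @export
simulate_delivery <- function(plan, geometry, source = NULL,
                              grid = plane_grid(), n_histories = 1e5,
                              seed = 1L, n_batch = 10L, scatter = TRUE,
                              n_steps = 128L, chunk = 2e4) {
  if (inherits(plan, "aperture_state")) {
    plan <- mlc_plan(list(control_point(0, 0, plan),
                          control_point(1, 0, plan)),
                     total_mu = 100, name = "static")
  }
  stopifnot(inherits(plan, "mlc_plan"), n_histories >= 1)
  if (is.null(source)) source <- beam_preset(plan$beam)
  set.seed(as.integer(seed))
  n_histories <- as.integer(n_histories)
  n_batch <- as.integer(n_batch)
  chunk <- as.integer(chunk)
  table <- attenuation_table()
  static <- length(plan$control_points) == 2 &&
    identical(plan$control_points[[1]]$aperture,
              plan$control_points[[2]]$aperture) &&
    plan$control_points[[1]]$gantry_angle_deg ==
      plan$control_points[[2]]$gantry_angle_deg
  is_plane <- identical(grid$type, "plane")
  nx <- length(grid$xb) - 1L; ny <- length(grid$yb) - 1L
  nz <- if (is_plane) 1L else length(grid$zb) - 1L
  acc <- matrix(0, nx * ny * nz, n_batch)
  n_missed <- 0L
  # meterset-averaged jaw field area at the isocenter (per-unit-fluence
  # normalization across different field sizes, used by output_factor)
  st0 <- sample_control_point_state(plan, seq(0, 1, length.out = 101))
  field_area <- mean((st0$jaws[2, ] - st0$jaws[1, ]) *
                       (st0$jaws[4, ] - st0$jaws[3, ]))
  starts <- seq(1L, n_histories, by = chunk)
  for (i0 in starts) {
    m <- min(chunk, n_histories - i0 + 1L)
    u <- stats::runif(m)
    st <- sample_control_point_state(plan, u)
    fr <- list(x1 = min(st$jaws[1, ]), x2 = max(st$jaws[2, ]),
               y1 = min(st$jaws[3, ]), y2 = max(st$jaws[4, ]))
    ph <- sample_source_photon(source, fr, m, sad = geometry$sad)
    # per-history jaw rejection (exact for dynamic jaws)
    xi <- ph$x * geometry$sad / (geometry$sad - ph$z)
    yi <- ph$y * geometry$sad / (geometry$sad - ph$z)
    inside <- xi >= st$jaws[1, ] & xi < st$jaws[2, ] &
      yi >= st$jaws[3, ] & yi < st$jaws[4, ]
    keep <- which(inside)
    if (!length(keep)) next
    ap <- if (static) plan$control_points[[1]]$aperture else
      list(bank_a = st$bank_a[, keep, drop = FALSE],
           bank_b = st$bank_b[, keep, drop = FALSE])
    out <- transport_through_mlc(ph[keep, , drop = FALSE], geometry, ap,
                                 table = table, scatter = scatter,
                                 n_steps = n_steps)
    hist_id <- (i0:(i0 + m - 1L))[keep][out$parent]
    batch <- ((hist_id - 1L) %% n_batch) + 1L
    if (is_plane) {
      stt <- .score_plane_acc(acc, n_missed, out, grid$xb, grid$yb,
                              grid$depth_cm, table, batch, n_batch)
      acc <- stt$acc; n_missed <- stt$n_missed
    } else {
      gantry <- st$gantry[keep][out$parent]
      acc <- .score_box_acc(acc, out, gantry, grid, table, batch)
    }
  }
  if (is_plane) {
    .finalize_grid(acc, nx, ny, 1L, grid$xb, grid$yb, c(-0.05, 0.05),
                   n_histories, n_batch,
                   per_area = outer(diff(grid$xb), diff(grid$yb)),
                   meta = list(seed = seed, n_histories = n_histories,
                               plan = plan$name, depth_cm = grid$depth_cm,
                               field_area_iso = field_area,
                               n_missed = n_missed))
  } else {
    vol <- diff(grid$xb)[1] * diff(grid$yb)[1] * diff(grid$zb)[1]
    .finalize_grid(acc, nx, ny, nz, grid$xb, grid$yb, grid$zb,
                   n_histories, n_batch, per_vol = vol,
                   meta = list(seed = seed, n_histories = n_histories,
                               plan = plan$name,
                               field_area_iso = field_area))
  }
}
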