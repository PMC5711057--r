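#' Dose grid container
#'
#' A 3D (or planar, with a single slice along z) dose array with per-voxel
#' relative statistical uncertainty and geometry metadata. Boundaries follow
#' the half-open voxel convention: a voxel spans `[b_i, b_{i+1})`.
#'
#' @param dose numeric array (nx x ny x nz); a matrix is treated as a single
#'   z slice.
#' @param xb,yb,zb voxel boundary vectors (cm), lengths `nx+1`, `ny+1`,
#'   `nz+1`.
#' @param relerr relative uncertainty array matching `dose` (fraction);
#'   defaults to zeros.
#' @param meta named list of provenance fields (seed, histories, ...).
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(dose, xb, yb, zb = c(-0.5, 0.5), relerr = NULL,
                      meta = list()) {
  if (is.matrix(dose)) dose <- array(dose, c(dim(dose), 1L))
  stopifnot(length(dim(dose)) == 3)
  if (is.null(relerr)) relerr <- array(0, dim(dose))
  if (is.matrix(relerr)) relerr <- array(relerr, c(dim(relerr), 1L))
  d <- dim(dose)
  stopifnot(length(xb) == d[1] + 1, length(yb) == d[2] + 1,
            length(zb) == d[3] + 1, all(dim(relerr) == d),
            all(diff(xb) > 0), all(diff(yb) > 0), all(diff(zb) > 0))
  if (any(dose < 0)) stop("dose must be non-negative")
  if (any(relerr < 0)) stop("relative uncertainty must be non-negative")
  structure(list(dose = dose, relerr = relerr,
                 xb = as.numeric(xb), yb = as.numeric(yb),
                 zb = as.numeric(zb), meta = meta),
            class = "dose_grid")
}

.voxel_centers <- function(b) (b[-1] + b[-length(b)]) / 2

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$dose)
  cat("<dose_grid> ", d[1], " x ", d[2], " x ", d[3], " voxels\n", sep = "")
  cat("  extent x [", min(x$xb), ", ", max(x$xb), "] y [", min(x$yb), ", ",
      max(x$yb), "] z [", min(x$zb), ", ", max(x$zb), "] cm\n", sep = "")
  cat("  max dose ", format(max(x$dose)), ", median rel. err. in dose > 50% max: ",
      format(round(stats::median(x$relerr[x$dose > 0.5 * max(x$dose)]), 4)),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.dose_grid <- function(object, ...) {
  hi <- object$dose > 0.5 * max(object$dose)
  out <- list(dim = dim(object$dose), max_dose = max(object$dose),
              mean_relerr_high = mean(object$relerr[hi]),
              meta = object$meta)
  class(out) <- "summary.dose_grid"
  out
}

#' @export
print.summary.dose_grid <- function(x, ...) {
  cat("dose_grid: ", paste(x$dim, collapse = " x "), " voxels; max dose ",
      format(x$max_dose), "; mean rel. err (>50% max) ",
      format(round(x$mean_relerr_high, 4)), "\n", sep = "")
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn dose_grid image of the central z slice.
#' @param x,... plot arguments.
#' @param slice z-slice index (default: central).
#' @export
plot.dose_grid <- function(x, slice = NULL, ...) {
  d <- dim(x$dose)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  graphics::image(.voxel_centers(x$xb), .voxel_centers(x$yb),
                  x$dose[, , slice], xlab = "x (cm)", ylab = "y (cm)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  invisible(x)
}

# index of the voxel containing each coordinate (NA outside), half-open
.voxel_index <- function(v, b) {
  i <- findInterval(v, b)
  i[i < 1L | i > length(b) - 1L] <- NA_integer_
  i
}

#' Score collision kerma on a plane
#'
#' Deposits each photon's collision-kerma contribution into the voxel it
#' crosses on a plane at the stated water-equivalent depth:
#' `weight * E * (muen/rho)(E) * exp(-(mu/rho)_water(E) * depth * slant)`,
#' divided by the voxel area. The plane passes through the isocenter,
#' perpendicular to the beam axis; `depth` is the water-equivalent depth of
#' that plane (the scorer assumes charged-particle equilibrium and does not
#' model buildup). Per-voxel relative uncertainty comes from batch statistics.
#'
#' @param photons photon data.frame (isocenter frame, `uz < 0`).
#' @param xb,yb voxel boundaries on the plane (cm at isocenter).
#' @param depth_cm water-equivalent depth of the plane (cm).
#' @param table attenuation tables.
#' @param batch integer batch label per photon (for uncertainty); defaults
#'   to a single batch (zero uncertainty).
#' @param n_batch number of batches.
#' @param n_source number of source histories the photons represent (for
#'   per-particle normalization); defaults to `nrow(photons)`.
#' @return a [dose_grid()] (single z slice, Gy per source particle).
#' @export
score_plane_kerma <- function(photons, xb, yb, depth_cm = 5,
                              table = attenuation_table(),
                              batch = NULL, n_batch = 10L,
                              n_source = nrow(photons)) {
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  if (is.null(batch)) { batch <- rep(1L, nrow(photons)); n_batch <- 1L }
  acc <- matrix(0, nx * ny, n_batch)
  st <- .score_plane_acc(acc, 0L, photons, xb, yb, depth_cm, table,
                         batch, n_batch)
  .finalize_grid(st$acc, nx, ny, 1L, xb, yb, c(-0.05, 0.05),
                 n_source, n_batch,
                 per_area = outer(diff(xb), diff(yb)),
                 meta = list(depth_cm = depth_cm, n_missed = st$n_missed,
                             n_source = n_source))
}

# accumulate plane-kerma batch sums into acc (nvox x n_batch); returns the
# updated accumulator and the running count of photons missing the grid
.score_plane_acc <- function(acc, n_missed, photons, xb, yb, depth_cm,
                             table, batch, n_batch) {
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  tpl <- (0 - photons$z) / photons$uz
  xp <- photons$x + photons$ux * tpl
  yp <- photons$y + photons$uy * tpl
  slant <- 1 / abs(photons$uz)
  lk <- mu_lookup(table, "water", photons$energy)
  contrib <- photons$weight * photons$energy * lk$muen_over_rho *
    exp(-lk$mu_over_rho * depth_cm * slant) * .MEV_PER_G_TO_GY
  ix <- .voxel_index(xp, xb); iy <- .voxel_index(yp, yb)
  ok <- !is.na(ix) & !is.na(iy)
  n_missed <- n_missed + sum(!ok)
  if (any(ok)) {
    vox <- (iy[ok] - 1L) * nx + ix[ok]
    key <- (batch[ok] - 1L) * (nx * ny) + vox
    sums <- rowsum(contrib[ok], key)
    keys <- as.integer(rownames(sums))
    pos <- cbind((keys - 1L) %% (nx * ny) + 1L,
                 (keys - 1L) %/% (nx * ny) + 1L)
    acc[pos] <- acc[pos] + sums[, 1]
  }
  list(acc = acc, n_missed = n_missed)
}

# batch sums -> dose_grid with per-voxel relative uncertainty
.finalize_grid <- function(acc, nx, ny, nz, xb, yb, zb, n_source, n_batch,
                           per_area = NULL, per_vol = NULL, meta = list()) {
  per_hist <- n_source / n_batch
  bm <- acc / per_hist
  dose <- rowMeans(bm)
  if (n_batch > 1L) {
    sd_m <- sqrt(pmax(rowMeans(bm^2) - dose^2, 0) / (n_batch - 1L))
    rel <- ifelse(dose > 0, sd_m / dose, 0)
  } else rel <- rep(0, length(dose))
  dose <- array(dose, c(nx, ny, nz))
  if (!is.null(per_area)) dose <- dose / as.vector(per_area)
  if (!is.null(per_vol)) dose <- dose / per_vol
  dose_grid(dose, xb, yb, zb, relerr = array(rel, c(nx, ny, nz)),
            meta = meta)
}
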