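#' Absolute dose calibration factors
#'
#' Linear conversion from Monte Carlo dose per source particle to absolute
#' dose: each voxel is multiplied by
#' `(D_cal_measured / D_cal_mc) * U`. The calibration field is the 10 x 10
#' cm^2 reference field at SAD 100 cm and 10 cm depth. The monitor
#' backscatter term is fixed at zero: the monitor chamber response to
#' collimator backscatter is not modeled, which reduces the conversion to a
#' single linear factor.
#'
#' @param d_cal_measured measured calibration dose per MU (Gy/MU).
#' @param d_cal_mc simulated raw dose for the same calibration field
#'   (Gy/particle).
#' @param d_chback monitor backscatter term; must be 0 (the validated
#'   simplification this calibration is built on).
#' @return object of class `dose_calibration`.
#' @export
dose_calibration <- function(d_cal_measured, d_cal_mc, d_chback = 0) {
  if (!isTRUE(d_cal_measured > 0) || !isTRUE(d_cal_mc > 0))
    stop("calibration doses must be positive")
  if (d_chback != 0)
    stop("the monitor backscatter term is fixed at zero in this model")
  structure(list(d_cal_measured = d_cal_measured, d_cal_mc = d_cal_mc,
                 d_chback = 0), class = "dose_calibration")
}

#' Convert a raw Monte Carlo dose grid to absolute dose
#'
#' @param dose_grid_raw a [dose_grid()] in Gy per source particle.
#' @param calibration a [dose_calibration()].
#' @param U monitor units delivered (MU).
#' @return a [dose_grid()] in Gy; relative uncertainties are unchanged.
#' @export
absolute_dose <- function(dose_grid_raw, calibration, U) {
  stopifnot(inherits(dose_grid_raw, "dose_grid"),
            inherits(calibration, "dose_calibration"))
  if (!isTRUE(U > 0)) stop("U must be positive")
  f <- calibration$d_cal_measured / calibration$d_cal_mc * U
  out <- dose_grid_raw
  out$dose <- out$dose * f
  out$meta$absolute <- TRUE
  out$meta$mu <- U
  out
}

#' Locally adaptive Savitzky--Golay denoising
#'
#' For each voxel, the largest candidate window (half-widths tried in
#' descending order) whose order-2 weighted least-squares polynomial fit
#' passes a chi-squared test against the stated per-voxel uncertainties is
#' used; the fitted central value replaces the voxel and its uncertainty is
#' recomputed from the fit covariance. Where no window passes -- at sharp
#' dose steps relative to the local noise -- the voxel is returned
#' unsmoothed, which is what makes the filter edge-preserving.
#'
#' @param grid a [dose_grid()] with populated relative uncertainties
#'   (positive wherever dose is positive).
#' @param half_widths candidate window half-widths per axis, in voxels,
#'   largest first.
#' @param chi_mult acceptance threshold multiplier: a window passes when its
#'   reduced chi-squared is at most `1 + chi_mult * sqrt(2/nu)`.
#' @return a denoised [dose_grid()]; `meta$sg_window` records the window
#'   half-width used per voxel (0 = unsmoothed).
#' @export
sg_denoise <- function(grid, half_widths = c(4, 3, 2, 1), chi_mult = 2) {
  stopifnot(inherits(grid, "dose_grid"))
  if (any(grid$relerr[grid$dose > 0] <= 0))
    stop("uncertainty array must be positive wherever dose is positive")
  d <- dim(grid$dose)
  sigma <- grid$dose * grid$relerr
  res <- sg_filter_cpp(as.numeric(grid$dose), as.numeric(sigma),
                       as.integer(d),
                       as.integer(sort(half_widths, decreasing = TRUE)),
                       chi_mult)
  out <- grid
  out$dose <- array(pmax(res$value, 0), d)
  out$relerr <- array(ifelse(res$value > 0, res$sd / res$value, 0), d)
  out$meta$sg_window <- array(res$window, d)
  out
}

#' Gamma comparison criteria
#'
#' @param dose_percent dose-difference criterion as percent of the reference
#'   maximum (global normalization).
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param roi_threshold_percent only reference voxels above this percentage
#'   of the reference maximum enter the region of interest.
#' @return object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent = 3, dta_mm = 3,
                           roi_threshold_percent = 20) {
  stopifnot(dose_percent > 0, dta_mm > 0, roi_threshold_percent > 0)
  structure(list(dose_percent = dose_percent, dta_mm = dta_mm,
                 roi_threshold_percent = roi_threshold_percent),
            class = "gamma_criteria")
}

#' 3D gamma-index comparison of two dose grids
#'
#' Per region-of-interest voxel, the gamma index is the minimum over a
#' search neighborhood of `sqrt((dd/dcrit)^2 + (dr/DTA)^2)`, with global
#' dose normalization to the reference maximum. The evaluated distribution
#' is trilinearly interpolated on a cubic subgrid inside a neighborhood
#' capped at `cap` times the DTA. Note the comparison is not symmetric: the
#' normalization and the ROI are derived from the reference grid, so
#' exchanging the grids changes the result.
#'
#' @param reference,evaluated [dose_grid()]s on identical geometry.
#' @param criteria a [gamma_criteria()].
#' @param subsample_mm search subgrid step (mm).
#' @param cap neighborhood radius in units of the DTA.
#' @return object of class `gamma_result`: per-voxel gamma array (NA outside
#'   the ROI), ROI mask, pass fraction (gamma < 1) and the criteria used.
#' @export
gamma_3d <- function(reference, evaluated, criteria = gamma_criteria(),
                     subsample_mm = 0.3, cap = 3) {
  stopifnot(inherits(reference, "dose_grid"),
            inherits(evaluated, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  same <- isTRUE(all.equal(reference$xb, evaluated$xb)) &&
    isTRUE(all.equal(reference$yb, evaluated$yb)) &&
    isTRUE(all.equal(reference$zb, evaluated$zb))
  if (!same) stop("grids are not on a common coordinate frame")
  d <- dim(reference$dose)
  vox <- c(diff(reference$xb)[1], diff(reference$yb)[1],
           diff(reference$zb)[1])
  ref_max <- max(reference$dose)
  if (ref_max <= 0) stop("reference grid has no dose")
  dcrit <- criteria$dose_percent / 100 * ref_max
  dta <- criteria$dta_mm / 10
  roi_abs <- criteria$roi_threshold_percent / 100 * ref_max
  g <- gamma_index_cpp(as.numeric(reference$dose),
                       as.numeric(evaluated$dose),
                       as.integer(d), vox, dcrit, dta, roi_abs, cap,
                       subsample_mm / 10)
  g <- array(g, d)
  roi <- reference$dose > roi_abs
  structure(list(gamma = g, roi = roi,
                 pass_fraction = mean(g[roi] < 1),
                 criteria = criteria), class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cr <- x$criteria
  cat("<gamma_result> ", cr$dose_percent, "%/", cr$dta_mm, " mm, ROI > ",
      cr$roi_threshold_percent, "% of reference max\n", sep = "")
  cat("  ROI voxels: ", sum(x$roi), ", pass (gamma < 1): ",
      format(round(100 * x$pass_fraction, 2)), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.gamma_result <- function(object, ...) {
  g <- object$gamma[object$roi]
  c(pass_fraction = object$pass_fraction, mean_gamma = mean(g),
    max_gamma = max(g))
}

#' Mean MLC transmission from a blocked/open grid pair
#'
#' Voxelwise blocked/open dose ratio averaged over a span perpendicular to
#' leaf motion (across the leaves) centered on the beam axis.
#'
#' @param blocked_grid,open_grid co-registered [dose_grid()]s.
#' @param span_cm extent of the averaging region along the leaf-stacking
#'   axis y (cm).
#' @param band_cm extent along the leaf-motion axis x (cm).
#' @return mean transmission fraction.
#' @export
mean_transmission <- function(blocked_grid, open_grid, span_cm = 12,
                              band_cm = 4) {
  stopifnot(inherits(blocked_grid, "dose_grid"),
            inherits(open_grid, "dose_grid"))
  if (!isTRUE(all.equal(blocked_grid$xb, open_grid$xb)) ||
      !isTRUE(all.equal(blocked_grid$yb, open_grid$yb)))
    stop("grids are not co-registered")
  xc <- .voxel_centers(blocked_grid$xb)
  yc <- .voxel_centers(blocked_grid$yb)
  sel_x <- abs(xc) <= band_cm / 2
  sel_y <- abs(yc) <= span_cm / 2
  ob <- open_grid$dose[sel_x, sel_y, , drop = FALSE]
  bb <- blocked_grid$dose[sel_x, sel_y, , drop = FALSE]
  if (any(ob <= 0) || mean(ob) <= 0)
    stop("open-field dose is ~0 inside the measurement span")
  mean(bb / ob)
}

#' Calibrate the tungsten density against a target transmission
#'
#' Reproduces the standard commissioning step: the physical density of the
#' leaf material is adjusted until the simulated mean transmission matches a
#' measured value. Transmission is monotone decreasing in density, so a
#' bracketing root find converges; every simulation in the search reuses the
#' same seed so the objective is deterministic.
#'
#' @param geometry an [mlc_geometry()]; its density is the starting point.
#' @param source a [source_model()].
#' @param target_transmission measured transmission fraction in `(0, 0.1)`.
#' @param tolerance relative tolerance on the returned density.
#' @param n_histories histories per simulated transmission evaluation.
#' @param seed seed shared by all evaluations.
#' @param bracket density search interval (g/cm^3).
#' @param ... passed to [simulate_delivery()].
#' @return calibrated density (g/cm^3).
#' @export
calibrate_density <- function(geometry, source, target_transmission,
                              tolerance = 0.005, n_histories = 1e5,
                              seed = 1L, bracket = c(8, 30), ...) {
  if (!isTRUE(target_transmission > 0 && target_transmission < 0.1))
    stop("target transmission must be in (0, 0.1)")
  fields <- make_transmission_fields(geometry)
  grid <- plane_grid(xlim = c(-8, 8), ylim = c(-9, 9), voxel = 0.2,
                     depth_cm = 5)
  open <- simulate_delivery(fields$open, geometry, source, grid,
                            n_histories = n_histories, seed = seed, ...)
  sim_t <- function(rho) {
    g2 <- geometry
    g2$density <- rho
    blocked <- simulate_delivery(fields$blocked, g2, source, grid,
                                 n_histories = n_histories, seed = seed, ...)
    mean_transmission(blocked, open)
  }
  f <- function(rho) sim_t(rho) - target_transmission
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (flo * fhi > 0)
    stop("target transmission not reachable within the density bracket")
  r <- stats::uniroot(f, bracket, f.lower = flo, f.upper = fhi,
                      tol = tolerance * geometry$density)
  r$root
}

#' Output factor between two simulated fields
#'
#' Ratio of central-axis dose (mean over a small central region) of a field
#' to the reference field at the same depth. With only MLC/jaw-shaped
#' primary and first-scatter fluence modeled (no collimator head scatter and
#' no phantom scatter), simulated output factors stay close to unity; the
#' field-size trends a water tank measures are largely driven by physics
#' outside this model.
#'
#' Simulated grids are in dose per source particle; when both grids carry
#' the jaw field area recorded by [simulate_delivery()], they are first put
#' on a common per-unit-incident-fluence scale (a field of twice the area
#' receives twice the photons at fixed fluence density).
#'
#' @param dose_field,dose_reference_field co-registered [dose_grid()]s.
#' @param roi_halfwidth_cm half-width of the central averaging region (cm).
#' @return output factor (ratio).
#' @export
output_factor <- function(dose_field, dose_reference_field,
                          roi_halfwidth_cm = 0.5) {
  stopifnot(inherits(dose_field, "dose_grid"),
            inherits(dose_reference_field, "dose_grid"))
  cax <- function(g) {
    xc <- .voxel_centers(g$xb); yc <- .voxel_centers(g$yb)
    d <- mean(g$dose[abs(xc) <= roi_halfwidth_cm,
                     abs(yc) <= roi_halfwidth_cm, ])
    a <- g$meta$field_area_iso
    if (!is.null(a)) d * a else d
  }
  af <- dose_field$meta$field_area_iso
  ar <- dose_reference_field$meta$field_area_iso
  if (is.null(af) != is.null(ar))
    warning("only one grid records its field area; comparing per-particle")
  ref <- cax(dose_reference_field)
  if (ref <= 0) stop("reference field has zero central dose")
  cax(dose_field) / ref
}
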