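#' Parametric photon source model
#'
#' A parametric replacement for a stored linac phase space: photons are
#' emitted from a point focal spot, positioned on a phase plane at
#' `phase_plane_z` cm from the source, with energies drawn from a binned
#' spectrum and statistical weights proportional to a radial fluence profile.
#'
#' @param spectrum data.frame with columns `energy_lo`, `energy_hi`,
#'   `fluence` (relative, per bin).
#' @param lateral_profile function of the off-axis radius projected to the
#'   isocenter plane (cm) returning relative fluence (> 0).
#' @param phase_plane_z distance of the phase plane from the source (cm).
#' @param name label for printing.
#' @return an object of class `source_model`.
#' @seealso [beam_preset()], [sample_source_photon()]
#' @export
source_model <- function(spectrum, lateral_profile, phase_plane_z = 55,
                         name = "custom") {
  spectrum <- as.data.frame(spectrum)
  stopifnot(all(c("energy_lo", "energy_hi", "fluence") %in% names(spectrum)))
  if (nrow(spectrum) < 1) stop("empty spectrum")
  if (any(spectrum$fluence < 0) || sum(spectrum$fluence) <= 0)
    stop("spectrum fluence must be non-negative and normalizable")
  if (any(spectrum$energy_hi <= spectrum$energy_lo))
    stop("spectrum bins must have energy_hi > energy_lo")
  stopifnot(is.function(lateral_profile), phase_plane_z > 0)
  structure(list(spectrum = spectrum, lateral_profile = lateral_profile,
                 phase_plane_z = phase_plane_z, name = name),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  sp <- x$spectrum
  p <- sp$fluence / sum(sp$fluence)
  em <- sum(p * (sp$energy_lo + sp$energy_hi) / 2)
  cat("<source_model> ", x$name, ": ", nrow(sp), " bins, ",
      format(min(sp$energy_lo)), "-", format(max(sp$energy_hi)),
      " MeV, mean ", format(round(em, 3)), " MeV, phase plane at ",
      x$phase_plane_z, " cm\n", sep = "")
  invisible(x)
}

#' Packaged beam presets
#'
#' `"6X"` is a flattened 6 MV beam: an energy spectrum with mean ~1.8 MeV and
#' a flat lateral profile with mild off-axis horns. `"6X-FFF"` is the
#' flattening-filter-free variant: a softer spectrum and a forward-peaked
#' (Gaussian) lateral profile. Both are parametric approximations packaged as
#' editable tables; the vendor spectra are not public.
#'
#' @param beam `"6X"` or `"6X-FFF"` (case-insensitive; `"6X FFF"` accepted).
#' @return a [source_model()].
#' @export
beam_preset <- function(beam = c("6X", "6X-FFF")) {
  key <- toupper(gsub("[ _]", "-", beam[1]))
  if (!key %in% c("6X", "6X-FFF")) stop("unknown beam preset: ", beam)
  file <- if (key == "6X") "6x_spectrum.csv" else "6x_fff_spectrum.csv"
  path <- system.file("extdata", "spectra", file, package = "mlcport")
  if (path == "") stop("packaged spectrum table not found: ", file)
  sp <- utils::read.csv(path, comment.char = "#")
  if (key == "6X") {
    prof <- function(r_iso) 1 + 0.03 * (r_iso / 10)^2
  } else {
    prof <- function(r_iso) exp(-r_iso^2 / (2 * 10^2))
  }
  source_model(sp, prof, phase_plane_z = 55, name = key)
}

#' Sample photon energies from a binned spectrum
#'
#' Inverse-CDF sampling over bins with uniform sampling within a bin.
#'
#' @param spectrum spectrum data.frame (see [source_model()]) or a
#'   `source_model`.
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of energies (MeV).
#' @export
sample_energy <- function(spectrum, n, seed = NULL) {
  if (inherits(spectrum, "source_model")) spectrum <- spectrum$spectrum
  if (nrow(spectrum) < 1 || sum(spectrum$fluence) <= 0)
    stop("empty spectrum")
  if (!is.null(seed)) set.seed(seed)
  p <- spectrum$fluence / sum(spectrum$fluence)
  i <- sample.int(nrow(spectrum), n, replace = TRUE, prob = p)
  stats::runif(n, spectrum$energy_lo[i], spectrum$energy_hi[i])
}

#' Sample source photons on the phase plane
#'
#' Positions are uniform over the jaw-defined rectangle projected from the
#' isocenter onto the phase plane; directions point from the focal spot
#' through the sampled position; weights are proportional to the lateral
#' fluence profile (normalized to a maximum of 1 over the rectangle).
#'
#' @param source a [source_model()].
#' @param field_rect list or vector with `x1`, `x2`, `y1`, `y2`: the field
#'   rectangle at the isocenter plane (cm).
#' @param n number of photons.
#' @param seed optional integer seed.
#' @param sad source-axis distance (cm).
#' @return data.frame of photons: `energy` (MeV), position `x`, `y`, `z`
#'   (isocenter frame, cm), unit direction `ux`, `uy`, `uz` (uz < 0), and
#'   `weight`.
#' @export
sample_source_photon <- function(source, field_rect, n, seed = NULL,
                                 sad = 100) {
  stopifnot(inherits(source, "source_model"))
  fr <- as.list(field_rect)
  if ((fr$x2 - fr$x1) <= 0 || (fr$y2 - fr$y1) <= 0)
    stop("degenerate (zero-area) field rectangle")
  if (!is.null(seed)) set.seed(seed)
  e <- sample_energy(source$spectrum, n)
  # iso-plane coordinates; the geometric position sits on the phase plane
  xi <- stats::runif(n, fr$x1, fr$x2)
  yi <- stats::runif(n, fr$y1, fr$y2)
  r_iso <- sqrt(xi^2 + yi^2)
  # profile normalization over the rectangle (coarse grid maximum)
  gx <- seq(fr$x1, fr$x2, length.out = 21)
  gy <- seq(fr$y1, fr$y2, length.out = 21)
  rg <- sqrt(outer(gx^2, gy^2, `+`))
  pmaxv <- max(source$lateral_profile(rg))
  w <- source$lateral_profile(r_iso) / pmaxv
  if (any(w <= 0)) stop("lateral profile must be positive inside the field")
  fz <- source$phase_plane_z / sad
  xp <- xi * fz
  yp <- yi * fz
  zp <- sad - source$phase_plane_z
  # direction from the source point (0, 0, sad)
  dx <- xp; dy <- yp; dz <- zp - sad
  nn <- sqrt(dx^2 + dy^2 + dz^2)
  data.frame(energy = e, x = xp, y = yp, z = zp,
             ux = dx / nn, uy = dy / nn, uz = dz / nn,
             weight = w, generation = "primary",
             stringsAsFactors = FALSE)
}

#' Machine state at one point of a delivery
#'
#' @param cumulative_meterset delivered meterset fraction in `[0, 1]`.
#' @param gantry_angle_deg gantry angle (degrees).
#' @param aperture an [aperture_state()].
#' @return an object of class `control_point`.
#' @export
control_point <- function(cumulative_meterset, gantry_angle_deg, aperture) {
  stopifnot(cumulative_meterset >= 0, cumulative_meterset <= 1,
            inherits(aperture, "aperture_state"))
  structure(list(cumulative_meterset = cumulative_meterset,
                 gantry_angle_deg = gantry_angle_deg,
                 aperture = aperture), class = "control_point")
}

#' A delivery plan: ordered control points plus monitor units
#'
#' @param control_points list of [control_point()]s; cumulative meterset must
#'   be non-decreasing with first value 0 and last value 1.
#' @param total_mu monitor units delivered by the plan.
#' @param beam beam preset name (`"6X"` or `"6X-FFF"`).
#' @param name plan label.
#' @return an object of class `mlc_plan`.
#' @export
mlc_plan <- function(control_points, total_mu, beam = "6X", name = "plan") {
  if (length(control_points) < 2)
    stop("a plan needs at least two control points")
  if (!isTRUE(total_mu > 0)) stop("total_mu must be positive")
  ok <- vapply(control_points, inherits, TRUE, "control_point")
  if (!all(ok)) stop("control_points must be control_point objects")
  ms <- vapply(control_points, `[[`, numeric(1), "cumulative_meterset")
  if (any(diff(ms) < 0)) stop("cumulative meterset must be non-decreasing")
  if (ms[1] != 0 || ms[length(ms)] != 1)
    stop("cumulative meterset must start at 0 and end at 1")
  nl <- vapply(control_points,
               function(cp) length(cp$aperture$bank_a), integer(1))
  if (length(unique(nl)) != 1)
    stop("all control points must have the same leaf count")
  structure(list(control_points = control_points, total_mu = total_mu,
                 beam = beam, name = name), class = "mlc_plan")
}

#' @export
print.mlc_plan <- function(x, ...) {
  ga <- vapply(x$control_points, `[[`, numeric(1), "gantry_angle_deg")
  cat("<mlc_plan> ", x$name, ": ", length(x$control_points),
      " control points, ", x$total_mu, " MU, beam ", x$beam, "\n", sep = "")
  cat("  gantry ", format(ga[1]), " -> ", format(ga[length(ga)]),
      " deg, ", length(x$control_points[[1]]$aperture$bank_a),
      " leaf pairs\n", sep = "")
  invisible(x)
}

# unwrapped gantry angles across the plan (no 360 deg jumps)
.unwrap_gantry <- function(angles) {
  d <- diff(angles)
  d <- (d + 180) %% 360 - 180
  cumsum(c(angles[1], d))
}

#' Interpolate the machine state at a meterset fraction
#'
#' Exact at control points; linear interpolation of the gantry angle
#' (unwrapped across 360 degrees), every leaf position and every jaw
#' coordinate between the bracketing control points. At a repeated meterset
#' value the later control point takes precedence.
#'
#' @param plan an [mlc_plan()].
#' @param u meterset fraction(s) in `[0, 1]`, vectorised.
#' @return list with `gantry` (numeric vector), `bank_a`, `bank_b` (matrices,
#'   leaves x length(u)) and `jaws` (4 x length(u) matrix: x1, x2, y1, y2).
#' @export
sample_control_point_state <- function(plan, u) {
  stopifnot(inherits(plan, "mlc_plan"))
  if (any(u < 0 | u > 1)) stop("meterset fraction outside [0, 1]")
  cps <- plan$control_points
  ms <- vapply(cps, `[[`, numeric(1), "cumulative_meterset")
  ga <- .unwrap_gantry(vapply(cps, `[[`, numeric(1), "gantry_angle_deg"))
  ba <- vapply(cps, function(cp) cp$aperture$bank_a,
               numeric(length(cps[[1]]$aperture$bank_a)))
  bb <- vapply(cps, function(cp) cp$aperture$bank_b,
               numeric(length(cps[[1]]$aperture$bank_a)))
  ba <- matrix(ba, ncol = length(cps))
  bb <- matrix(bb, ncol = length(cps))
  jw <- vapply(cps, function(cp) unlist(cp$aperture[
    c("jaw_x1", "jaw_x2", "jaw_y1", "jaw_y2")]), numeric(4))
  i <- findInterval(u, ms, rightmost.closed = TRUE)
  i <- pmax(pmin(i, length(ms) - 1L), 1L)
  den <- ms[i + 1L] - ms[i]
  f <- ifelse(den > 0, (u - ms[i]) / den, 1)
  f <- pmin(pmax(f, 0), 1)
  interp <- function(m) m[, i, drop = FALSE] +
    sweep(m[, i + 1L, drop = FALSE] - m[, i, drop = FALSE], 2, f, `*`)
  list(gantry = ga[i] + f * (ga[i + 1L] - ga[i]),
       bank_a = interp(ba), bank_b = interp(bb), jaws = interp(jw))
}
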