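#' MLC geometry container
#'
#' Builds the complete physical description of a two-bank multileaf collimator:
#' per-leaf projected widths, the two thickness-versus-position half tables
#' (tongue-and-groove and interleaf structure), the rounded leaf-tip
#' parameters, tungsten density and the position of the leaf assembly along the
#' beam axis.
#'
#' Coordinates are right-handed with the origin at the isocenter, the beam
#' along -z at gantry 0, leaf motion along x and the leaf stack along y. All
#' lengths are cm. Leaf positions are stored at the isocenter plane and
#' projected to the leaf assembly by similar triangles. The half tables are
#' indexed by the cross-leaf coordinate at the mid-plane of the leaf assembly
#' (`z_upper + physical_thickness/2` from the source); leaf side faces are
#' treated as focused, i.e. a point at distance `s` from the source is looked
#' up at `y * z_mid / s`.
#'
#' @param model_name `"HD120"` or `"Millennium120"` (free-form names allowed).
#' @param leaf_widths_iso ordered per-leaf projected widths at 100 cm (cm),
#'   from -y to +y.
#' @param upper_table,lower_table data.frames with columns `leaf`, `y`,
#'   `thickness`: piecewise-constant thickness (cm of tungsten) of the upper /
#'   lower half of the leaf assembly versus cross-leaf position at the MLC
#'   mid-plane. Each row's thickness applies from its `y` up to the next row's
#'   `y`; the final row is a terminator whose thickness must be 0.
#' @param physical_thickness total leaf height (cm).
#' @param tip_radius leaf-end radius of curvature (cm).
#' @param tip_angle tip facet angle in degrees (0 disables the facet; the
#'   HD120 leaf end is a pure arc).
#' @param tip_max_thickness maximum thickness of the curved leaf tip (cm); the
#'   arc is truncated by flat top/bottom surfaces beyond this thickness.
#' @param density leaf physical density (g/cm^3).
#' @param leaf_offset physical gap between closed opposing leaf tips (cm,
#'   calibration dependent).
#' @param z_upper distance of the upper MLC surface from the source (cm).
#' @param sad source-to-axis distance (cm).
#' @return an object of class `mlc_geometry`.
#' @seealso [mlc_preset()], [load_mlc_config()], [radiological_path()]
#' @export
mlc_geometry <- function(model_name, leaf_widths_iso, upper_table, lower_table,
                         physical_thickness, tip_radius, tip_angle = 0,
                         tip_max_thickness = physical_thickness,
                         density = 18.9, leaf_offset = 0.01,
                         z_upper = 50.9, sad = 100) {
  stopifnot(density > 0, tip_radius > 0, physical_thickness > 0,
            tip_max_thickness > 0, z_upper > 0, sad > z_upper,
            all(leaf_widths_iso > 0))
  up <- .check_half_table(upper_table, "upper")
  lo <- .check_half_table(lower_table, "lower")
  n_up <- length(unique(up$leaf))
  n_lo <- length(unique(lo$leaf))
  if (n_up != n_lo)
    stop("inconsistent leaf counts between halves: upper ", n_up,
         ", lower ", n_lo)
  if (n_up != length(leaf_widths_iso))
    stop("table leaf count (", n_up, ") does not match leaf_widths_iso (",
         length(leaf_widths_iso), ")")
  th <- physical_thickness
  if (any(up$thickness > th / 2 + 1e-9) || any(lo$thickness > th / 2 + 1e-9))
    stop("half-table thickness exceeds physical_thickness/2")
  g <- structure(list(
    model_name = model_name,
    leaf_widths_iso = as.numeric(leaf_widths_iso),
    upper_table = up, lower_table = lo,
    physical_thickness = th,
    tip_radius = tip_radius,
    tip_angle = tip_angle,
    tip_max_thickness = min(tip_max_thickness, th),
    density = density,
    leaf_offset = leaf_offset,
    z_upper = z_upper,
    sad = sad
  ), class = "mlc_geometry")
  g
}

.check_half_table <- function(tab, name) {
  tab <- as.data.frame(tab)
  need <- c("leaf", "y", "thickness")
  if (!all(need %in% names(tab)))
    stop(name, " table must have columns leaf, y, thickness")
  tab <- tab[order(tab$y), need]
  if (any(diff(tab$y) < 0)) stop(name, " table breakpoints not sorted")
  if (any(tab$thickness < 0)) stop(name, " table has negative thickness")
  nr <- nrow(tab)
  if (nr < 2) stop(name, " table needs at least two rows")
  if (tab$thickness[nr] != 0)
    stop(name, " table must end with a terminator row of thickness 0")
  tab
}

#' @export
print.mlc_geometry <- function(x, ...) {
  w <- x$leaf_widths_iso
  cat("<mlc_geometry> ", x$model_name, "\n", sep = "")
  cat("  leaves/bank:        ", length(w), " (projected field length ",
      format(sum(w)), " cm)\n", sep = "")
  cat("  leaf height:        ", x$physical_thickness, " cm at z_upper ",
      x$z_upper, " cm\n", sep = "")
  cat("  tip: radius ", x$tip_radius, " cm, angle ", x$tip_angle,
      " deg, max thickness ", x$tip_max_thickness, " cm\n", sep = "")
  cat("  density:            ", x$density, " g/cm^3, closed-tip offset ",
      x$leaf_offset, " cm\n", sep = "")
  invisible(x)
}

# cumulative iso-plane leaf boundaries, length n+1, centered on the axis
.leaf_boundaries_iso <- function(geometry) {
  w <- geometry$leaf_widths_iso
  b <- cumsum(c(0, w))
  b - sum(w) / 2
}

.z_mid <- function(geometry) geometry$z_upper + geometry$physical_thickness / 2

#' Total projected MLC-defined field length
#'
#' Sum of all per-leaf projected widths at the isocenter plane, i.e. the
#' maximum field length perpendicular to leaf motion.
#'
#' @param geometry an [mlc_geometry()].
#' @return length in cm at 100 cm from the source.
#' @examples
#' \donttest{projected_field_length(mlc_preset("hd120"))  # 22.0}
#' @export
projected_field_length <- function(geometry) {
  stopifnot(inherits(geometry, "mlc_geometry"))
  sum(geometry$leaf_widths_iso)
}

#' Locate the leaf under a cross-leaf position
#'
#' Leaf intervals are half-open: a boundary coordinate belongs to the
#' higher-index leaf. The topmost stack edge maps to the last leaf.
#'
#' @param geometry an [mlc_geometry()].
#' @param y_iso cross-leaf coordinate(s) at the isocenter plane (cm).
#' @return list with integer `leaf_index` (1-based, from -y) and
#'   `offset_within_leaf` (cm from the leaf's lower-y edge).
#' @export
leaf_index_at <- function(geometry, y_iso) {
  b <- .leaf_boundaries_iso(geometry)
  n <- length(b) - 1L
  if (any(y_iso < b[1] | y_iso > b[n + 1L]))
    stop("y_iso outside the leaf stack [", b[1], ", ", b[n + 1L], "] cm")
  idx <- findInterval(y_iso, b)
  idx <- pmin(idx, n)  # top edge belongs to the last leaf
  list(leaf_index = as.integer(idx), offset_within_leaf = y_iso - b[idx])
}

# piecewise-constant lookup in a half table; y at the MLC mid-plane
.half_thickness <- function(tab, y_mlc) {
  i <- findInterval(y_mlc, tab$y)
  out <- numeric(length(y_mlc))
  inside <- i >= 1L & i < nrow(tab)
  out[inside] <- tab$thickness[i[inside]]
  out
}

#' Upper/lower half thickness at a cross-leaf position
#'
#' Looks up the two half tables at a position expressed at the MLC mid-plane.
#' The sum of the two values is the total tungsten height for a ray parallel to
#' the beam axis at that position (away from the leaf tips), including
#' tongue-and-groove steps and interleaf gaps.
#'
#' @param geometry an [mlc_geometry()].
#' @param y_mlc cross-leaf coordinate(s) at the MLC mid-plane (cm).
#' @return list with numeric vectors `upper` and `lower` (cm tungsten).
#' @export
thickness_profile <- function(geometry, y_mlc) {
  rng <- range(c(geometry$upper_table$y, geometry$lower_table$y))
  if (any(y_mlc < rng[1] | y_mlc > rng[2]))
    stop("y_mlc outside the physical leaf stack [", rng[1], ", ", rng[2], "]")
  list(upper = .half_thickness(geometry$upper_table, y_mlc),
       lower = .half_thickness(geometry$lower_table, y_mlc))
}

# Leaf tip face position at height s (distance from source) for one bank.
# Bank B leaves occupy x >= face; bank A leaves occupy x <= face (mirrored).
# pos_iso is the leaf tip position projected at the isocenter plane.
.tip_face <- function(geometry, pos_iso, s, bank = c("B", "A")) {
  bank <- match.arg(bank)
  sgn <- if (bank == "B") 1 else -1
  p <- sgn * pos_iso  # work in the bank-B orientation
  R <- geometry$tip_radius
  zc <- .z_mid(geometry)
  m <- p / geometry$sad
  xc <- m * zc + R * sqrt(1 + m^2) + geometry$leaf_offset / 2
  u <- abs(s - zc)
  ucap <- min(geometry$tip_max_thickness / 2, geometry$physical_thickness / 2)
  u <- pmin(u, ucap)
  alpha <- geometry$tip_angle * pi / 180
  if (alpha > 0) {
    ut <- R * sin(alpha)
    arc <- ifelse(u <= ut,
                  sqrt(pmax(R^2 - u^2, 0)),
                  R * cos(alpha) - (u - ut) * tan(alpha))
  } else {
    arc <- sqrt(pmax(R^2 - pmin(u, R)^2, 0))
  }
  sgn * (xc - arc)
}

#' Tungsten chord through the rounded leaf tip
#'
#' Thickness of tungsten traversed by a beam-axis-parallel ray at lateral
#' position `x_ray_mlc` through a leaf whose tip sits at `leaf_position_mlc`
#' (both at the MLC mid-plane scale, bank-B orientation: the leaf body extends
#' toward +x). The leaf end is modeled as a circular arc of radius
#' `tip_radius` spanning the leaf height, truncated at `tip_max_thickness`,
#' with the optional planar facet cut tangent to the arc at `tip_angle`.
#'
#' @param geometry an [mlc_geometry()].
#' @param x_ray_mlc lateral ray position(s) (cm).
#' @param leaf_position_mlc leaf tip position (cm); the front-most point of
#'   the tip arc sits at this coordinate.
#' @param z_in_leaf optional depth (cm) from the top of the leaf; when given,
#'   only the part of the chord above that depth is counted.
#' @return chord length(s) in cm, between 0 and `physical_thickness`.
#' @export
tip_thickness <- function(geometry, x_ray_mlc, leaf_position_mlc,
                          z_in_leaf = NULL) {
  R <- geometry$tip_radius
  h <- geometry$physical_thickness
  ucap <- min(geometry$tip_max_thickness, h) / 2
  # front of the tip at x = leaf_position; circle center at pos + R
  xc <- leaf_position_mlc + R
  d <- xc - x_ray_mlc                      # distance from circle center
  ustar <- numeric(length(x_ray_mlc))
  inside <- d <= R
  alpha <- geometry$tip_angle * pi / 180
  u_arc <- sqrt(pmax(R^2 - pmax(d, 0)^2, 0))
  if (alpha > 0) {
    ut <- R * sin(alpha)
    # facet region: face(u) = xc - (R cos a - (u - ut) tan a)
    u_fac <- ut + (R * cos(alpha) - d) / tan(alpha)
    ustar <- ifelse(u_arc <= ut, u_arc, pmin(u_fac, h / 2))
  } else {
    ustar <- u_arc
  }
  ustar[!inside & d > R] <- 0
  ustar <- pmin(ustar, ucap)
  chord <- 2 * ustar
  chord <- pmin(chord, h)
  if (!is.null(z_in_leaf)) {
    # count only the chord above depth z_in_leaf from the top surface
    top <- h / 2 - pmin(ustar, h / 2)       # depth at which tungsten starts
    chord <- pmin(pmax(z_in_leaf - top, 0), chord)
  }
  chord
}

#' Aperture state of the two leaf banks and jaws
#'
#' @param bank_a,bank_b per-leaf tip positions projected to the isocenter
#'   plane (cm, signed along the leaf-motion axis x). Bank A leaves close from
#'   -x (a leaf occupies x below its position), bank B from +x.
#' @param jaw_x1,jaw_x2,jaw_y1,jaw_y2 jaw positions at the isocenter (cm).
#' @param leaf_offset closed-pair tolerance used by the validity check (cm).
#' @return an object of class `aperture_state`.
#' @export
aperture_state <- function(bank_a, bank_b, jaw_x1 = -20, jaw_x2 = 20,
                           jaw_y1 = -20, jaw_y2 = 20, leaf_offset = 0.01) {
  if (length(bank_a) != length(bank_b))
    stop("bank A and bank B must have the same number of leaves")
  if (any(bank_a > bank_b + leaf_offset + 1e-9))
    stop("bank A leaf extends past its bank B partner (closed-pair violation)")
  if (jaw_x1 > jaw_x2 || jaw_y1 > jaw_y2) stop("inverted jaw settings")
  structure(list(bank_a = as.numeric(bank_a), bank_b = as.numeric(bank_b),
                 jaw_x1 = jaw_x1, jaw_x2 = jaw_x2,
                 jaw_y1 = jaw_y1, jaw_y2 = jaw_y2),
            class = "aperture_state")
}

#' @export
print.aperture_state <- function(x, ...) {
  cat("<aperture_state> ", length(x$bank_a), " leaf pairs, jaws x [",
      x$jaw_x1, ", ", x$jaw_x2, "] y [", x$jaw_y1, ", ", x$jaw_y2, "] cm\n",
      sep = "")
  op <- x$bank_b - x$bank_a
  cat("  open pairs: ", sum(op > 1e-6), ", max gap ",
      format(max(op)), " cm\n", sep = "")
  invisible(x)
}

#' A geometric ray
#'
#' @param origin 3-vector (cm), isocenter coordinates (beam travels toward
#'   -z at gantry 0; the source sits at `(0, 0, sad)`).
#' @param direction 3-vector; must be unit length within 1e-12 unless
#'   `normalize = TRUE`.
#' @param normalize normalize `direction` instead of requiring unit length.
#' @return an object of class `mlc_ray`.
#' @export
ray <- function(origin, direction, normalize = FALSE) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  n2 <- sum(direction^2)
  if (normalize) direction <- direction / sqrt(n2)
  else if (abs(n2 - 1) > 1e-12)
    stop("direction is not unit length (|d|^2 - 1 = ", n2 - 1, ")")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction)), class = "mlc_ray")
}

# Build the flat numeric representation handed to the C++ tracer.
.tracer_geom <- function(geometry) {
  up <- geometry$upper_table
  lo <- geometry$lower_table
  list(
    up_breaks = up$y, up_thick = up$thickness, up_leaf = as.integer(up$leaf),
    lo_breaks = lo$y, lo_thick = lo$thickness, lo_leaf = as.integer(lo$leaf),
    z_u = geometry$z_upper, h = geometry$physical_thickness,
    z_mid = .z_mid(geometry), density = geometry$density,
    tip_radius = geometry$tip_radius, tip_angle = geometry$tip_angle,
    tip_max = geometry$tip_max_thickness, leaf_offset = geometry$leaf_offset,
    sad = geometry$sad, n_leaf = length(geometry$leaf_widths_iso)
  )
}

# rays: list of mlc_ray or a list(ox, oy, os, dx, dy, ds) in source-depth
# coordinates (s = sad - z, increasing toward the patient).
.rays_to_s <- function(geometry, rays) {
  if (inherits(rays, "mlc_ray")) rays <- list(rays)
  if (is.list(rays) && all(vapply(rays, inherits, TRUE, "mlc_ray"))) {
    o <- t(vapply(rays, `[[`, numeric(3), "origin"))
    d <- t(vapply(rays, `[[`, numeric(3), "direction"))
    if (any(abs(d[, 3]) < 1e-9))
      stop("ray parallel to the MLC plane")
    # flip so all rays advance toward the patient in s
    flip <- d[, 3] > 0
    d[flip, ] <- -d[flip, ]
    list(ox = o[, 1], oy = o[, 2], os = geometry$sad - o[, 3],
         dx = -d[, 1] / d[, 3], dy = -d[, 2] / d[, 3],
         slant = 1 / abs(d[, 3]))
  } else rays
}

#' Radiological path length through the MLC
#'
#' Areal tungsten density (g/cm^2) traversed by rays through a given aperture
#' state, accounting for intraleaf thickness variation, tongue-and-groove
#' steps, interleaf gaps and the rounded leaf tips. Rays wholly inside the
#' open aperture return 0.
#'
#' @param geometry an [mlc_geometry()].
#' @param aperture an [aperture_state()].
#' @param rays a single [ray()] or a list of rays. Rays must cross the leaf
#'   assembly (origin on the source side).
#' @param n_steps number of integration steps across the leaf height.
#' @return numeric vector of areal densities (g/cm^2), one per ray.
#' @export
radiological_path <- function(geometry, aperture, rays, n_steps = 128L) {
  stopifnot(inherits(geometry, "mlc_geometry"),
            inherits(aperture, "aperture_state"))
  rs <- .rays_to_s(geometry, rays)
  gg <- .tracer_geom(geometry)
  ba <- matrix(aperture$bank_a, ncol = 1)
  bb <- matrix(aperture$bank_b, ncol = 1)
  res <- trace_mlc_cpp(rs$ox, rs$oy, rs$os, rs$dx, rs$dy,
                       ba, bb, TRUE, gg, as.integer(n_steps),
                       numeric(0), numeric(0))
  res$path
}
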