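#' Open/blocked field pair for transmission measurement
#'
#' The blocked plan has one leaf bank (bank A) fully extended across the
#' field so every field point is behind a leaf body; the open plan has
#' identical jaws with both banks retracted clear of the field. Defaults
#' reproduce the standard transmission setup: a 15 x 17 cm^2 jaw-defined
#' field delivered with 4000 MU to the blocked field.
#'
#' @param geometry an [mlc_geometry()].
#' @param field_x,field_y field sizes along / across leaf motion (cm).
#' @param mu monitor units for the blocked delivery.
#' @return list with `open` and `blocked` [mlc_plan()]s.
#' @export
make_transmission_fields <- function(geometry, field_x = 15, field_y = 17,
                                     mu = 4000) {
  n <- length(geometry$leaf_widths_iso)
  hx <- field_x / 2; hy <- field_y / 2
  over <- 1 + geometry$tip_radius * 0.05  # clear the tip arc recession
  blocked_ap <- aperture_state(rep(hx + over, n), rep(hx + over + 0.2, n),
                               jaw_x1 = -hx, jaw_x2 = hx,
                               jaw_y1 = -hy, jaw_y2 = hy,
                               leaf_offset = geometry$leaf_offset)
  open_ap <- aperture_state(rep(-hx - over, n), rep(hx + over, n),
                            jaw_x1 = -hx, jaw_x2 = hx,
                            jaw_y1 = -hy, jaw_y2 = hy,
                            leaf_offset = geometry$leaf_offset)
  static_plan <- function(ap, nm, m) {
    mlc_plan(list(control_point(0, 0, ap), control_point(1, 0, ap)),
             total_mu = m, name = nm)
  }
  list(open = static_plan(open_ap, "transmission-open", mu),
       blocked = static_plan(blocked_ap, "transmission-blocked", mu))
}

#' Static odd-leaf bar pattern
#'
#' Odd-numbered bank-A leaves project into the field to create a bar pattern
#' whose fluence alternates with the leaf-width periodicity.
#'
#' @param geometry an [mlc_geometry()].
#' @param extension_cm how far the odd leaves project past the axis (cm).
#' @param field_halfwidth_cm retracted-leaf and jaw half-width (cm).
#' @param bank which bank projects (`"A"` or `"B"`); the `"B"` pattern is
#'   the mirror image.
#' @return an [aperture_state()].
#' @export
make_odd_leaf_bar <- function(geometry, extension_cm = 3,
                              field_halfwidth_cm = 5, bank = c("A", "B")) {
  bank <- match.arg(bank)
  n <- length(geometry$leaf_widths_iso)
  odd <- seq_len(n) %% 2 == 1
  hw <- field_halfwidth_cm
  if (bank == "A") {
    ba <- ifelse(odd, extension_cm, -hw)
    bb <- rep(hw, n)
  } else {
    ba <- rep(-hw, n)
    bb <- ifelse(odd, -extension_cm, hw)
  }
  aperture_state(ba, bb, jaw_x1 = -hw, jaw_x2 = hw, jaw_y1 = -hw,
                 jaw_y2 = hw, leaf_offset = geometry$leaf_offset)
}

# Sliding-window synthesis: build leaf trajectories that deliver a target
# relative fluence profile F(x) with a unidirectional left-to-right sweep.
# The trailing (bank A) edge passes x at meterset u_A(x), the leading
# (bank B) edge at u_B(x) = u_A(x) - F(x)/S; exposure time is proportional
# to F. Returns per-control-point positions for one leaf pair.
.sliding_window <- function(fluence, xlim, n_cp, events = TRUE) {
  xg <- seq(xlim[1], xlim[2], length.out = 1024)
  fx <- fluence(xg)
  if (any(fx < 0)) stop("fluence must be non-negative")
  dF <- diff(fx)
  # leading edge must move monotonically: u_B' = max(0, -F') (+ floor)
  ub <- cumsum(c(0, pmax(0, -dF)))
  ua <- ub + fx
  S <- ua[length(ua)]
  eps <- 1e-9 * seq_along(xg)           # strict monotonicity for inversion
  ub <- ub / S + eps; ua <- ua / S + eps
  # control points at a uniform grid plus the meterset values where the
  # fluence profile jumps (there the trajectories change slope, so placing
  # nodes at the events keeps linear interpolation between control points
  # faithful)
  u <- seq(0, 1, length.out = n_cp)
  if (events) {
    jumps <- which(abs(dF) > 0.25 * max(abs(dF), 1e-12))
    u_ev <- c(ub[jumps], ub[jumps + 1], ua[jumps], ua[jumps + 1])
    u <- sort(unique(c(u, pmin(pmax(u_ev, 0), 1))))
  }
  pos_b <- stats::approx(ub, xg, u, rule = 2)$y
  pos_a <- stats::approx(ua, xg, u, rule = 2)$y
  u[1] <- 0; u[length(u)] <- 1
  list(u = u, a = pos_a, b = pos_b, efficiency = 1 / S)
}

#' Dynamic multibar pattern
#'
#' A sliding-gap control-point sequence whose cumulative fluence forms three
#' bar sets of widths 7, 5 and 2 mm on a uniform background, delivered
#' simultaneously by all leaf pairs inside the field.
#'
#' @param geometry an [mlc_geometry()].
#' @param n_cp number of control points.
#' @param field_halfwidth_cm field half-width (cm).
#' @param mu monitor units.
#' @param bar_amplitude bar fluence relative to the background (background
#'   is 0.35).
#' @return an [mlc_plan()] (attribute `fluence` carries the target profile
#'   function).
#' @export
make_multibar <- function(geometry, n_cp = 120, field_halfwidth_cm = 5,
                          mu = 600, bar_amplitude = 1) {
  hw <- field_halfwidth_cm
  bars <- rbind(c(-3.0, -3.0 + 0.7), c(-0.25, -0.25 + 0.5), c(2.5, 2.5 + 0.2))
  target <- function(x) {
    f <- rep(0.35, length(x))
    for (i in seq_len(nrow(bars)))
      f[x >= bars[i, 1] & x < bars[i, 2]] <- 0.35 + bar_amplitude
    f
  }
  sw <- .sliding_window(target, c(-hw, hw), n_cp)
  n <- length(geometry$leaf_widths_iso)
  cps <- lapply(seq_along(sw$u), function(i) {
    control_point(sw$u[i], 0, aperture_state(
      rep(sw$a[i], n), rep(max(sw$b[i], sw$a[i]), n),
      jaw_x1 = -hw, jaw_x2 = hw, jaw_y1 = -hw, jaw_y2 = hw,
      leaf_offset = geometry$leaf_offset))
  })
  p <- mlc_plan(cps, total_mu = mu, name = "multibar")
  attr(p, "fluence") <- target
  p
}

#' Dynamic cross-leaf gradient pattern
#'
#' Every leaf pair sweeps across the field at the same speed with a gap
#' width proportional to the target fluence at its y position, producing a
#' fluence gradient along the cross-leaf (y) direction.
#'
#' @param geometry an [mlc_geometry()].
#' @param n_cp control points.
#' @param field_halfwidth_cm field half-width (cm).
#' @param mu monitor units.
#' @param gap_range minimum/maximum sliding-gap widths (cm).
#' @return an [mlc_plan()].
#' @export
make_gradient_y <- function(geometry, n_cp = 80, field_halfwidth_cm = 5,
                            mu = 600, gap_range = c(0.4, 2.5)) {
  hw <- field_halfwidth_cm
  b <- .leaf_boundaries_iso(geometry)
  yc <- (b[-1] + b[-length(b)]) / 2
  n <- length(yc)
  frac <- (yc + hw) / (2 * hw)        # 0 at y = -hw, 1 at +hw
  frac <- pmin(pmax(frac, 0), 1)
  gap <- gap_range[1] + (gap_range[2] - gap_range[1]) * frac
  u <- seq(0, 1, length.out = n_cp)
  cps <- lapply(u, function(ui) {
    lead <- -hw + (2 * hw + gap) * ui       # bank B edge
    ba <- pmin(pmax(lead - gap, -hw), hw)
    bb <- pmin(pmax(lead, -hw), hw)
    bb <- pmax(bb, ba)
    control_point(ui, 0, aperture_state(
      ba, bb, jaw_x1 = -hw, jaw_x2 = hw, jaw_y1 = -hw, jaw_y2 = hw,
      leaf_offset = geometry$leaf_offset))
  })
  mlc_plan(cps, total_mu = mu, name = "gradient-y")
}

#' Dynamic negative-pyramid pattern
#'
#' Cumulative fluence minimal at the field center and increasing along both
#' the leaf-motion and cross-leaf directions (4-fold symmetric): each leaf
#' pair delivers a V-shaped profile `max(|x|, |y|)/L` via per-pair
#' sliding-window synthesis.
#'
#' @param geometry an [mlc_geometry()].
#' @param n_cp control points.
#' @param field_halfwidth_cm field half-width L (cm).
#' @param mu monitor units.
#' @param floor_fluence fluence at the center relative to the edge.
#' @return an [mlc_plan()].
#' @export
make_negative_pyramid <- function(geometry, n_cp = 80,
                                  field_halfwidth_cm = 5, mu = 600,
                                  floor_fluence = 0.2) {
  hw <- field_halfwidth_cm
  b <- .leaf_boundaries_iso(geometry)
  yc <- (b[-1] + b[-length(b)]) / 2
  n <- length(yc)
  u <- seq(0, 1, length.out = n_cp)
  A <- matrix(0, n, n_cp); B <- matrix(0, n, n_cp)
  for (i in seq_len(n)) {
    yi <- min(abs(yc[i]), hw)
    prof <- function(x)
      pmax(pmax(abs(x), yi) / hw, floor_fluence)
    sw <- .sliding_window(prof, c(-hw, hw), n_cp, events = FALSE)
    A[i, ] <- sw$a
    B[i, ] <- pmax(sw$b, sw$a)
  }
  cps <- lapply(seq_len(n_cp), function(j) {
    control_point(u[j], 0, aperture_state(
      A[, j], B[, j], jaw_x1 = -hw, jaw_x2 = hw, jaw_y1 = -hw,
      jaw_y2 = hw, leaf_offset = geometry$leaf_offset))
  })
  mlc_plan(cps, total_mu = mu, name = "negative-pyramid")
}

#' Toy VMAT arc
#'
#' A full arc (gantry 181 through 360 degrees of rotation to 179) with
#' uniform meterset per control point and a square aperture with a gentle
#' sinusoidal leaf modulation that always respects the closed-pair
#' invariant.
#'
#' @param geometry an [mlc_geometry()].
#' @param n_control_points number of control points.
#' @param field_size square field side (cm).
#' @param total_mu monitor units.
#' @param modulation leaf modulation amplitude (cm), < field_size/2.
#' @return an [mlc_plan()].
#' @export
make_toy_vmat_arc <- function(geometry, n_control_points = 90,
                              field_size = 10.5, total_mu = 2000,
                              modulation = 1) {
  stopifnot(modulation < field_size / 2)
  n <- length(geometry$leaf_widths_iso)
  hw <- field_size / 2
  u <- seq(0, 1, length.out = n_control_points)
  gantry <- (181 + u * 358) %% 360
  b <- .leaf_boundaries_iso(geometry)
  yc <- (b[-1] + b[-length(b)]) / 2
  cps <- lapply(seq_len(n_control_points), function(j) {
    mod <- modulation * sin(2 * pi * (u[j] + yc / (4 * hw)))
    ba <- pmin(-hw + pmax(mod, 0), hw)
    bb <- pmax(hw + pmin(mod, 0), ba)
    control_point(u[j], gantry[j], aperture_state(
      ba, bb, jaw_x1 = -hw, jaw_x2 = hw, jaw_y1 = -hw, jaw_y2 = hw,
      leaf_offset = geometry$leaf_offset))
  })
  mlc_plan(cps, total_mu = total_mu, name = "toy-vmat-arc")
}

#' Ideal cumulative fluence of a plan at the isocenter plane
#'
#' Accumulates the open-aperture indicator over the meterset, by midpoint
#' sampling of the control-point sequence: the geometric fluence a point
#' receives ignoring transmission, tips and scatter. Used to verify that
#' dynamic patterns deliver their intended shapes.
#'
#' @param plan an [mlc_plan()].
#' @param x,y evaluation coordinates at the isocenter (cm); `y` picks each
#'   point's leaf pair.
#' @param geometry an [mlc_geometry()] (for leaf lookup).
#' @param n_u meterset subdivisions.
#' @return matrix of relative fluence, `length(x)` by `length(y)`.
#' @export
plan_fluence <- function(plan, x, y, geometry, n_u = 400) {
  um <- (seq_len(n_u) - 0.5) / n_u
  st <- sample_control_point_state(plan, um)
  li <- leaf_index_at(geometry, y)$leaf_index
  flu <- matrix(0, length(x), length(y))
  for (j in seq_along(y)) {
    a <- st$bank_a[li[j], ]             # n_u trajectory for this pair
    bpos <- st$bank_b[li[j], ]
    jx1 <- st$jaws[1, ]; jx2 <- st$jaws[2, ]
    open <- outer(x, a, `>`) & outer(x, bpos, `<`) &
      outer(x, jx1, `>=`) & outer(x, jx2, `<`)
    flu[, j] <- rowMeans(open)
  }
  flu
}
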