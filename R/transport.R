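#' Primary transmission factor through a tungsten path
#'
#' Beer--Lambert weight multiplier for the forced (deterministic) primary:
#' `exp(-(mu/rho)(E) * areal_density)`.
#'
#' @param energy_mev photon energy (MeV), vectorised.
#' @param areal_density tungsten areal density along the ray (g/cm^2).
#' @param table attenuation tables ([attenuation_table()]).
#' @return multiplier in `(0, 1]`.
#' @export
transmit_primary <- function(energy_mev, areal_density,
                             table = attenuation_table()) {
  if (any(areal_density < 0)) stop("areal_density must be >= 0")
  mu <- mu_lookup(table, "tungsten", energy_mev)$mu_over_rho
  exp(-mu * areal_density)
}

#' Sample a Compton scatter from the Klein--Nishina distribution
#'
#' Kahn-style composition/rejection sampling of the Klein--Nishina
#' differential cross section for a free electron. The scattered energy
#' follows Compton kinematics `E' = E / (1 + (E/0.511)(1 - cos theta))`;
#' the azimuth is uniform.
#'
#' @param energy_mev incident photon energies (MeV), vectorised; recycled to
#'   length `n` when scalar.
#' @param n number of samples (default `length(energy_mev)`).
#' @param seed optional integer seed.
#' @return data.frame with `energy` (scattered, MeV), `cos_theta`, `phi`.
#' @export
sample_klein_nishina <- function(energy_mev, n = length(energy_mev),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- rep_len(energy_mev, n)
  k <- e / .ME_C2
  r <- numeric(n)          # r = E/E' in [1, 1+2k]
  todo <- rep(TRUE, n)
  a1 <- log1p(2 * k)
  a2 <- k * (1 + k) * 2 / (1 + 2 * k)^2  # weight of the r^-2-ish branch
  p1 <- a1 / (a1 + a2)
  while (any(todo)) {
    m <- sum(todo)
    km <- k[todo]
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    br1 <- u1 < p1[todo]
    rr <- numeric(m)
    rr[br1] <- exp(u2[br1] * a1[todo][br1])   # density ~ 1/eps on [eps0, 1]
    e0 <- 1 / (1 + 2 * km[!br1])
    rr[!br1] <- 1 / sqrt(e0^2 + u2[!br1] * (1 - e0^2))  # density ~ eps
    t <- (rr - 1) / km
    sin2 <- t * (2 - t)
    acc <- u3 <= (1 - rr * sin2 / (1 + rr^2))
    idx <- which(todo)
    r[idx[acc]] <- rr[acc]
    todo[idx[acc]] <- FALSE
  }
  data.frame(energy = e / r, cos_theta = 1 - (r - 1) / k,
             phi = stats::runif(n, 0, 2 * pi))
}

# rotate unit vectors (ux,uy,uz) by polar angle (cos_t) and azimuth phi
.rotate_direction <- function(ux, uy, uz, cos_t, phi) {
  sin_t <- sqrt(pmax(1 - cos_t^2, 0))
  sp <- sin(phi); cp <- cos(phi)
  # orthonormal frame around the incident direction
  small <- abs(uz) > 0.99
  # a = normalized (d x e) with e = z-hat (or x-hat near the pole)
  ax <- ifelse(small, 0, uy)
  ay <- ifelse(small, uz, -ux)
  az <- ifelse(small, -uy, 0)
  an <- sqrt(ax^2 + ay^2 + az^2)
  ax <- ax / an; ay <- ay / an; az <- az / an
  bx <- uy * az - uz * ay
  by <- uz * ax - ux * az
  bz <- ux * ay - uy * ax
  list(ux = ux * cos_t + sin_t * (cp * ax + sp * bx),
       uy = uy * cos_t + sin_t * (cp * ay + sp * by),
       uz = uz * cos_t + sin_t * (cp * az + sp * bz))
}

#' Carry photons through the MLC
#'
#' Implements the simplified leaf transport: the primary photon is always
#' transmitted deterministically with its weight multiplied by
#' `exp(-mu t)` over its tungsten path, and (optionally) one first-Compton
#' scattered photon is generated per attenuated primary as a weighted
#' particle: interaction depth sampled from the truncated exponential along
#' the tungsten chord, scattering angle and energy from Klein--Nishina, and
#' the scattered photon attenuated over its residual tungsten path to exit.
#' Electrons, photoelectric absorption re-emission, pair production and
#' higher-order scatter are not transported.
#'
#' @param photons data.frame of photons (see [sample_source_photon()]).
#' @param geometry an [mlc_geometry()].
#' @param aperture an [aperture_state()], or a list of `bank_a`/`bank_b`
#'   matrices (leaves x photons) for per-photon apertures.
#' @param table attenuation tables.
#' @param scatter generate first-Compton photons (default TRUE).
#' @param n_steps tracer integration steps across the leaf height.
#' @param seed optional integer seed.
#' @return data.frame of outgoing photons; `generation` is `"primary"` or
#'   `"compton1"`. Scattered photons directed away from the patient are
#'   dropped (they cannot reach the scoring plane).
#' @export
transport_through_mlc <- function(photons, geometry, aperture,
                                  table = attenuation_table(),
                                  scatter = TRUE, n_steps = 128L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(photons)
  gg <- .tracer_geom(geometry)
  if (inherits(aperture, "aperture_state")) {
    ba <- matrix(aperture$bank_a, ncol = 1)
    bb <- matrix(aperture$bank_b, ncol = 1)
    shared <- TRUE
  } else {
    ba <- aperture$bank_a; bb <- aperture$bank_b
    shared <- FALSE
  }
  if (any(photons$uz >= 0)) stop("photons must travel toward the patient")
  dxds <- -photons$ux / photons$uz
  dyds <- -photons$uy / photons$uz
  # source photons fly on straight lines from the focal spot, so a photon
  # recorded on a phase plane at or below the leaf assembly can be rewound
  # upstream exactly before tracing
  os <- geometry$sad - photons$z
  rew <- pmax(os - 0, 0)
  ox <- photons$x - dxds * rew
  oy <- photons$y - dyds * rew
  os <- os - rew
  uscat <- if (scatter) stats::runif(n) else numeric(0)
  lk <- mu_lookup(table, "tungsten", photons$energy)
  tr <- trace_mlc_cpp(ox, oy, os, dxds, dyds, ba, bb, shared,
                      gg, as.integer(n_steps), uscat,
                      if (scatter) lk$mu_over_rho else numeric(0))
  path <- tr$path
  out <- photons
  out$weight <- photons$weight * exp(-lk$mu_over_rho * path)
  out$generation <- "primary"
  out$parent <- seq_len(n)
  if (!scatter || !any(path > 0)) return(out)

  sc <- which(path > 0 & !is.na(tr$s_sc))
  if (length(sc)) {
    mu <- lk$mu_over_rho[sc]
    A <- path[sc]
    kn <- sample_klein_nishina(photons$energy[sc])
    dirs <- .rotate_direction(photons$ux[sc], photons$uy[sc],
                              photons$uz[sc], kn$cos_theta, kn$phi)
    keep <- dirs$uz < -0.05 & kn$energy > 0.02
    if (any(keep)) {
      sck <- sc[keep]
      zs <- geometry$sad - tr$s_sc[sck]
      mu2 <- mu_lookup(table, "tungsten", kn$energy[keep])$mu_over_rho
      res <- trace_mlc_cpp(tr$x_sc[sck], tr$y_sc[sck], tr$s_sc[sck],
                           -dirs$ux[keep] / dirs$uz[keep],
                           -dirs$uy[keep] / dirs$uz[keep],
                           ba[, if (shared) 1 else sck, drop = FALSE],
                           bb[, if (shared) 1 else sck, drop = FALSE],
                           shared, gg, as.integer(n_steps), numeric(0),
                           numeric(0))
      # forced-interaction estimator: interaction probability (1 - e^{-mu A}),
      # Compton share f_c, exit attenuation over the residual tungsten path
      w_sc <- photons$weight[sck] * (-expm1(-mu[keep] * A[keep])) *
        lk$compton_fraction[sck] * exp(-mu2 * res$path)
      scat <- data.frame(energy = kn$energy[keep],
                         x = tr$x_sc[sck], y = tr$y_sc[sck], z = zs,
                         ux = dirs$ux[keep], uy = dirs$uy[keep],
                         uz = dirs$uz[keep],
                         weight = w_sc, generation = "compton1",
                         parent = sck,
                         stringsAsFactors = FALSE)
      scat <- scat[scat$weight > 0, ]
      out <- rbind(out[, names(scat)], scat)
    }
  }
  out
}
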