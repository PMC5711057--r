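#' Synthesize MLC half tables and config
#'
#' Generates the thickness-versus-position half tables and the key-value
#' config for a two-bank MLC with tongue-and-groove structure. The numeric
#' content of the vendor tables is proprietary, so the packaged tables are
#' synthesized: full-thickness leaf bodies, with the upper-half metal
#' shifted by half the tongue width toward +y and the lower half toward -y
#' (forming the interlocking tongue-and-groove), a small air gap between
#' adjacent leaves in each half, and a vertical tongue/groove clearance that
#' makes the summed thickness dip below the full leaf height inside the step
#' region. All dimensions are configurable.
#'
#' @param model `"hd120"` or `"millennium120"`.
#' @param tg_width tongue-and-groove step width at the MLC plane (cm).
#' @param air_gap effective air gap between adjacent leaves in a half (cm).
#'   The default is an effective value, a little wider than a physical
#'   leaf-side clearance, because the model treats leaf side faces as
#'   focused toward the source while real leaf sides are parallel; it is
#'   fixed by the standard commissioning condition that the packaged
#'   geometry at the transmission-calibrated density reproduce the
#'   measured mean MLC transmission.
#' @param tg_clearance vertical tongue/groove machining clearance (cm); the
#'   summed thickness in the step region is the leaf height minus this.
#' @param density leaf density (g/cm^3); the packaged default is the value
#'   calibrated against transmission measurements.
#' @param z_upper distance of the upper MLC surface from the source (cm).
#' @param leaf_offset physical gap between closed opposing leaf tips (cm).
#' @return list with `upper`, `lower` (data.frames: leaf, y, thickness),
#'   `config` (named list) and `widths_iso`.
#' @export
synthesize_mlc_tables <- function(model = c("hd120", "millennium120"),
                                  tg_width = 0.03, air_gap = 0.0115,
                                  tg_clearance = 0.04, density = NULL,
                                  z_upper = 50.9, leaf_offset = 0.01) {
  model <- match.arg(model)
  if (model == "hd120") {
    widths <- c(rep(0.5, 14), rep(0.25, 32), rep(0.5, 14))
    h <- 6.9; tipR <- 16; tipA <- 0
    if (is.null(density)) density <- 18.9
    name <- "HD120"
  } else {
    widths <- c(rep(1.0, 10), rep(0.5, 40), rep(1.0, 10))
    h <- 6.7; tipR <- 8; tipA <- 11.3
    if (is.null(density)) density <- 17.6
    name <- "Millennium120"
  }
  z_mid <- z_upper + h / 2
  f <- z_mid / 100
  b_iso <- cumsum(c(0, widths)) - sum(widths) / 2
  b <- b_iso * f                       # boundaries at the MLC mid-plane
  n <- length(widths)
  th <- h / 2
  s2 <- tg_width / 2; g2 <- air_gap / 2; cl <- tg_clearance / 2
  up <- lo <- vector("list", n)
  for (i in seq_len(n)) {
    # upper-half metal shifted +s2, lower-half -s2; air gap g at each joint;
    # edge strips of width tg carry the tongue/groove clearance
    u0 <- b[i] + s2 + g2; u1 <- b[i + 1] + s2 - g2
    l0 <- b[i] - s2 + g2; l1 <- b[i + 1] - s2 - g2
    up[[i]] <- data.frame(
      leaf = i,
      y = c(u0, u1 - tg_width, u1),
      thickness = c(th, th - cl, 0))
    lo[[i]] <- data.frame(
      leaf = i,
      y = c(l0, l0 + tg_width, l1),
      thickness = c(th - cl, th, 0))
  }
  list(upper = do.call(rbind, up), lower = do.call(rbind, lo),
       config = list(model_name = name, density = density,
                     tip_radius = tipR, tip_angle = tipA,
                     tip_max_thickness = h, leaf_offset = leaf_offset,
                     z_upper = z_upper, physical_thickness = h, sad = 100),
       widths_iso = widths)
}

#' Write MLC geometry files in the documented dialect
#'
#' The half tables are whitespace-delimited rows `leaf y thickness` after
#' `#` comment lines; the config is `key = value` lines. Leaf widths are
#' stored in the config as `inner_leaves/inner_width/outer_leaves/
#' outer_width`.
#'
#' @param tables output of [synthesize_mlc_tables()].
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_mlc_config <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtab <- function(tab, path, label) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# ", label, " leaf thickness vs cross-leaf position"),
                 "# columns: leaf_number  y_breakpoint_cm  thickness_cm"), con)
    writeLines(sprintf("%d  %.6f  %.4f", tab$leaf, tab$y, tab$thickness), con)
  }
  up_path <- file.path(dir, "upperhalf.table")
  lo_path <- file.path(dir, "lowerhalf.table")
  cf_path <- file.path(dir, "particledmlc.config")
  wtab(tables$upper, up_path, "upper half")
  wtab(tables$lower, lo_path, "lower half")
  w <- tables$widths_iso
  rw <- rle(w)
  cfg <- tables$config
  cfg$inner_leaves <- rw$lengths[2]
  cfg$inner_width <- rw$values[2]
  cfg$outer_leaves <- rw$lengths[1] + rw$lengths[3]
  cfg$outer_width <- rw$values[1]
  con <- file(cf_path, "w")
  writeLines("# MLC physical configuration", con)
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) paste(format(v), collapse = ","),
                            character(1))), con)
  close(con)
  invisible(c(upper = up_path, lower = lo_path, config = cf_path))
}

.parse_table_file <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 3)
  if (length(bad))
    stop("malformed row in ", basename(path), " at line ", rows[bad[1]],
         ": expected 'leaf y thickness'")
  num <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE))
  if (any(is.na(num))) {
    bad <- rows[which(apply(is.na(num), 1, any))[1]]
    stop("malformed row in ", basename(path), " at line ", bad,
         ": non-numeric field")
  }
  data.frame(leaf = as.integer(num[, 1]), y = num[, 2], thickness = num[, 3])
}

.parse_config_file <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  kv <- strsplit(lines[keep], "=", fixed = TRUE)
  bad <- which(vapply(kv, length, integer(1)) != 2)
  if (length(bad))
    stop("malformed line in ", basename(path), ": ", lines[keep][bad[1]])
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  out <- as.list(vals)
  names(out) <- keys
  num <- suppressWarnings(lapply(vals, as.numeric))
  for (i in seq_along(out)) if (!is.na(num[[i]])) out[[i]] <- num[[i]]
  out
}

#' Load an MLC geometry from config files
#'
#' Reads the two half tables and the physical config in the documented
#' dialect (see [write_mlc_config()]) and assembles a validated
#' [mlc_geometry()].
#'
#' @param upper_table_path,lower_table_path,config_path file paths.
#' @return an [mlc_geometry()].
#' @export
load_mlc_config <- function(upper_table_path, lower_table_path, config_path) {
  for (p in c(upper_table_path, lower_table_path, config_path))
    if (!file.exists(p)) stop("file not found: ", p)
  up <- .parse_table_file(upper_table_path)
  lo <- .parse_table_file(lower_table_path)
  cfg <- .parse_config_file(config_path)
  need <- c("density", "tip_radius", "z_upper", "physical_thickness",
            "inner_leaves", "inner_width", "outer_leaves", "outer_width")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing keys: ", paste(miss, collapse = ", "))
  no2 <- cfg$outer_leaves / 2
  widths <- c(rep(cfg$outer_width, no2), rep(cfg$inner_width, cfg$inner_leaves),
              rep(cfg$outer_width, no2))
  mlc_geometry(
    model_name = if (!is.null(cfg$model_name)) cfg$model_name else "custom",
    leaf_widths_iso = widths,
    upper_table = up, lower_table = lo,
    physical_thickness = cfg$physical_thickness,
    tip_radius = cfg$tip_radius,
    tip_angle = if (!is.null(cfg$tip_angle)) cfg$tip_angle else 0,
    tip_max_thickness = if (!is.null(cfg$tip_max_thickness))
      cfg$tip_max_thickness else cfg$physical_thickness,
    density = cfg$density,
    leaf_offset = if (!is.null(cfg$leaf_offset)) cfg$leaf_offset else 0.01,
    z_upper = cfg$z_upper,
    sad = if (!is.null(cfg$sad)) cfg$sad else 100)
}

#' Packaged MLC geometry presets
#'
#' Loads the packaged HD120 (60 leaves per bank: 32 quarter-cm central plus
#' 28 half-cm outer, 6.9 cm leaf height, 16 cm tip radius, no tip facet) or
#' Millennium120 (6.7 cm height, 8 cm tip radius, 11.3 degree tip facet)
#' geometry from the shipped config files. The half-table numeric content is
#' synthesized (see [synthesize_mlc_tables()]); the packaged density is the
#' transmission-calibrated value of 18.9 g/cm^3 for the HD120.
#'
#' @param model `"hd120"` or `"millennium120"`.
#' @return an [mlc_geometry()].
#' @export
mlc_preset <- function(model = c("hd120", "millennium120")) {
  model <- match.arg(model)
  dir <- system.file("extdata", model, package = "mlcport")
  if (dir == "") stop("packaged geometry not found for ", model)
  load_mlc_config(file.path(dir, "upperhalf.table"),
                  file.path(dir, "lowerhalf.table"),
                  file.path(dir, "particledmlc.config"))
}
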