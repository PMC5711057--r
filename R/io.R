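#' Read and write dose grids in a 3ddose-style text dialect
#'
#' Layout follows the classic DOSXYZnrc text convention: voxel counts on the
#' first data line, then the three boundary lists, then all dose values, then
#' all relative errors (x fastest). Lines starting with `#` are provenance
#' comments; [write_dose_grid()] records the package version and any `seed`
#' / `n_histories` fields present in the grid's metadata.
#'
#' @param grid a [dose_grid()].
#' @param path file path.
#' @return `read_dose_grid` returns a [dose_grid()]; `write_dose_grid`
#'   returns `path` invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$dose)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(paste0("# mlcport dose grid v1 (package ",
                  as.character(utils::packageVersion("mlcport")), ")"))
  for (k in intersect(c("seed", "n_histories", "plan", "depth_cm"),
                      names(grid$meta)))
    hdr <- c(hdr, paste0("# ", k, " = ", format(grid$meta[[k]])))
  writeLines(hdr, con)
  writeLines(paste(d, collapse = " "), con)
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  writeLines(fmt(grid$xb), con)
  writeLines(fmt(grid$yb), con)
  writeLines(fmt(grid$zb), con)
  writeLines(fmt(as.numeric(grid$dose)), con)
  writeLines(fmt(as.numeric(grid$relerr)), con)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  data <- lines[!grepl("^\\s*#", lines)]
  data <- data[nzchar(trimws(data))]
  toks <- strsplit(trimws(data[1]), "\\s+")[[1]]
  d <- suppressWarnings(as.integer(toks))
  if (length(d) != 3 || any(is.na(d)) || any(d < 1))
    stop("parse error in ", basename(path),
         ": header must hold three voxel counts, got '", data[1], "'")
  rest <- suppressWarnings(as.numeric(unlist(strsplit(trimws(data[-1]),
                                                      "\\s+"))))
  if (any(is.na(rest))) stop("parse error in ", basename(path),
                             ": non-numeric value in body")
  nb <- (d[1] + 1) + (d[2] + 1) + (d[3] + 1)
  nv <- prod(d)
  if (length(rest) != nb + 2 * nv)
    stop("parse error in ", basename(path), ": expected ", nb + 2 * nv,
         " values after the header, found ", length(rest))
  xb <- rest[1:(d[1] + 1)]
  yb <- rest[(d[1] + 2):(d[1] + d[2] + 2)]
  zb <- rest[(d[1] + d[2] + 3):nb]
  if (any(diff(xb) <= 0) || any(diff(yb) <= 0) || any(diff(zb) <= 0))
    stop("parse error in ", basename(path),
         ": boundary list is not strictly increasing")
  dose <- array(rest[nb + 1:nv], d)
  rel <- array(rest[nb + nv + 1:nv], d)
  meta <- list()
  for (ln in grep("^# \\w+ = ", lines, value = TRUE)) {
    kv <- sub("^# ", "", ln)
    k <- sub(" = .*", "", kv); v <- sub(".* = ", "", kv)
    vn <- suppressWarnings(as.numeric(v))
    meta[[k]] <- if (!is.na(vn)) vn else v
  }
  dose_grid(dose, xb, yb, zb, relerr = rel, meta = meta)
}

#' Read and write delivery plans as JSON
#'
#' The native plan format is a JSON document with fields `name`, `beam`,
#' `total_mu` and `control_points`, each control point holding
#' `cumulative_meterset`, `gantry_angle_deg`, `jaws` (x1, x2, y1, y2) and
#' the two leaf banks. Plan invariants (meterset monotone 0 to 1,
#' closed-pair ordering) are enforced on read.
#'
#' @param plan an [mlc_plan()].
#' @param path file path.
#' @return `read_plan` returns an [mlc_plan()]; `write_plan` returns `path`
#'   invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "mlc_plan"))
  cps <- lapply(plan$control_points, function(cp) {
    ap <- cp$aperture
    list(cumulative_meterset = cp$cumulative_meterset,
         gantry_angle_deg = cp$gantry_angle_deg,
         jaws = c(ap$jaw_x1, ap$jaw_x2, ap$jaw_y1, ap$jaw_y2),
         bank_a = ap$bank_a, bank_b = ap$bank_b)
  })
  doc <- list(format = "mlcport-plan-v1", name = plan$name,
              beam = plan$beam, total_mu = plan$total_mu,
              control_points = cps)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$control_points)) stop("not a plan file: ", path)
  cps <- doc$control_points
  build <- function(i) {
    jw <- if (is.matrix(cps$jaws)) cps$jaws[i, ] else unlist(cps$jaws[[i]])
    ba <- if (is.matrix(cps$bank_a)) cps$bank_a[i, ] else cps$bank_a[[i]]
    bb <- if (is.matrix(cps$bank_b)) cps$bank_b[i, ] else cps$bank_b[[i]]
    control_point(cps$cumulative_meterset[i], cps$gantry_angle_deg[i],
                  aperture_state(ba, bb, jw[1], jw[2], jw[3], jw[4]))
  }
  n <- length(cps$cumulative_meterset)
  mlc_plan(lapply(seq_len(n), build), total_mu = doc$total_mu,
           beam = if (!is.null(doc$beam)) doc$beam else "6X",
           name = if (!is.null(doc$name)) doc$name else "plan")
}
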