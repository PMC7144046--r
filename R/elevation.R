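#' Construct an elevation map
#'
#' A gridded anterior corneal elevation surface. Heights are in micrometres
#' on a rectangular, uniformly spaced grid of mm coordinates. Points outside
#' the analysis aperture (inscribed circle of `diameter_mm`) may be NA;
#' NA inside the aperture marks missing data.
#'
#' @param xs,ys strictly increasing, uniformly spaced grid coordinates (mm).
#' @param z height matrix in micrometres, dim `length(xs) x length(ys)`
#'   (rows follow `xs`, columns follow `ys`).
#' @param center label of the current grid origin, one of
#'   `"corneal_vertex"`, `"geometric_center"`, `"pupil_center"`.
#' @param diameter_mm analysis aperture diameter (mm).
#' @param ref_points named list of `(x, y)` offsets (mm, in the current
#'   coordinates) of the available centering references; used by
#'   [recenter_elevation()].
#' @return object of class `elevation_map`.
#' @export
elevation_map <- function(xs, ys, z,
                          center = "corneal_vertex",
                          diameter_mm = max(xs) - min(xs),
                          ref_points = list()) {
  center <- match.arg(center,
                      c("corneal_vertex", "geometric_center", "pupil_center"))
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  check_uniform <- function(v, nm) {
    if (length(v) < 2L || any(diff(v) <= 0)) {
      stop(nm, " coordinates must be strictly increasing", call. = FALSE)
    }
    d <- diff(v)
    if (max(d) - min(d) > 1e-6 * mean(d)) {
      stop(nm, " coordinates must be uniformly spaced", call. = FALSE)
    }
  }
  check_uniform(xs, "x"); check_uniform(ys, "y")
  z <- as.matrix(z)
  if (!all(dim(z) == c(length(xs), length(ys)))) {
    stop("z must have dim length(xs) x length(ys)", call. = FALSE)
  }
  stopifnot(diameter_mm > 0)
  structure(list(xs = xs, ys = ys, z = z, center = center,
                 diameter_mm = as.numeric(diameter_mm),
                 ref_points = ref_points),
            class = "elevation_map")
}

#' @export
print.elevation_map <- function(x, ...) {
  cat("Corneal elevation map\n")
  cat(sprintf("  grid: %d x %d, x in [%g, %g] mm, y in [%g, %g] mm\n",
              length(x$xs), length(x$ys), min(x$xs), max(x$xs),
              min(x$ys), max(x$ys)))
  cat(sprintf("  aperture: %g mm, centered on %s\n", x$diameter_mm, x$center))
  zr <- range(x$z, na.rm = TRUE)
  cat(sprintf("  height range: %.2f to %.2f um (%d missing cells)\n",
              zr[1], zr[2], sum(is.na(x$z))))
  invisible(x)
}

#' @export
plot.elevation_map <- function(x, main = "Anterior elevation (um)", ...) {
  graphics::image(x$xs, x$ys, x$z, asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                  main = main, ...)
  graphics::contour(x$xs, x$ys, x$z, add = TRUE, drawlabels = FALSE,
                    col = "grey30")
  invisible(x)
}

# Catmull-Rom bicubic interpolation on the uniform grid; NA where the 4x4
# support leaves the grid. Used for meridional profile sampling, where the
# O(h^2) bias of bilinear interpolation would alias into spurious
# keratometric astigmatism.
interp_bicubic <- function(map, x, y) {
  xs <- map$xs; ys <- map$ys; z <- map$z
  nx <- length(xs); ny <- length(ys)
  fx <- (x - xs[1]) / (xs[2] - xs[1])
  fy <- (y - ys[1]) / (ys[2] - ys[1])
  i <- floor(fx); j <- floor(fy)
  out <- rep(NA_real_, length(x))
  ok <- i >= 1 & i <= nx - 3 & j >= 1 & j <= ny - 3
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]
  tx <- fx[ok] - i; ty <- fy[ok] - j
  wcr <- function(t) {
    cbind(-0.5 * t^3 + t^2 - 0.5 * t,
          1.5 * t^3 - 2.5 * t^2 + 1,
          -1.5 * t^3 + 2 * t^2 + 0.5 * t,
          0.5 * t^3 - 0.5 * t^2)
  }
  wx <- wcr(tx); wy <- wcr(ty)
  acc <- numeric(length(i))
  for (a in 0:3) {
    rowv <- numeric(length(i))
    for (b in 0:3) {
      rowv <- rowv + wx[, b + 1L] * z[cbind(i + b, j + a)]
    }
    acc <- acc + wy[, a + 1L] * rowv
  }
  out[ok] <- acc
  out
}

# bilinear interpolation on the uniform grid; NA outside the grid
interp_bilinear <- function(map, x, y) {
  xs <- map$xs; ys <- map$ys; z <- map$z
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  fx <- (x - xs[1]) / dx
  fy <- (y - ys[1]) / dy
  i <- floor(fx); j <- floor(fy)
  out <- rep(NA_real_, length(x))
  ok <- i >= 0 & i <= length(xs) - 2 & j >= 0 & j <= length(ys) - 2
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]
  tx <- fx[ok] - i; ty <- fy[ok] - j
  i1 <- i + 1L; j1 <- j + 1L   # 1-based corner
  z11 <- z[cbind(i1, j1)]; z21 <- z[cbind(i1 + 1L, j1)]
  z12 <- z[cbind(i1, j1 + 1L)]; z22 <- z[cbind(i1 + 1L, j1 + 1L)]
  out[ok] <- (1 - tx) * (1 - ty) * z11 + tx * (1 - ty) * z21 +
    (1 - tx) * ty * z12 + tx * ty * z22
  out
}

#' Re-center an elevation map on a different reference
#'
#' Translates the map coordinates so that the chosen reference point
#' (corneal vertex, geometric center, or pupil center) becomes the origin of
#' the analysis aperture. The grid itself is not resampled -- coordinates
#' and stored reference offsets are shifted exactly -- so re-centering and
#' centering back is an identity. Downstream Zernike fits see a different
#' in-aperture sample set and a different tilt/coma partition, but the same
#' physical surface.
#'
#' @param map an [elevation_map].
#' @param center requested reference label.
#' @return the translated [elevation_map] with `center` updated.
#' @export
recenter_elevation <- function(map, center) {
  stopifnot(inherits(map, "elevation_map"))
  center <- match.arg(center,
                      c("corneal_vertex", "geometric_center", "pupil_center"))
  if (identical(center, map$center)) return(map)
  off <- map$ref_points[[center]]
  if (is.null(off)) {
    stop("reference point '", center, "' is not present in the map metadata",
         call. = FALSE)
  }
  map$xs <- map$xs - off[1]
  map$ys <- map$ys - off[2]
  map$ref_points <- lapply(map$ref_points,
                           function(p) c(p[1] - off[1], p[2] - off[2]))
  map$ref_points[[map$center]] <- c(-off[1], -off[2])
  map$ref_points[[center]] <- c(0, 0)
  map$center <- center
  map
}

#' Read an elevation map from a CSV grid
#'
#' Expected layout: the first row holds the corner tag followed by the x
#' coordinates (mm); each following row starts with its y coordinate (mm)
#' followed by heights in micrometres. Blank cells are missing points. The
#' corner tag must contain the unit markers `mm` and `um` (the writer emits
#' `y_mm\\x_mm;z=um`).
#'
#' @param path file path.
#' @param ... passed to [elevation_map()] (e.g. `diameter_mm`, `ref_points`).
#' @return an [elevation_map].
#' @export
read_elevation_csv <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("elevation CSV too short", call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("ragged elevation CSV: row ", bad, " has ", widths[bad],
         " cells, expected ", widths[1], call. = FALSE)
  }
  tag <- cells[[1]][1]
  if (!grepl("mm", tag, fixed = TRUE) || !grepl("um", tag, fixed = TRUE)) {
    stop("elevation CSV corner tag '", tag,
         "' lacks the expected unit markers (mm, um)", call. = FALSE)
  }
  num <- function(v) suppressWarnings(as.numeric(ifelse(trimws(v) == "", NA, v)))
  xs <- num(cells[[1]][-1])
  if (anyNA(xs) || any(diff(xs) <= 0)) {
    stop("header x coordinates (row 1) must be numeric and strictly increasing",
         call. = FALSE)
  }
  ys <- num(vapply(cells[-1], `[`, "", 1L))
  if (anyNA(ys) || any(diff(ys) <= 0)) {
    stop("y coordinates (column 1) must be numeric and strictly increasing",
         call. = FALSE)
  }
  z <- t(vapply(cells[-1], function(r) num(r[-1]), numeric(length(xs))))
  # rows of the file follow ys; elevation_map stores z as xs x ys
  elevation_map(xs, ys, t(z), ...)
}

#' Write an elevation map as a CSV grid
#'
#' @param map an [elevation_map].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_elevation_csv <- function(map, path) {
  stopifnot(inherits(map, "elevation_map"))
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  header <- paste(c("y_mm\\x_mm;z=um", fmt(map$xs)), collapse = ",")
  rows <- vapply(seq_along(map$ys), function(j) {
    paste(c(fmt(map$ys[j]), fmt(map$z[, j])), collapse = ",")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
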