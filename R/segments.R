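#' KeraRing segment catalog
#'
#' The eight simulated segment types: the SI5 family (5 mm optical-zone
#' diameter) with arc lengths 90, 120, 160 and 210 degrees, and the SI6
#' family (6 mm) with arcs 90, 120, 150 and 210 degrees.
#'
#' @return data.frame with columns `model` and `arc_deg`.
#' @export
keraring_catalog <- function() {
  data.frame(model = rep(c("SI5", "SI6"), each = 4L),
             arc_deg = c(90, 120, 160, 210, 90, 120, 150, 210))
}

#' Default segment thickness set
#'
#' Manufacturer-typical catalog thicknesses in micrometres. Configurable in
#' every function that takes a thickness set.
#'
#' @return numeric vector of thicknesses (um).
#' @export
default_thickness_set <- function() {
  c(150, 200, 250, 300, 350)
}

#' Construct an intracorneal ring segment descriptor
#'
#' @param model `"SI5"` (5 mm diameter family) or `"SI6"` (6 mm).
#' @param arc_deg arc length in degrees; must be a catalog arc for the
#'   model (SI5: 90/120/160/210, SI6: 90/120/150/210).
#' @param thickness_um segment thickness (um).
#' @param bisecting_line_deg meridian through the arc midpoint, normalized
#'   to \[0, 360).
#' @return object of class `segment_spec`.
#' @export
#' @examples
#' segment_spec("SI6", 150, 250, 90)
segment_spec <- function(model, arc_deg, thickness_um, bisecting_line_deg) {
  model <- match.arg(model, c("SI5", "SI6"))
  cat_arcs <- keraring_catalog()
  legal <- cat_arcs$arc_deg[cat_arcs$model == model]
  if (!arc_deg %in% legal) {
    stop("arc ", arc_deg, " is not in the ", model, " catalog (",
         paste(legal, collapse = ", "), ")", call. = FALSE)
  }
  if (thickness_um <= 0) stop("thickness must be positive", call. = FALSE)
  structure(list(model = model, arc_deg = as.numeric(arc_deg),
                 thickness_um = as.numeric(thickness_um),
                 bisecting_line_deg = bisecting_line_deg %% 360,
                 diameter_mm = if (model == "SI5") 5 else 6),
            class = "segment_spec")
}

format_segment <- function(s) {
  sprintf("%s-%g/%gum@%g", s$model, s$arc_deg, s$thickness_um,
          s$bisecting_line_deg)
}

#' @export
print.segment_spec <- function(x, ...) {
  cat(sprintf("ICRS segment %s-%g: %g um thick, bisecting line %g deg (%g mm diameter)\n",
              x$model, x$arc_deg, x$thickness_um, x$bisecting_line_deg,
              x$diameter_mm))
  invisible(x)
}

# smallest angular distance between two meridians (degrees)
angle_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Enumerate candidate implant configurations
#'
#' Builds the exhaustive candidate space of the planner: every single
#' segment (catalog model-arc x thickness x bisecting line on the axis
#' grid), and every unordered pair of segments whose arcs do not overlap
#' (angular separation of the bisecting lines at least the mean of the two
#' arc lengths). Ordering is deterministic.
#'
#' @param catalog data.frame of model/arc rows (default [keraring_catalog()]).
#' @param thickness_set thicknesses in um (default [default_thickness_set()]).
#' @param axis_step_deg bisecting-line grid step; must divide 360
#'   (default 5).
#' @param max_segments 1 for singles only, 2 to include pairs.
#' @return data.frame with one row per candidate: `n_segments`, `model1`,
#'   `arc1`, `thickness1`, `axis1`, and the slot-2 analogues (NA for
#'   singles), plus a deterministic `code` string.
#' @export
enumerate_candidates <- function(catalog = keraring_catalog(),
                                 thickness_set = default_thickness_set(),
                                 axis_step_deg = 5,
                                 max_segments = 2) {
  if (is.null(catalog) || nrow(catalog) == 0L) {
    stop("segment catalog is empty", call. = FALSE)
  }
  if (360 %% axis_step_deg != 0) {
    stop("axis_step_deg must divide 360", call. = FALSE)
  }
  stopifnot(max_segments %in% 1:2)
  axes <- seq(0, 360 - axis_step_deg, by = axis_step_deg)
  singles <- expand.grid(axis1 = axes, thickness1 = sort(thickness_set),
                         seg = seq_len(nrow(catalog)),
                         KEEP.OUT.ATTRS = FALSE)
  singles <- data.frame(n_segments = 1L,
                        model1 = catalog$model[singles$seg],
                        arc1 = catalog$arc_deg[singles$seg],
                        thickness1 = singles$thickness1,
                        axis1 = singles$axis1,
                        model2 = NA_character_, arc2 = NA_real_,
                        thickness2 = NA_real_, axis2 = NA_real_,
                        stringsAsFactors = FALSE)
  # deterministic order: catalog row, thickness, axis
  singles <- singles[order(match(singles$model1, c("SI5", "SI6")),
                           singles$arc1, singles$thickness1, singles$axis1), ]
  out <- singles
  if (max_segments == 2L) {
    n <- nrow(singles)
    i <- rep(seq_len(n), times = n)
    j <- rep(seq_len(n), each = n)
    keep <- i < j
    i <- i[keep]; j <- j[keep]
    a <- singles[i, ]; b <- singles[j, ]
    sep <- angle_dist(a$axis1, b$axis1)
    ok <- sep >= (a$arc1 + b$arc1) / 2
    pairs <- data.frame(n_segments = 2L,
                        model1 = a$model1[ok], arc1 = a$arc1[ok],
                        thickness1 = a$thickness1[ok], axis1 = a$axis1[ok],
                        model2 = b$model1[ok], arc2 = b$arc1[ok],
                        thickness2 = b$thickness1[ok], axis2 = b$axis1[ok],
                        stringsAsFactors = FALSE)
    out <- rbind(singles, pairs)
  }
  out$code <- with(out, ifelse(
    n_segments == 1L,
    sprintf("%s-%03d/%03d@%03d", model1, arc1, thickness1, axis1),
    sprintf("%s-%03d/%03d@%03d+%s-%03d/%03d@%03d",
            model1, arc1, thickness1, axis1,
            model2, arc2, thickness2, axis2)))
  rownames(out) <- NULL
  out
}

# build list of segment_spec from a candidate row
candidate_segments <- function(row) {
  segs <- list(segment_spec(row$model1, row$arc1, row$thickness1, row$axis1))
  if (row$n_segments == 2L) {
    segs <- c(segs, list(segment_spec(row$model2, row$arc2, row$thickness2,
                                      row$axis2)))
  }
  segs
}
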