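# Core geometric data model: subpixel polygon contours on a slice/phase grid.
#
# Coordinate convention: 0-based pixel coordinates, x = column, y = row, both
# subpixel floats. Physical distances and areas are obtained by scaling
# x by the column spacing and y by the row spacing (mm/pixel) before any
# distance or area computation, so anisotropic spacing is honoured.

## ---- low-level ring helpers -------------------------------------------------

as_ring <- function(ring) {
  if (is.data.frame(ring)) ring <- as.matrix(ring[, c("x", "y")])
  ring <- unname(as.matrix(ring))
  if (ncol(ring) != 2L) stop("a ring must be an n x 2 matrix of (x, y) vertices", call. = FALSE)
  storage.mode(ring) <- "double"
  # rings are implicitly closed: drop a duplicated closing vertex
  n <- nrow(ring)
  if (n >= 2L && isTRUE(all(ring[1L, ] == ring[n, ]))) ring <- ring[-n, , drop = FALSE]
  ring
}

# Signed shoelace area; positive for counter-clockwise rings in (x, y).
ring_area_signed <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

ring_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

ring_perimeter <- function(ring) {
  d <- ring[c(2:nrow(ring), 1L), , drop = FALSE] - ring
  sum(sqrt(rowSums(d^2)))
}

# Scale pixel coordinates to mm: x (column) by spacing[2], y (row) by spacing[1].
scale_ring <- function(ring, spacing) {
  cbind(ring[, 1L] * spacing[2L], ring[, 2L] * spacing[1L])
}

point_in_ring <- function(px, py, ring) {
  sp::point.in.polygon(px, py, ring[, 1L], ring[, 2L]) > 0
}

## ---- ContourPolygon ---------------------------------------------------------

#' Create a subpixel contour polygon
#'
#' A contour polygon is one structure's annotation on one slice/phase: an
#' outer boundary ring plus optional hole rings, with subpixel vertex
#' coordinates in pixel units (x = column, y = row). Rings are implicitly
#' closed. On construction the outer ring is normalised to counter-clockwise
#' (positive shoelace area) and holes to clockwise.
#'
#' @param rings a single n x 2 matrix (or data frame with columns `x`, `y`),
#'   or a list of such matrices; the first is the outer boundary, the rest
#'   are holes.
#' @param structure one of `"lv_endo"`, `"lv_epi"`, `"rv_endo"`.
#' @return an object of class `contour_polygon`.
#' @examples
#' sq <- contour_polygon(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)), "lv_endo")
#' polygon_area(sq)
#' @export
contour_polygon <- function(rings, structure = "lv_endo") {
  structure <- match.arg(structure, STRUCTURES)
  if (!is.list(rings) || is.data.frame(rings)) rings <- list(rings)
  rings <- lapply(rings, as_ring)
  for (i in seq_along(rings)) {
    if (nrow(rings[[i]]) < 3L) {
      stop(sprintf("degenerate geometry: ring %d has fewer than 3 vertices", i), call. = FALSE)
    }
    if (!all(is.finite(rings[[i]]))) stop("ring vertices must be finite", call. = FALSE)
  }
  # orientation: outer counter-clockwise, holes clockwise
  a <- vapply(rings, ring_area_signed, numeric(1))
  if (a[1L] < 0) { rings[[1L]] <- rings[[1L]][nrow(rings[[1L]]):1L, , drop = FALSE] }
  if (length(rings) > 1L) {
    for (i in 2:length(rings)) {
      if (a[i] > 0) rings[[i]] <- rings[[i]][nrow(rings[[i]]):1L, , drop = FALSE]
      ctr <- ring_centroid(rings[[i]])
      if (!point_in_ring(ctr[1L], ctr[2L], rings[[1L]])) {
        stop("hole ring lies outside the outer boundary", call. = FALSE)
      }
    }
  }
  structure(list(structure = structure, rings = rings), class = "contour_polygon")
}

#' @export
print.contour_polygon <- function(x, ...) {
  cat(sprintf("<contour_polygon> %s: %d ring(s), %d vertices, area %.2f px^2\n",
              x$structure, length(x$rings),
              sum(vapply(x$rings, nrow, integer(1))), polygon_area(x)))
  invisible(x)
}

#' Polygon area in physical units
#'
#' Shoelace area of the outer ring minus hole areas, scaled by
#' row-spacing x column-spacing.
#'
#' @param poly a [contour_polygon()].
#' @param spacing `(row, column)` pixel spacing in mm/pixel; the default
#'   `c(1, 1)` yields the area in px^2.
#' @return area in mm^2 (nonnegative).
#' @export
polygon_area <- function(poly, spacing = c(1, 1)) {
  stopifnot(inherits(poly, "contour_polygon"), length(spacing) == 2L, all(spacing > 0))
  a <- vapply(poly$rings, ring_area_signed, numeric(1))
  max(0, sum(a)) * spacing[1L] * spacing[2L]
}

#' Resample a polygon boundary to a maximum step length
#'
#' Subdivides every edge so that consecutive points are at most `max_step`
#' apart (in the polygon's coordinate units); all original vertices are
#' retained. Used to build the dense point sets behind the Hausdorff distance.
#'
#' @param poly a [contour_polygon()].
#' @param max_step maximum distance between consecutive resampled points.
#' @return a list with one n x 2 coordinate matrix per ring.
#' @export
resample_boundary <- function(poly, max_step) {
  stopifnot(inherits(poly, "contour_polygon"), max_step > 0)
  lapply(poly$rings, resample_ring, max_step = max_step)
}

resample_ring <- function(ring, max_step) {
  n <- nrow(ring)
  nxt <- ring[c(2:n, 1L), , drop = FALSE]
  seg <- sqrt(rowSums((nxt - ring)^2))
  k <- pmax(1L, ceiling(seg / max_step))
  total <- sum(k)
  out <- matrix(0, total, 2L)
  pos <- 1L
  for (i in seq_len(n)) {
    t <- (seq_len(k[i]) - 1L) / k[i]
    out[pos:(pos + k[i] - 1L), ] <- cbind(ring[i, 1L] + t * (nxt[i, 1L] - ring[i, 1L]),
                                          ring[i, 2L] + t * (nxt[i, 2L] - ring[i, 2L]))
    pos <- pos + k[i]
  }
  out
}

## ---- SliceAnnotation ---------------------------------------------------------

#' Create a slice annotation
#'
#' One reader's contours on one slice and cardiac phase. Slice index 0 is the
#' most apical acquired slice, increasing toward the base. If both `lv_endo`
#' and `lv_epi` are present, the endocardial contour must lie within the
#' epicardial one (at most 1% of the endo area may fall outside).
#'
#' @param slice_index integer position in the stack (0 = most apical).
#' @param phase_label `"ED"`, `"ES"`, or another phase name (unlabeled phases
#'   are permitted but ignored by the clinical parameter engine).
#' @param contours named list of [contour_polygon()]s keyed by structure;
#'   possibly empty when the reader segmented nothing on this slice/phase.
#' @return an object of class `slice_annotation`.
#' @export
slice_annotation <- function(slice_index, phase_label, contours = list()) {
  stopifnot(length(slice_index) == 1L, slice_index >= 0, slice_index == round(slice_index))
  stopifnot(is.character(phase_label), length(phase_label) == 1L)
  if (length(contours)) {
    if (is.null(names(contours)) || any(!names(contours) %in% STRUCTURES)) {
      stop("contours must be a named list keyed by structure label", call. = FALSE)
    }
    if (anyDuplicated(names(contours))) {
      stop("at most one contour per structure per slice/phase", call. = FALSE)
    }
    ok <- vapply(contours, inherits, logical(1), what = "contour_polygon")
    if (!all(ok)) stop("contours must be contour_polygon objects", call. = FALSE)
    check_endo_in_epi(contours, slice_index, phase_label)
  }
  structure(list(slice_index = as.integer(slice_index),
                 phase_label = phase_label,
                 contours = contours),
            class = "slice_annotation")
}

# Tolerance: endo area outside epi must stay below 1% of the endo area.
check_endo_in_epi <- function(contours, slice_index, phase_label) {
  if (is.null(contours$lv_endo) || is.null(contours$lv_epi)) return(invisible(TRUE))
  endo <- contours$lv_endo$rings[[1L]]
  epi <- contours$lv_epi$rings[[1L]]
  a_endo <- abs(ring_area_signed(endo))
  inter <- rings_intersection_area(list(endo), list(epi))
  if (a_endo - inter > 0.01 * a_endo) {
    stop(sprintf("containment violation on slice %d phase %s: lv_endo extends outside lv_epi",
                 slice_index, phase_label), call. = FALSE)
  }
  invisible(TRUE)
}

has_structure <- function(slice, structure) {
  !is.null(slice$contours[[structure]])
}

# Presence of a *derived* entity on a slice.
has_entity <- function(slice, entity) {
  switch(entity,
         lv_endo = has_structure(slice, "lv_endo"),
         rv_endo = has_structure(slice, "rv_endo"),
         lvm = has_structure(slice, "lv_epi") && has_structure(slice, "lv_endo"),
         stop("unknown entity: ", entity, call. = FALSE))
}

## ---- RegionSpec --------------------------------------------------------------

#' Build the planar region of a derived entity on a slice
#'
#' For `lv_endo` and `rv_endo` the region is the filled contour. For the
#' myocardium (`lvm`) it is the epicardial polygon minus the endocardial one
#' (an annulus: outer ring with a hole), so the myocardium is always derived
#' and never stored. Coordinates are scaled to mm using `spacing`.
#'
#' @param slice a [slice_annotation()].
#' @param entity `"lv_endo"`, `"rv_endo"` or `"lvm"`.
#' @param spacing `(row, column)` pixel spacing in mm/pixel.
#' @return an object of class `region_spec` (fields `entity`, `rings` in mm
#'   with the outer ring first, `area_mm2`, `pixel_spacing_mm`), or `NULL`
#'   when the entity is absent on the slice.
#' @export
build_region <- function(slice, entity, spacing = c(1, 1)) {
  stopifnot(inherits(slice, "slice_annotation"))
  entity <- match.arg(entity, ENTITIES)
  if (!has_entity(slice, entity)) return(NULL)
  if (entity == "lvm") {
    epi <- lapply(slice$contours$lv_epi$rings, scale_ring, spacing = spacing)
    endo <- lapply(slice$contours$lv_endo$rings, scale_ring, spacing = spacing)
    # annulus: epi outer ring + endo outer ring reversed into a hole
    endo_outer <- endo[[1L]]
    rings <- c(epi[1L], list(endo_outer[nrow(endo_outer):1L, , drop = FALSE]))
    area <- abs(ring_area_signed(epi[[1L]])) - abs(ring_area_signed(endo_outer))
  } else {
    src <- if (entity == "lv_endo") slice$contours$lv_endo else slice$contours$rv_endo
    rings <- lapply(src$rings, scale_ring, spacing = spacing)
    area <- sum(vapply(rings, ring_area_signed, numeric(1)))
  }
  structure(list(entity = entity, rings = rings,
                 area_mm2 = max(0, area),
                 pixel_spacing_mm = as.numeric(spacing)),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s: %d ring(s), area %.2f mm^2\n",
              x$entity, length(x$rings), x$area_mm2))
  invisible(x)
}

## ---- ContourStack ------------------------------------------------------------

#' Create a contour stack
#'
#' One reader's full annotation of one case: slice annotations covering a
#' rectangular slice x phase grid (a cell with no contours is an empty
#' `slice_annotation`), together with the acquisition geometry.
#'
#' @param case_id,reader_id identifying strings.
#' @param pixel_spacing_mm `(row, column)` spacing in mm/pixel, both > 0.
#' @param slice_thickness_mm slice thickness in mm (> 0).
#' @param slice_gap_mm inter-slice gap in mm (>= 0; 0 for contiguous stacks).
#' @param image_shape `(rows, columns)` of the underlying image grid.
#' @param slices list of [slice_annotation()]s; for each phase the slice
#'   indices must form a contiguous integer range.
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(case_id, reader_id, pixel_spacing_mm,
                          slice_thickness_mm, slice_gap_mm = 0,
                          image_shape = c(256L, 256L), slices = list()) {
  stopifnot(length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0),
            slice_thickness_mm > 0, slice_gap_mm >= 0)
  ok <- vapply(slices, inherits, logical(1), what = "slice_annotation")
  if (length(slices) && !all(ok)) stop("slices must be slice_annotation objects", call. = FALSE)
  st <- structure(list(case_id = as.character(case_id),
                       reader_id = as.character(reader_id),
                       pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                       slice_thickness_mm = as.numeric(slice_thickness_mm),
                       slice_gap_mm = as.numeric(slice_gap_mm),
                       image_shape = as.integer(image_shape),
                       slices = slices),
                  class = "contour_stack")
  validate_contour_stack(st)
  st
}

validate_contour_stack <- function(stack) {
  for (ph in stack_phases(stack)) {
    idx <- sort(stack_slice_indices(stack, ph))
    if (anyDuplicated(idx)) stop("duplicate slice_index within phase ", ph, call. = FALSE)
    if (length(idx) && !identical(idx, idx[1L]:idx[length(idx)])) {
      stop("slice_index values must form a contiguous range within phase ", ph, call. = FALSE)
    }
  }
  invisible(stack)
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> case %s, reader %s: %d slice cells, phases {%s}\n",
              x$case_id, x$reader_id, length(x$slices),
              paste(stack_phases(x), collapse = ", ")))
  cat(sprintf("  spacing %.3g x %.3g mm, thickness %g mm, gap %g mm\n",
              x$pixel_spacing_mm[1L], x$pixel_spacing_mm[2L],
              x$slice_thickness_mm, x$slice_gap_mm))
  invisible(x)
}

stack_phases <- function(stack) {
  unique(vapply(stack$slices, function(s) s$phase_label, character(1)))
}

stack_slice_indices <- function(stack, phase) {
  idx <- vapply(stack$slices, function(s) if (s$phase_label == phase) s$slice_index else NA_integer_,
                integer(1))
  idx[!is.na(idx)]
}

get_slice <- function(stack, slice_index, phase) {
  for (s in stack$slices) {
    if (s$slice_index == slice_index && s$phase_label == phase) return(s)
  }
  NULL
}

# Slice indices on which the reader segmented the derived entity.
segmented_indices <- function(stack, entity, phase) {
  idx <- integer(0)
  for (s in stack$slices) {
    if (s$phase_label == phase && has_entity(s, entity)) idx <- c(idx, s$slice_index)
  }
  sort(idx)
}

# Check that two stacks share the same slice/phase grid and geometry.
check_aligned <- function(a, b) {
  pa <- sort(stack_phases(a)); pb <- sort(stack_phases(b))
  if (!identical(pa, pb)) stop("alignment error: phase sets differ", call. = FALSE)
  for (ph in pa) {
    if (!identical(sort(stack_slice_indices(a, ph)), sort(stack_slice_indices(b, ph)))) {
      stop("alignment error: slice grids differ in phase ", ph, call. = FALSE)
    }
  }
  if (!isTRUE(all.equal(a$pixel_spacing_mm, b$pixel_spacing_mm)) ||
      !isTRUE(all.equal(a$slice_thickness_mm, b$slice_thickness_mm)) ||
      !isTRUE(all.equal(a$slice_gap_mm, b$slice_gap_mm))) {
    stop("alignment error: acquisition geometry differs", call. = FALSE)
  }
  invisible(TRUE)
}
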