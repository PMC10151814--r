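# Contour-stack interchange format (JSON, schema version "1") and raster mask
# import/export. The on-disk format mirrors the in-memory model: a header with
# case/reader identity and acquisition geometry plus a flat list of contour
# records. Vertices are serialized with 17 significant digits so that
# write -> read reproduces every coordinate bit-exactly.

SCHEMA_VERSION <- "1"

## ---- JSON contour stacks -----------------------------------------------------

#' Write a contour stack to a JSON file
#'
#' Output is deterministic: identical stacks produce byte-identical files
#' (stable key order, stable float formatting with 17 significant digits).
#' `slice_order` is always written as `"apex_to_base"`.
#'
#' @param stack a [contour_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour_stack <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  grid <- lapply(stack_phases(stack), function(ph) {
    idx <- stack_slice_indices(stack, ph)
    list(phase_label = ph, slice_min = min(idx), slice_max = max(idx))
  })
  records <- list()
  ord <- order(vapply(stack$slices, function(s) s$phase_label, character(1)),
               vapply(stack$slices, function(s) s$slice_index, integer(1)))
  for (s in stack$slices[ord]) {
    for (st in intersect(STRUCTURES, names(s$contours))) {
      records[[length(records) + 1L]] <- list(
        slice_index = s$slice_index,
        phase_label = s$phase_label,
        structure_label = st,
        rings = lapply(s$contours[[st]]$rings, identity))
    }
  }
  doc <- list(schema_version = SCHEMA_VERSION,
              case_id = stack$case_id,
              reader_id = stack$reader_id,
              pixel_spacing_mm = stack$pixel_spacing_mm,
              slice_thickness_mm = stack$slice_thickness_mm,
              slice_gap_mm = stack$slice_gap_mm,
              slice_order = "apex_to_base",
              image_shape = stack$image_shape,
              grid = grid,
              contours = records)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a contour stack from a JSON file
#'
#' Validates the document against the shipped schema (version "1") and
#' normalises the slice order so that index 0 is the most apical slice.
#'
#' @param path path to a file written by [write_contour_stack()] or conforming
#'   to `system.file("extdata", "contour-stack-schema.json", package = "cmrqc")`.
#' @return a [contour_stack()].
#' @export
read_contour_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("schema_version", "case_id", "reader_id", "pixel_spacing_mm",
              "slice_thickness_mm", "slice_gap_mm", "slice_order",
              "image_shape", "grid", "contours")) {
    if (is.null(doc[[f]])) stop("parse error: missing header field '", f, "'", call. = FALSE)
  }
  if (!identical(as.character(doc$schema_version), SCHEMA_VERSION)) {
    stop("parse error: unsupported schema_version ", doc$schema_version, call. = FALSE)
  }
  slice_order <- match.arg(doc$slice_order, c("apex_to_base", "base_to_apex"))
  n_top <- max(vapply(doc$grid, function(g) as.integer(g$slice_max), integer(1)))
  remap <- function(i) if (slice_order == "base_to_apex") n_top - i else i

  cells <- list()  # keyed "phase|index" -> named list of contour_polygon
  for (g in doc$grid) {
    for (i in as.integer(g$slice_min):as.integer(g$slice_max)) {
      cells[[paste(g$phase_label, remap(i), sep = "|")]] <- list()
    }
  }
  for (k in seq_along(doc$contours)) {
    rec <- doc$contours[[k]]
    loc <- sprintf("record %d (slice %s, phase %s, structure %s)",
                   k, rec$slice_index %||% "?", rec$phase_label %||% "?",
                   rec$structure_label %||% "?")
    if (is.null(rec$slice_index) || is.null(rec$phase_label) ||
        is.null(rec$structure_label) || is.null(rec$rings)) {
      stop("parse error: incomplete ", loc, call. = FALSE)
    }
    rings <- lapply(rec$rings, function(r) {
      do.call(rbind, lapply(r, function(v) as.numeric(unlist(v))))
    })
    if (any(vapply(rings, nrow, integer(1)) < 3L)) {
      stop("parse error: ring with fewer than 3 vertices in ", loc, call. = FALSE)
    }
    poly <- tryCatch(contour_polygon(rings, rec$structure_label),
                     error = function(e) stop("parse error in ", loc, ": ",
                                              conditionMessage(e), call. = FALSE))
    key <- paste(rec$phase_label, remap(as.integer(rec$slice_index)), sep = "|")
    if (is.null(cells[[key]])) cells[[key]] <- list()
    if (!is.null(cells[[key]][[rec$structure_label]])) {
      stop("parse error: duplicate structure in ", loc, call. = FALSE)
    }
    cells[[key]][[rec$structure_label]] <- poly
  }
  slices <- lapply(names(cells), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    slice_annotation(as.integer(parts[2L]), parts[1L], cells[[key]])
  })
  contour_stack(case_id = doc$case_id, reader_id = doc$reader_id,
                pixel_spacing_mm = as.numeric(unlist(doc$pixel_spacing_mm)),
                slice_thickness_mm = as.numeric(doc$slice_thickness_mm),
                slice_gap_mm = as.numeric(doc$slice_gap_mm),
                image_shape = as.integer(unlist(doc$image_shape)),
                slices = slices)
}

## ---- rasterization -----------------------------------------------------------

# Fill a set of oriented rings on an integer pixel grid. A pixel belongs to
# the region when its center is inside under even-odd counting; centers that
# fall exactly on a ring boundary count as inside.
fill_rings <- function(rings, shape) {
  out <- matrix(FALSE, shape[1L], shape[2L])
  xs <- vapply(rings, function(r) range(r[, 1L]), numeric(2))
  ys <- vapply(rings, function(r) range(r[, 2L]), numeric(2))
  c0 <- max(0L, floor(min(xs[1L, ]))); c1 <- min(shape[2L] - 1L, ceiling(max(xs[2L, ])))
  r0 <- max(0L, floor(min(ys[1L, ]))); r1 <- min(shape[1L] - 1L, ceiling(max(ys[2L, ])))
  if (c0 > c1 || r0 > r1) return(out)
  px <- rep(c0:c1, times = r1 - r0 + 1L)
  py <- rep(r0:r1, each = c1 - c0 + 1L)
  count <- integer(length(px))
  boundary <- logical(length(px))
  for (r in rings) {
    code <- sp::point.in.polygon(px, py, r[, 1L], r[, 2L])
    count <- count + (code == 1L)
    boundary <- boundary | code >= 2L
  }
  inside <- boundary | (count %% 2L == 1L)
  out[cbind(py + 1L, px + 1L)] <- inside
  out
}

#' Rasterize a slice annotation to a label mask
#'
#' Labels: 0 background, 1 LV blood pool (endo fill), 2 LV myocardium
#' (inside epi, outside endo), 3 RV blood pool. A pixel is labeled by
#' containment of its center; boundary points count as inside.
#'
#' @param slice a [slice_annotation()].
#' @param shape `(rows, columns)` of the output raster.
#' @return an integer matrix of shape `shape`.
#' @export
contours_to_mask <- function(slice, shape) {
  stopifnot(inherits(slice, "slice_annotation"), length(shape) == 2L)
  shape <- as.integer(shape)
  for (st in names(slice$contours)) {
    for (r in slice$contours[[st]]$rings) {
      if (min(r[, 1L]) < -0.5 || max(r[, 1L]) > shape[2L] - 0.5 ||
          min(r[, 2L]) < -0.5 || max(r[, 2L]) > shape[1L] - 0.5) {
        stop("out-of-bounds error: contour for ", st, " exceeds image bounds", call. = FALSE)
      }
    }
  }
  mask <- matrix(0L, shape[1L], shape[2L])
  if (has_structure(slice, "lv_epi")) {
    mask[fill_rings(slice$contours$lv_epi$rings, shape)] <- 2L
  }
  if (has_structure(slice, "lv_endo")) {
    mask[fill_rings(slice$contours$lv_endo$rings, shape)] <- 1L
  }
  if (has_structure(slice, "rv_endo")) {
    mask[fill_rings(slice$contours$rv_endo$rings, shape)] <- 3L
  }
  mask
}

## ---- vectorization -----------------------------------------------------------

# Marching-squares iso-contours of a binary map at level 0.5, returned as a
# list of subpixel rings in (x = column, y = row) pixel coordinates.
binary_to_rings <- function(bin) {
  R <- nrow(bin); C <- ncol(bin)
  pad <- matrix(0, R + 2L, C + 2L)
  pad[2:(R + 1L), 2:(C + 1L)] <- bin
  # contourLines: x indexes rows of z, y indexes columns
  cl <- grDevices::contourLines(x = -1:R, y = -1:C, z = pad, levels = 0.5)
  rings <- lapply(cl, function(l) {
    ring <- cbind(l$y, l$x)  # back to (x = column, y = row)
    n <- nrow(ring)
    if (n > 1L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    ring
  })
  rings[vapply(rings, nrow, integer(1)) >= 3L]
}

#' Vectorize a label mask to subpixel contours
#'
#' Extracts iso-contours of each label's binary map at level 0.5 (marching
#' squares with linear interpolation, so vertices are subpixel). The
#' epicardial contour is reconstructed as the boundary of the union of
#' labels 1 and 2. With `keep_largest` the connected component with the
#' largest polygon area is retained per structure — mirroring
#' largest-polygon postprocessing of automatic segmentations.
#'
#' @param mask integer matrix with labels in `{0, 1, 2, 3}` (see
#'   [contours_to_mask()] for their meaning).
#' @param slice_index,phase_label metadata for the resulting annotation.
#' @param keep_largest keep only the largest component per structure; when
#'   `FALSE`, multiple components raise an error.
#' @return a [slice_annotation()] (with no contours for an all-zero mask).
#' @export
mask_to_contours <- function(mask, slice_index = 0L, phase_label = "ED",
                             keep_largest = TRUE) {
  if (!all(mask %in% 0:3)) stop("format error: mask labels must be in {0, 1, 2, 3}", call. = FALSE)
  maps <- list(lv_endo = mask == 1L,
               lv_epi = mask == 1L | mask == 2L,
               rv_endo = mask == 3L)
  if (!any(mask == 2L)) maps$lv_epi <- NULL  # no myocardium: epi not recoverable
  contours <- list()
  for (st in names(maps)) {
    if (!any(maps[[st]])) next
    rings <- binary_to_rings(maps[[st]])
    if (!length(rings)) next
    areas <- vapply(rings, function(r) abs(ring_area_signed(r)), numeric(1))
    if (keep_largest) {
      rings <- rings[which.max(areas)]
    } else if (length(rings) > 1L) {
      stop("multiple components for ", st, " and keep_largest is FALSE", call. = FALSE)
    }
    contours[[st]] <- contour_polygon(rings, st)
  }
  slice_annotation(slice_index, phase_label, contours)
}

## ---- raster file import ------------------------------------------------------

#' Read a label mask from a PNG or NIfTI file
#'
#' PNG files are read as 8-bit label images. NIfTI files may be 2D or 3D
#' (slices stacked along the third axis); the pixel spacing is taken from the
#' header and returned as an attribute `pixel_spacing_mm`.
#'
#' @param path path to a `.png`, `.nii` or `.nii.gz` file.
#' @return for PNG, an integer label matrix; for NIfTI, a list of label
#'   matrices (one per slice) with spacing/thickness attributes.
#' @export
read_label_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) stop("the 'png' package is required", call. = FALSE)
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) stop("the 'RNifti' package is required", call. = FALSE)
    img <- RNifti::readNifti(path)
    pd <- attr(RNifti::niftiHeader(img), "pixdim") %||% RNifti::pixdim(img)
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    slices <- lapply(seq_len(dim(arr)[3L]), function(k) {
      matrix(as.integer(round(arr[, , k])), dim(arr)[1L], dim(arr)[2L])
    })
    attr(slices, "pixel_spacing_mm") <- as.numeric(RNifti::pixdim(img)[1:2])
    if (length(RNifti::pixdim(img)) >= 3L) {
      attr(slices, "slice_thickness_mm") <- as.numeric(RNifti::pixdim(img)[3L])
    }
    return(slices)
  }
  stop("unsupported mask format: ", path, call. = FALSE)
}
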