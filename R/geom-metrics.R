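# Contour-level agreement metrics between two readers. All metrics are
# computed on the polygons themselves (never on rasterized masks): Dice by
# polygon clipping in physical coordinates, Hausdorff distance on densely
# resampled boundary point sets.

#' Dice similarity coefficient of two regions, in percent
#'
#' `100 * 2|A intersect B| / (|A| + |B|)` with the intersection computed by
#' polygon clipping in physical (mm) coordinates. This is the pure geometric
#' operation: both regions must be present with positive area. The
#' segmentation-decision conventions (100 when neither reader segmented,
#' 0 when only one did) are applied at comparison level by [compare_slice()].
#'
#' @param region_a,region_b [build_region()] results for the same entity.
#' @return Dice in `[0, 100]`.
#' @export
dice <- function(region_a, region_b) {
  stopifnot(inherits(region_a, "region_spec"), inherits(region_b, "region_spec"))
  if (region_a$area_mm2 <= 0 || region_b$area_mm2 <= 0) {
    stop("degenerate geometry: Dice requires regions with positive area", call. = FALSE)
  }
  if (identical(region_a$rings, region_b$rings)) return(100)
  inter <- rings_intersection_area(region_a$rings, region_b$rings)
  100 * min(1, (2 * inter) / (region_a$area_mm2 + region_b$area_mm2))
}

#' Hausdorff distance between two region boundaries, in mm
#'
#' Symmetric Hausdorff distance
#' `max(sup_a inf_b d(a,b), sup_b inf_a d(a,b))` between the region
#' boundaries, approximated on boundary point sets densely resampled at
#' `max_step_px` pixels (converted to mm with the smaller spacing component).
#' All rings contribute: for the myocardium both the epicardial and
#' endocardial boundary form one point set. The reported value is within two
#' resampling steps of the continuous contour Hausdorff distance.
#'
#' @param region_a,region_b [build_region()] results (rings in mm).
#' @param max_step_px boundary resampling step in pixels (default 0.25).
#' @return distance in mm.
#' @export
hausdorff <- function(region_a, region_b, max_step_px = 0.25) {
  stopifnot(inherits(region_a, "region_spec"), inherits(region_b, "region_spec"),
            max_step_px > 0)
  if (identical(region_a$rings, region_b$rings)) return(0)
  step_mm <- max_step_px * min(region_a$pixel_spacing_mm %||% 1)
  pa <- do.call(rbind, lapply(region_a$rings, resample_ring, max_step = step_mm))
  pb <- do.call(rbind, lapply(region_b$rings, resample_ring, max_step = step_mm))
  max(directed_max_min(pa, pb), directed_max_min(pb, pa))
}

# sup over rows of `from` of the min distance to rows of `to`, blocked to
# bound memory for large point sets.
directed_max_min <- function(from, to, block = 2048L) {
  n <- nrow(from)
  worst <- 0
  tx <- to[, 1L]; ty <- to[, 2L]
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    dx <- outer(from[idx, 1L], tx, "-")
    dy <- outer(from[idx, 2L], ty, "-")
    d2 <- dx * dx + dy * dy
    worst <- max(worst, sqrt(max(apply(d2, 1L, min))))
  }
  worst
}

#' Per-slice volume difference for one entity
#'
#' `(area_b - area_a) * (thickness + gap) / 1000`, with a missing region
#' counting as zero area. Returns the signed and absolute difference in ml.
#'
#' @param slice_a,slice_b aligned [slice_annotation()]s (reference reader a).
#' @param entity derived entity.
#' @param stack_meta list with `pixel_spacing_mm`, `slice_thickness_mm`,
#'   `slice_gap_mm` (e.g. a [contour_stack()]).
#' @return named numeric vector `c(signed_ml, abs_ml)`.
#' @export
slice_volume_difference <- function(slice_a, slice_b, entity, stack_meta) {
  spacing <- stack_meta$pixel_spacing_mm
  step_mm <- stack_meta$slice_thickness_mm + stack_meta$slice_gap_mm
  ra <- build_region(slice_a, entity, spacing)
  rb <- build_region(slice_b, entity, spacing)
  area_a <- if (is.null(ra)) 0 else ra$area_mm2
  area_b <- if (is.null(rb)) 0 else rb$area_mm2
  signed <- (area_b - area_a) * step_mm / 1000
  c(signed_ml = signed, abs_ml = abs(signed))
}

#' Compare one slice between two readers for one entity
#'
#' Populates the per-slice record: segmentation decision (`both`, `only_a`,
#' `only_b`, `neither`), Dice under the decision conventions (computed when
#' both segmented; 100 when neither; 0 when only one), Hausdorff distance
#' (only when both segmented), areas and the signed/absolute per-slice volume
#' difference.
#'
#' @param slice_a reference reader's [slice_annotation()] (the expert).
#' @param slice_b evaluated reader's [slice_annotation()].
#' @inheritParams slice_volume_difference
#' @param max_step_px Hausdorff boundary resampling step in pixels.
#' @return a one-row tibble (a `SliceComparison` record).
#' @export
compare_slice <- function(slice_a, slice_b, entity, stack_meta, max_step_px = 0.25) {
  entity <- match.arg(entity, ENTITIES)
  if (slice_a$slice_index != slice_b$slice_index ||
      slice_a$phase_label != slice_b$phase_label) {
    stop("argument error: slices are not aligned", call. = FALSE)
  }
  spacing <- stack_meta$pixel_spacing_mm
  ra <- build_region(slice_a, entity, spacing)
  rb <- build_region(slice_b, entity, spacing)
  decision <- if (!is.null(ra) && !is.null(rb)) "both"
              else if (!is.null(ra)) "only_a"
              else if (!is.null(rb)) "only_b"
              else "neither"
  d <- switch(decision,
              both = dice(ra, rb),
              neither = 100,
              0)
  hd <- if (decision == "both") hausdorff(ra, rb, max_step_px) else NA_real_
  vd <- slice_volume_difference(slice_a, slice_b, entity, stack_meta)
  tibble::tibble(
    slice_index = slice_a$slice_index,
    phase_label = slice_a$phase_label,
    entity = entity,
    decision = decision,
    dice_pct = d,
    hausdorff_mm = hd,
    area_a_mm2 = if (is.null(ra)) 0 else ra$area_mm2,
    area_b_mm2 = if (is.null(rb)) 0 else rb$area_mm2,
    volume_diff_ml = unname(vd["signed_ml"]),
    abs_volume_diff_ml = unname(vd["abs_ml"]))
}

#' Per-slice comparison records for a reader pair
#'
#' Runs [compare_slice()] over every slice/phase/entity cell of two aligned
#' stacks and attaches slice-position labels computed against the reference
#' reader (see [classify_slice_positions()]).
#'
#' @param expert reference reader's [contour_stack()].
#' @param reader evaluated reader's [contour_stack()].
#' @param phases phases to compare (default ED and ES).
#' @param max_step_px Hausdorff boundary resampling step in pixels.
#' @return a tibble of `SliceComparison` records with a `position` column.
#' @export
compare_stacks <- function(expert, reader, phases = PHASES, max_step_px = 0.25) {
  check_aligned(expert, reader)
  phases <- intersect(phases, stack_phases(expert))
  out <- list()
  for (ph in phases) {
    for (ent in ENTITIES) {
      labels <- classify_slice_positions(expert, reader, ent, ph)
      for (i in sort(stack_slice_indices(expert, ph))) {
        sa <- get_slice(expert, i, ph)
        sb <- get_slice(reader, i, ph)
        rec <- compare_slice(sa, sb, ent, expert, max_step_px)
        rec$position <- unname(labels[as.character(i)])
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  dplyr::bind_rows(out)
}

# High-resolution rasterized Dice: the independent cross-check for the
# polygon-clipping route. Both regions are rasterized by even-odd scanline
# filling on a common fine grid spanning their joint bounding box; Dice is
# computed from pixel counts.
rasterized_dice <- function(region_a, region_b, grid = 1024L) {
  all_r <- c(region_a$rings, region_b$rings)
  xs <- range(unlist(lapply(all_r, function(r) r[, 1L])))
  ys <- range(unlist(lapply(all_r, function(r) r[, 2L])))
  pad <- 0.02 * max(diff(xs), diff(ys))
  gx <- seq(xs[1L] - pad, xs[2L] + pad, length.out = grid)
  gy <- seq(ys[1L] - pad, ys[2L] + pad, length.out = grid)
  a <- scanline_fill(region_a$rings, gx, gy)
  b <- scanline_fill(region_b$rings, gx, gy)
  100 * 2 * sum(a & b) / (sum(a) + sum(b))
}

# Even-odd scanline fill of oriented rings sampled at grid centers gx x gy.
scanline_fill <- function(rings, gx, gy) {
  nr <- length(gy); nc <- length(gx)
  cross_row <- vector("list", nr)  # crossing x positions per scan row
  for (r in rings) {
    n <- nrow(r)
    x1 <- r[, 1L]; y1 <- r[, 2L]
    x2 <- r[c(2:n, 1L), 1L]; y2 <- r[c(2:n, 1L), 2L]
    for (e in which(y1 != y2)) {
      lo <- min(y1[e], y2[e]); hi <- max(y1[e], y2[e])
      rows <- which(gy >= lo & gy < hi)  # half-open rule handles shared vertices
      if (!length(rows)) next
      t <- (gy[rows] - y1[e]) / (y2[e] - y1[e])
      xc <- x1[e] + t * (x2[e] - x1[e])
      for (j in seq_along(rows)) {
        cross_row[[rows[j]]] <- c(cross_row[[rows[j]]], xc[j])
      }
    }
  }
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    cs <- cross_row[[i]]
    if (is.null(cs)) next
    out[i, ] <- findInterval(gx, sort(cs)) %% 2L == 1L
  }
  out
}
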