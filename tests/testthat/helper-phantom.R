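# Shared fixture builders: all fixtures are generated in code.

# Regular n-gon approximating a circle, in pixel coordinates.
circle_ring <- function(cx = 100, cy = 100, r = 20, n = 256L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

circle_poly <- function(cx = 100, cy = 100, r = 20, n = 256L, structure = "lv_endo") {
  contour_polygon(circle_ring(cx, cy, r, n), structure)
}

# Stack with one lv_endo circle on each index in `seg`, on a contiguous grid.
circle_stack <- function(seg, grid = 0:9, reader_id = "expert", case_id = "c1",
                         r = 20, spacing = c(1, 1), thickness = 7,
                         phases = c("ED", "ES"), n = 64L) {
  slices <- list()
  for (ph in phases) {
    for (i in grid) {
      ctr <- if (i %in% seg) list(lv_endo = circle_poly(r = r, n = n)) else list()
      slices[[length(slices) + 1L]] <- slice_annotation(i, ph, ctr)
    }
  }
  contour_stack(case_id, reader_id, spacing, thickness, 0, c(256L, 256L), slices)
}

region_circle <- function(cx = 100, cy = 100, r = 20, n = 256L, spacing = c(1, 1)) {
  build_region(slice_annotation(0L, "ED", list(lv_endo = circle_poly(cx, cy, r, n))),
               "lv_endo", spacing)
}

# Canonical form of a stack for deep equality across serialization (slice
# cell order is not semantically meaningful).
canonical_stack <- function(stack) {
  key <- vapply(stack$slices, function(s) paste(s$phase_label, s$slice_index), character(1))
  stack$slices <- lapply(stack$slices[order(key)], function(s) {
    s$contours <- s$contours[sort(names(s$contours))]
    s
  })
  stack
}
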