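# Polygon clipping internals. Regions are lists of rings (n x 2 matrices),
# outer rings counter-clockwise, holes clockwise; intersection areas are
# computed with the Clipper library via polyclip using nonzero fill, which
# makes hole subtraction implicit in the ring orientations.

rings_to_polyclip <- function(rings) {
  lapply(rings, function(r) list(x = r[, 1L], y = r[, 2L]))
}

# Area enclosed by a set of oriented rings (outers CCW positive, holes CW
# negative under nonzero fill).
rings_area <- function(rings) {
  max(0, sum(vapply(rings, ring_area_signed, numeric(1))))
}

# Intersection area of two ring sets. Exact-equality fast path keeps
# identical-reader comparisons cheap and free of clipping degeneracies.
rings_intersection_area <- function(rings_a, rings_b) {
  if (identical(rings_a, rings_b)) return(rings_area(rings_a))
  if (!bbox_overlap(rings_a, rings_b)) return(0)
  out <- polyclip::polyclip(rings_to_polyclip(rings_a), rings_to_polyclip(rings_b),
                            op = "intersection",
                            fillA = "nonzero", fillB = "nonzero")
  if (!length(out)) return(0)
  abs(sum(vapply(out, function(p) {
    ring_area_signed(cbind(p$x, p$y))
  }, numeric(1))))
}

bbox_overlap <- function(rings_a, rings_b) {
  ra <- vapply(rings_a, function(r) c(range(r[, 1L]), range(r[, 2L])), numeric(4))
  rb <- vapply(rings_b, function(r) c(range(r[, 1L]), range(r[, 2L])), numeric(4))
  !(max(ra[2L, ]) < min(rb[1L, ]) || max(rb[2L, ]) < min(ra[1L, ]) ||
    max(ra[4L, ]) < min(rb[3L, ]) || max(rb[4L, ]) < min(ra[3L, ]))
}
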