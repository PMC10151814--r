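# Synthetic contour phantoms with analytic ground truth, plus parametric
# reader-error models emulating the failure modes of automatic cardiac
# segmentation: basal/apical segmentation-decision errors, radial over- or
# under-segmentation bias, contour displacement, fragmentation and boundary
# jitter.

#' Phantom geometry parameters
#'
#' Defines a synthetic short-axis case: left ventricular endo/epi circles
#' with an ellipsoidally tapering radius profile (apex to base), a right
#' ventricular crescent built as the clipped difference of two offset disks,
#' and a linear end-systolic contraction. Defaults model a mid-size adult
#' heart on a contiguous 7 mm stack: 10 segmented slices (plus one empty
#' grid slot at each end so that decision errors can add slices beyond the
#' anchors), 1.4 mm isotropic pixels on a 256 x 256 grid, LV endocardial
#' base radius 24 mm, 8 mm wall, contraction fractions 0.63 (LV) and 0.71
#' (RV) giving ejection fractions near 60% and 50%.
#'
#' @param n_slices number of segmented slices.
#' @param slice_thickness_mm,slice_gap_mm stack geometry (mm).
#' @param pixel_spacing_mm `(row, column)` spacing (mm/pixel).
#' @param image_shape `(rows, columns)` raster grid.
#' @param lv_endo_radius_profile per-slice LV endocardial radii in mm, most
#'   apical first; `NULL` for the ellipsoidal default taper.
#' @param lv_endo_max_radius_mm basal LV endocardial radius for the default
#'   profile.
#' @param wall_thickness_mm myocardial wall thickness (epi = endo + wall).
#' @param rv_outer_radius_mm radius of the RV disk at the base.
#' @param rv_center_offset_mm distance of the RV disk center from the LV
#'   center (along -x).
#' @param contraction_fraction named vector `c(lv = ..., rv = ...)`, the
#'   ES/ED linear scale per structure (areas scale with the square).
#' @param boundary_vertices vertex count per contour (>= 64).
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(n_slices = 10L,
                           slice_thickness_mm = 7,
                           slice_gap_mm = 0,
                           pixel_spacing_mm = c(1.4, 1.4),
                           image_shape = c(256L, 256L),
                           lv_endo_radius_profile = NULL,
                           lv_endo_max_radius_mm = 24,
                           wall_thickness_mm = 8,
                           rv_outer_radius_mm = 32,
                           rv_center_offset_mm = 40,
                           contraction_fraction = c(lv = 0.63, rv = 0.71),
                           boundary_vertices = 256L) {
  stopifnot(n_slices >= 1L, slice_thickness_mm > 0, slice_gap_mm >= 0,
            all(pixel_spacing_mm > 0), boundary_vertices >= 64L,
            all(contraction_fraction > 0), all(contraction_fraction < 1))
  if (is.null(lv_endo_radius_profile)) {
    s <- seq_len(n_slices)
    lv_endo_radius_profile <- lv_endo_max_radius_mm *
      sqrt(1 - ((n_slices - s) / n_slices)^2)
  }
  stopifnot(length(lv_endo_radius_profile) == n_slices, all(lv_endo_radius_profile > 0))
  structure(list(n_slices = as.integer(n_slices),
                 slice_thickness_mm = slice_thickness_mm,
                 slice_gap_mm = slice_gap_mm,
                 pixel_spacing_mm = pixel_spacing_mm,
                 image_shape = as.integer(image_shape),
                 lv_endo_radius_profile = lv_endo_radius_profile,
                 wall_thickness_mm = wall_thickness_mm,
                 rv_outer_radius_mm = rv_outer_radius_mm,
                 rv_center_offset_mm = rv_center_offset_mm,
                 contraction_fraction = contraction_fraction,
                 boundary_vertices = as.integer(boundary_vertices)),
            class = "phantom_params")
}

# Regular polygon approximating a circle of radius r_mm (mm) centered at
# c_mm, returned in pixel coordinates.
circle_ring_px <- function(center_mm, r_mm, n, spacing) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind((center_mm[1L] + r_mm * cos(th)) / spacing[2L],
        (center_mm[2L] + r_mm * sin(th)) / spacing[1L])
}

# RV crescent: disk at rv_center minus the LV epicardial disk, clipped with
# polyclip; returned in mm coordinates (largest resulting ring).
crescent_ring_mm <- function(rv_center, rv_r, lv_center, lv_epi_r, n) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  a <- list(list(x = rv_center[1L] + rv_r * cos(th), y = rv_center[2L] + rv_r * sin(th)))
  b <- list(list(x = lv_center[1L] + lv_epi_r * cos(th), y = lv_center[2L] + lv_epi_r * sin(th)))
  out <- polyclip::polyclip(a, b, op = "minus")
  if (!length(out)) stop("geometry error: RV crescent is empty", call. = FALSE)
  areas <- vapply(out, function(p) abs(ring_area_signed(cbind(p$x, p$y))), numeric(1))
  p <- out[[which.max(areas)]]
  cbind(p$x, p$y)
}

scale_ring_about <- function(ring, center, f) {
  cbind(center[1L] + f * (ring[, 1L] - center[1L]),
        center[2L] + f * (ring[, 2L] - center[2L]))
}

#' Generate a synthetic expert contour stack with analytic truth
#'
#' Builds circles for the LV endo- and epicardium and a crescent for the RV
#' on every segmented slice, for ED and ES (ES contours are the ED contours
#' scaled about their centroid by the contraction fraction). The returned
#' truth holds closed-form per-slice areas (shoelace for the RV crescent,
#' `pi r^2` for circles), disc-summation volumes, ejection fractions and
#' myocardial mass. Generation is deterministic.
#'
#' @param params a [phantom_params()].
#' @param case_id,reader_id identity of the generated stack.
#' @param density myocardial density (g/ml) for the truth LVM.
#' @return a list with `stack` (a [contour_stack()]) and `truth` (a
#'   `phantom_truth` list: `volumes`, `slice_areas`, `lvef_pct`, `rvef_pct`,
#'   `lvm_g`).
#' @export
generate_phantom <- function(params = phantom_params(), case_id = "phantom",
                             reader_id = "expert", density = 1.05) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  if (p$wall_thickness_mm <= 0) stop("geometry error: wall thickness must be positive", call. = FALSE)
  spacing <- p$pixel_spacing_mm
  center_mm <- c(p$image_shape[2L] / 2 * spacing[2L], p$image_shape[1L] / 2 * spacing[1L])
  rv_center <- center_mm - c(p$rv_center_offset_mm, 0)
  nv <- p$boundary_vertices
  cf <- p$contraction_fraction
  grid_idx <- 0:(p$n_slices + 1L)  # one empty slot at each end
  seg_idx <- seq_len(p$n_slices)   # slices 1 .. n_slices carry contours

  slices <- list()
  areas <- list()
  for (ph in PHASES) {
    f_lv <- if (ph == "ED") 1 else unname(cf["lv"])
    f_rv <- if (ph == "ED") 1 else unname(cf["rv"])
    for (i in grid_idx) {
      contours <- list()
      if (i %in% seg_idx) {
        r_endo <- p$lv_endo_radius_profile[i] * f_lv
        r_epi <- (p$lv_endo_radius_profile[i] + p$wall_thickness_mm) * f_lv
        contours$lv_endo <- contour_polygon(circle_ring_px(center_mm, r_endo, nv, spacing), "lv_endo")
        contours$lv_epi <- contour_polygon(circle_ring_px(center_mm, r_epi, nv, spacing), "lv_epi")
        rv_r <- p$rv_outer_radius_mm * (p$lv_endo_radius_profile[i] / max(p$lv_endo_radius_profile))
        cres <- crescent_ring_mm(rv_center, rv_r, center_mm,
                                 p$lv_endo_radius_profile[i] + p$wall_thickness_mm, nv)
        if (f_rv != 1) cres <- scale_ring_about(cres, ring_centroid(cres), f_rv)
        contours$rv_endo <- contour_polygon(
          cbind(cres[, 1L] / spacing[2L], cres[, 2L] / spacing[1L]), "rv_endo")
        areas[[length(areas) + 1L]] <- tibble::tibble(
          phase_label = ph, slice_index = i,
          lv_endo_mm2 = pi * r_endo^2,
          lvm_mm2 = pi * (r_epi^2 - r_endo^2),
          rv_endo_mm2 = abs(ring_area_signed(cres)))
      }
      slices[[length(slices) + 1L]] <- slice_annotation(i, ph, contours)
    }
  }
  stack <- contour_stack(case_id, reader_id, spacing, p$slice_thickness_mm,
                         p$slice_gap_mm, p$image_shape, slices)
  slice_areas <- dplyr::bind_rows(areas)
  step <- p$slice_thickness_mm + p$slice_gap_mm
  vol <- function(ph, col) sum(slice_areas[slice_areas$phase_label == ph, ][[col]]) * step / 1000
  volumes <- tibble::tibble(
    entity = rep(ENTITIES, each = 2L),
    phase_label = rep(PHASES, times = 3L),
    volume_ml = c(vol("ED", "lv_endo_mm2"), vol("ES", "lv_endo_mm2"),
                  vol("ED", "lvm_mm2"), vol("ES", "lvm_mm2"),
                  vol("ED", "rv_endo_mm2"), vol("ES", "rv_endo_mm2")))
  truth <- structure(list(
    volumes = volumes,
    slice_areas = slice_areas,
    lvef_pct = 100 * (1 - vol("ES", "lv_endo_mm2") / vol("ED", "lv_endo_mm2")),
    rvef_pct = 100 * (1 - vol("ES", "rv_endo_mm2") / vol("ED", "rv_endo_mm2")),
    lvm_g = vol("ED", "lvm_mm2") * density), class = "phantom_truth")
  list(stack = stack, truth = truth)
}

## ---- error models ------------------------------------------------------------

#' Define a reader-error model
#'
#' Parametric perturbations emulating automatic-segmentation failure modes:
#' \describe{
#'   \item{`radial_bias`}{move every boundary vertex radially by `delta_mm`
#'     (negative = under-segmentation).}
#'   \item{`translation`}{displace the contour by `d_mm` in direction
#'     `direction_deg`.}
#'   \item{`basal_decision`}{drop the most basal segmented slice with
#'     probability `p_drop_anchor`; add a spurious copy of it one slice
#'     further basal with probability `p_add_above`.}
#'   \item{`apical_decision`}{the mirrored rule at the apex (`p_drop`,
#'     `p_add_below`).}
#'   \item{`fragmentation`}{with probability `p`, replace the contour by a
#'     centered fragment of `fragment_area_fraction` of its area.}
#'   \item{`vertex_jitter`}{radial Gaussian noise with `sd_mm` per vertex.}
#' }
#' Models compose in the order they are supplied to [apply_error_model()].
#'
#' @param kind one of the six model kinds.
#' @param ... kind-specific parameters (see above).
#' @param structures stored structure labels the model targets.
#' @param positions `"all"` or a subset of `c("basal", "midventricular",
#'   "apical")`, resolved against the unperturbed stack's own segmented range.
#' @param phases phases the model targets.
#' @return an object of class `error_model`.
#' @export
error_model <- function(kind = c("radial_bias", "translation", "basal_decision",
                                 "apical_decision", "fragmentation", "vertex_jitter"),
                        ..., structures = "lv_endo", positions = "all",
                        phases = PHASES) {
  kind <- match.arg(kind)
  pars <- list(...)
  defaults <- switch(kind,
    radial_bias = list(delta_mm = -0.5),
    translation = list(d_mm = 5, direction_deg = 0),
    basal_decision = list(p_drop_anchor = 0, p_add_above = 0),
    apical_decision = list(p_drop = 0, p_add_below = 0),
    fragmentation = list(p = 0.1, fragment_area_fraction = 0.2),
    vertex_jitter = list(sd_mm = 0.3))
  unknown <- setdiff(names(pars), names(defaults))
  if (length(unknown)) stop("config error: unknown parameter(s) ",
                            paste(unknown, collapse = ", "), " for ", kind, call. = FALSE)
  pars <- modifyList(defaults, pars)
  probs <- unlist(pars[grepl("^p", names(pars)) & names(pars) != "direction_deg"])
  probs <- probs[names(probs) %in% c("p", "p_drop_anchor", "p_add_above", "p_drop", "p_add_below")]
  if (length(probs) && (any(probs < 0) || any(probs > 1))) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(structures %in% STRUCTURES))
  structure(c(list(kind = kind, structures = structures,
                   positions = positions, phases = phases), pars),
            class = "error_model")
}

# Slice indices a model targets for one structure/phase, resolved against the
# *unperturbed* stack (basal = most basal segmented, apical = most apical).
target_indices <- function(stack, structure, phase, positions) {
  seg <- sort(segmented_indices_structure(stack, structure, phase))
  if (!length(seg)) return(integer(0))
  if (identical(positions, "all")) return(seg)
  out <- integer(0)
  if ("basal" %in% positions) out <- c(out, max(seg))
  if ("apical" %in% positions) out <- c(out, min(seg))
  if ("midventricular" %in% positions) out <- c(out, seg[seg > min(seg) & seg < max(seg)])
  sort(unique(out))
}

segmented_indices_structure <- function(stack, structure, phase) {
  idx <- integer(0)
  for (s in stack$slices) {
    if (s$phase_label == phase && has_structure(s, structure)) idx <- c(idx, s$slice_index)
  }
  sort(idx)
}

set_contour <- function(stack, slice_index, phase, structure, poly) {
  for (j in seq_along(stack$slices)) {
    s <- stack$slices[[j]]
    if (s$slice_index == slice_index && s$phase_label == phase) {
      contours <- s$contours
      if (is.null(poly)) contours[[structure]] <- NULL else contours[[structure]] <- poly
      stack$slices[[j]] <- slice_annotation(slice_index, phase, contours)
      return(stack)
    }
  }
  stop("no grid cell at slice ", slice_index, " phase ", phase, call. = FALSE)
}

poly_area_mm2 <- function(poly, spacing) {
  if (is.null(poly)) 0 else polygon_area(poly, spacing)
}

# Perturb one contour polygon in mm space with a vertex-wise transform.
transform_poly_mm <- function(poly, spacing, f) {
  rings <- lapply(poly$rings, function(r) {
    mm <- scale_ring(r, spacing)
    mm2 <- f(mm)
    cbind(mm2[, 1L] / spacing[2L], mm2[, 2L] / spacing[1L])
  })
  contour_polygon(rings, poly$structure)
}

#' Apply reader-error models to an expert stack
#'
#' Produces a perturbed "reader" copy of the stack, deterministic given
#' `seed`, together with a bookkeeping table of every injected event: slice,
#' phase, structure, model kind, and the expected per-slice volume offset
#' (reader minus expert, in ml) implied by the contour area change.
#'
#' @param stack the unperturbed [contour_stack()].
#' @param models a single [error_model()] or a list of them (applied in
#'   order; position targeting is always resolved against the unperturbed
#'   input stack).
#' @param seed integer seed driving all stochastic model components.
#' @param reader_id identity of the perturbed stack.
#' @return a list with `stack` (the reader) and `events` (tibble).
#' @export
apply_error_model <- function(stack, models, seed = 1L, reader_id = "reader") {
  stopifnot(inherits(stack, "contour_stack"))
  if (inherits(models, "error_model")) models <- list(models)
  ok <- vapply(models, inherits, logical(1), what = "error_model")
  if (!all(ok)) stop("config error: models must be error_model objects", call. = FALSE)
  spacing <- stack$pixel_spacing_mm
  step <- stack$slice_thickness_mm + stack$slice_gap_mm
  reference <- stack  # anchors stay fixed to the unperturbed expert
  out <- stack
  out$reader_id <- as.character(reader_id)
  events <- list()
  note <- function(kind, structure, phase, slice_index, detail, dvol) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      kind = kind, structure = structure, phase_label = phase,
      slice_index = slice_index, detail = detail, expected_dvol_ml = dvol)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (m in models) {
    for (ph in intersect(m$phases, stack_phases(reference))) {
      for (st in m$structures) {
        seg <- segmented_indices_structure(reference, st, ph)
        if (m$kind %in% c("basal_decision", "apical_decision")) {
          if (!length(seg)) next
          if (m$kind == "basal_decision") {
            anchor <- max(seg); beyond <- anchor + 1L
            p_drop <- m$p_drop_anchor; p_add <- m$p_add_above
          } else {
            anchor <- min(seg); beyond <- anchor - 1L
            p_drop <- m$p_drop; p_add <- m$p_add_below
          }
          anchor_poly <- get_slice(out, anchor, ph)$contours[[st]]
          if (runif(1) < p_drop && !is.null(anchor_poly)) {
            out <- set_contour(out, anchor, ph, st, NULL)
            note(m$kind, st, ph, anchor, NA_real_, -poly_area_mm2(anchor_poly, spacing) * step / 1000)
          }
          grid <- sort(stack_slice_indices(reference, ph))
          src_poly <- get_slice(reference, anchor, ph)$contours[[st]]
          if (runif(1) < p_add && beyond %in% grid && !is.null(src_poly) &&
              is.null(get_slice(out, beyond, ph)$contours[[st]])) {
            out <- set_contour(out, beyond, ph, st, src_poly)
            note(m$kind, st, ph, beyond, NA_real_, poly_area_mm2(src_poly, spacing) * step / 1000)
          }
          next
        }
        for (i in target_indices(reference, st, ph, m$positions)) {
          poly <- get_slice(out, i, ph)$contours[[st]]
          if (is.null(poly)) next
          a0 <- polygon_area(poly, spacing)
          new_poly <- switch(m$kind,
            radial_bias = transform_poly_mm(poly, spacing, function(mm) {
              ctr <- ring_centroid(mm)
              v <- sweep(mm, 2L, ctr)
              rr <- sqrt(rowSums(v^2))
              sweep(v * pmax(0, 1 + m$delta_mm / pmax(rr, 1e-12)), 2L, ctr, "+")
            }),
            translation = {
              th <- m$direction_deg * pi / 180
              transform_poly_mm(poly, spacing, function(mm) {
                cbind(mm[, 1L] + m$d_mm * cos(th), mm[, 2L] + m$d_mm * sin(th))
              })
            },
            fragmentation = {
              if (runif(1) < m$p) {
                transform_poly_mm(poly, spacing, function(mm) {
                  scale_ring_about(mm, ring_centroid(mm), sqrt(m$fragment_area_fraction))
                })
              } else poly
            },
            vertex_jitter = transform_poly_mm(poly, spacing, function(mm) {
              ctr <- ring_centroid(mm)
              v <- sweep(mm, 2L, ctr)
              rr <- sqrt(rowSums(v^2))
              noise <- rnorm(nrow(mm), 0, m$sd_mm)
              sweep(v * (1 + noise / pmax(rr, 1e-12)), 2L, ctr, "+")
            }),
            stop("config error: unknown model kind ", m$kind, call. = FALSE))
          if (!identical(new_poly, poly)) {
            out <- set_contour(out, i, ph, st, new_poly)
            a1 <- polygon_area(new_poly, spacing)
            detail <- switch(m$kind, radial_bias = m$delta_mm, translation = m$d_mm,
                             fragmentation = m$fragment_area_fraction,
                             vertex_jitter = m$sd_mm)
            note(m$kind, st, ph, i, detail, (a1 - a0) * step / 1000)
          }
        }
      }
    }
  }
  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(kind = character(), structure = character(),
                   phase_label = character(), slice_index = integer(),
                   detail = numeric(), expected_dvol_ml = numeric())
  list(stack = out, events = events)
}

## ---- cohorts -----------------------------------------------------------------

# Stable per-case substream seed derived from the run seed and case id,
# kept below 2^31.
case_seed <- function(seed, case_id) {
  h <- sum(utf8ToInt(case_id) * seq_along(utf8ToInt(case_id)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483647)
}

#' Generate a paired synthetic cohort
#'
#' For each case, samples phantom geometry (via `params_sampler`), generates
#' the expert stack with analytic truth, and applies the error models to
#' obtain the evaluated reader's stack. Per-case randomness uses a substream
#' seed derived by stable hashing of `(seed, case_id)`, so cohorts are fully
#' reproducible.
#'
#' @param n_cases number of cases (>= 1).
#' @param params_sampler `function(case_seed)` returning a
#'   [phantom_params()]; the default varies heart size, wall thickness,
#'   slice count and contraction across cases within physiological ranges.
#' @param models list of [error_model()]s applied to every case (empty list
#'   for an identity cohort).
#' @param seed cohort seed.
#' @param outdir optional directory; when given, contour-stack JSON files
#'   and a `manifest.csv` are written there.
#' @return a list with `experts`, `readers` (lists of [contour_stack()]s),
#'   `truths` (list of `phantom_truth`), `events` (tibble over all cases)
#'   and `manifest` (tibble).
#' @export
make_cohort <- function(n_cases = 29L, params_sampler = NULL, models = list(),
                        seed = 1L, outdir = NULL) {
  stopifnot(n_cases >= 1L)
  if (is.null(params_sampler)) params_sampler <- default_params_sampler
  experts <- readers <- truths <- vector("list", n_cases)
  events <- list()
  manifest <- list()
  ids <- sprintf("case_%03d", seq_len(n_cases))
  for (j in seq_len(n_cases)) {
    cs <- case_seed(seed, ids[j])
    params <- params_sampler(cs)
    ph <- generate_phantom(params, case_id = ids[j])
    experts[[j]] <- ph$stack
    truths[[j]] <- ph$truth
    if (length(models)) {
      res <- apply_error_model(ph$stack, models, seed = cs + 1L)
      readers[[j]] <- res$stack
      if (nrow(res$events)) {
        res$events$case_id <- ids[j]
        events[[length(events) + 1L]] <- res$events
      }
    } else {
      rd <- ph$stack
      rd$reader_id <- "reader"
      readers[[j]] <- rd
    }
    manifest[[j]] <- tibble::tibble(
      case_id = ids[j], case_seed = cs, n_slices = params$n_slices,
      lv_base_radius_mm = max(params$lv_endo_radius_profile),
      wall_thickness_mm = params$wall_thickness_mm,
      truth_lvedv_ml = truths[[j]]$volumes$volume_ml[1L],
      truth_lvef_pct = truths[[j]]$lvef_pct)
  }
  events <- if (length(events)) dplyr::bind_rows(events) else NULL
  manifest <- dplyr::bind_rows(manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(n_cases)) {
      write_contour_stack(experts[[j]], file.path(outdir, paste0(ids[j], "_expert.json")))
      write_contour_stack(readers[[j]], file.path(outdir, paste0(ids[j], "_reader.json")))
    }
    write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  }
  list(experts = experts, readers = readers, truths = truths,
       events = events, manifest = manifest)
}

# Physiological variation across cases; all draws from the case substream.
default_params_sampler <- function(cs) {
  set.seed(cs)
  phantom_params(
    n_slices = sample(9:11, 1L),
    lv_endo_max_radius_mm = runif(1, 20, 27),
    wall_thickness_mm = runif(1, 7, 10),
    rv_outer_radius_mm = runif(1, 28, 34),
    contraction_fraction = c(lv = runif(1, 0.58, 0.68), rv = runif(1, 0.66, 0.76)),
    boundary_vertices = 256L)
}
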