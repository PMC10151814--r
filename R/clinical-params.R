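# Clinical function parameters by disc summation over segmented slices:
# volume = sum of slice cross-sectional areas x (thickness + gap). No partial
# basal/apical disc interpolation is applied; slices without the entity
# contribute zero.

#' Volume of a derived entity by disc summation
#'
#' @param stack a [contour_stack()].
#' @param entity `"lv_endo"`, `"rv_endo"` or `"lvm"`.
#' @param phase `"ED"` or `"ES"` (any annotated phase label is accepted).
#' @return volume in ml.
#' @export
structure_volume <- function(stack, entity, phase) {
  stopifnot(inherits(stack, "contour_stack"))
  entity <- match.arg(entity, ENTITIES)
  if (!phase %in% stack_phases(stack)) {
    stop("argument error: phase '", phase, "' is not annotated in this stack", call. = FALSE)
  }
  step_mm <- stack$slice_thickness_mm + stack$slice_gap_mm
  total_mm3 <- 0
  for (s in stack$slices) {
    if (s$phase_label != phase) next
    region <- build_region(s, entity, spacing = stack$pixel_spacing_mm)
    if (!is.null(region)) total_mm3 <- total_mm3 + region$area_mm2 * step_mm
  }
  total_mm3 / 1000
}

#' Ejection fraction in percent
#'
#' @param edv end-diastolic volume (ml), > 0.
#' @param esv end-systolic volume (ml), >= 0.
#' @return `100 * (edv - esv) / edv`.
#' @export
ejection_fraction <- function(edv, esv) {
  if (!is.finite(edv) || edv <= 0) stop("undefined EF: EDV must be positive", call. = FALSE)
  100 * (edv - esv) / edv
}

#' Left ventricular myocardial mass at end-diastole
#'
#' Myocardial volume at ED (epicardial minus endocardial disc summation)
#' times tissue density. Slices where the epicardium is drawn without an
#' endocardial contour contribute the full epicardial area (the cavity is
#' taken to vanish there, as happens apically); such slices are reported via
#' the `epi_only_slices` attribute.
#'
#' @param stack a [contour_stack()].
#' @param density myocardial tissue density in g/ml (default 1.05).
#' @return mass in grams, with attribute `epi_only_slices`.
#' @export
myocardial_mass <- function(stack, density = 1.05) {
  stopifnot(inherits(stack, "contour_stack"), density >= 0)
  if (!"ED" %in% stack_phases(stack)) {
    stop("phase error: myocardial mass requires an annotated ED phase", call. = FALSE)
  }
  step_mm <- stack$slice_thickness_mm + stack$slice_gap_mm
  total_mm3 <- 0
  epi_only <- integer(0)
  for (s in stack$slices) {
    if (s$phase_label != "ED") next
    if (has_structure(s, "lv_epi") && !has_structure(s, "lv_endo")) {
      area <- polygon_area(s$contours$lv_epi, stack$pixel_spacing_mm)
      total_mm3 <- total_mm3 + area * step_mm
      epi_only <- c(epi_only, s$slice_index)
    } else {
      region <- build_region(s, "lvm", spacing = stack$pixel_spacing_mm)
      if (!is.null(region)) total_mm3 <- total_mm3 + region$area_mm2 * step_mm
    }
  }
  mass <- total_mm3 / 1000 * density
  attr(mass, "epi_only_slices") <- epi_only
  mass
}

#' All seven clinical parameters for one case
#'
#' EDV, ESV and EF for both ventricles plus LV myocardial mass at ED,
#' computed by disc summation from a single reader's contour stack.
#'
#' @param stack a [contour_stack()] with ED and ES annotated.
#' @param density myocardial density in g/ml.
#' @return a one-row tibble with columns `case_id`, `reader_id`, `lvedv_ml`,
#'   `lvesv_ml`, `lvef_pct`, `rvedv_ml`, `rvesv_ml`, `rvef_pct`, `lvm_g`.
#' @export
clinical_summary <- function(stack, density = 1.05) {
  stopifnot(inherits(stack, "contour_stack"))
  missing_ph <- setdiff(PHASES, stack_phases(stack))
  if (length(missing_ph)) {
    stop("phase error: stack is missing phase(s) ", paste(missing_ph, collapse = ", "),
         call. = FALSE)
  }
  lvedv <- structure_volume(stack, "lv_endo", "ED")
  lvesv <- structure_volume(stack, "lv_endo", "ES")
  rvedv <- structure_volume(stack, "rv_endo", "ED")
  rvesv <- structure_volume(stack, "rv_endo", "ES")
  tibble::tibble(
    case_id = stack$case_id,
    reader_id = stack$reader_id,
    lvedv_ml = lvedv,
    lvesv_ml = lvesv,
    lvef_pct = if (lvedv > 0) ejection_fraction(lvedv, lvesv) else NA_real_,
    rvedv_ml = rvedv,
    rvesv_ml = rvesv,
    rvef_pct = if (rvedv > 0) ejection_fraction(rvedv, rvesv) else NA_real_,
    lvm_g = as.numeric(myocardial_mass(stack, density)))
}

CLINICAL_PARAMS <- c("lvedv_ml", "lvesv_ml", "lvef_pct",
                     "rvedv_ml", "rvesv_ml", "rvef_pct", "lvm_g")
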