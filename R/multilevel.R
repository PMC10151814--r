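# Multilevel error breakdown: slice-position classification anchored at the
# expert's extremal segmented slices, segmentation-decision confusion metrics,
# the two Dice averaging conventions, and position-stratified aggregation.

#' Classify slice positions for one entity and phase
#'
#' The most basal slice segmented by the expert, plus every slice above it
#' that the evaluated reader segmented (incorrectly), is `basal`; the most
#' apical expert-segmented slice plus every reader-segmented slice below it
#' is `apical`; everything strictly in between is `midventricular`. Slices
#' outside all blocks and segmented by neither reader are `unassigned` and
#' excluded from positional buckets. When the expert did not segment the
#' entity at all, every slice is `unassigned` (the reader's false-positive
#' slices are then reported in a separate unassigned bucket).
#'
#' Slice index 0 is the most apical slice, increasing toward the base.
#'
#' @param expert,reader aligned [contour_stack()]s; `expert` anchors the
#'   position blocks.
#' @param entity derived entity (`"lv_endo"`, `"lvm"`, `"rv_endo"`).
#' @param phase phase label.
#' @return a named character vector mapping slice index to position.
#' @export
classify_slice_positions <- function(expert, reader, entity, phase) {
  check_aligned(expert, reader)
  entity <- match.arg(entity, ENTITIES)
  grid <- sort(stack_slice_indices(expert, phase))
  labels <- setNames(rep("unassigned", length(grid)), as.character(grid))
  exp_idx <- segmented_indices(expert, entity, phase)
  if (!length(exp_idx)) return(labels)
  rdr_idx <- segmented_indices(reader, entity, phase)
  basal_anchor <- max(exp_idx)
  apical_anchor <- min(exp_idx)
  labels[as.character(grid[grid > apical_anchor & grid < basal_anchor])] <- "midventricular"
  labels[as.character(basal_anchor)] <- "basal"
  labels[as.character(rdr_idx[rdr_idx > basal_anchor])] <- "basal"
  labels[as.character(apical_anchor)] <- "apical"
  labels[as.character(rdr_idx[rdr_idx < apical_anchor])] <- "apical"
  labels
}

#' Segmentation-decision confusion and precision/recall
#'
#' Counts, per position bucket, the slices segmented by both readers (tp),
#' by the evaluated reader only (fp), by the expert only (fn) and by neither
#' (tn), and computes precision `tp/(tp+fp)` and recall `tp/(tp+fn)` in
#' percent. Empty denominators yield `NA`, never 0.
#'
#' @inheritParams classify_slice_positions
#' @param labels position labels from [classify_slice_positions()] for the
#'   same pair/entity/phase.
#' @return a list with `by_position` (tibble of counts and rates per
#'   position) and overall `precision_pct`, `recall_pct`.
#' @export
decision_metrics <- function(expert, reader, entity, phase, labels = NULL) {
  if (is.null(labels)) labels <- classify_slice_positions(expert, reader, entity, phase)
  grid <- as.integer(names(labels))
  exp_seg <- grid %in% segmented_indices(expert, entity, phase)
  rdr_seg <- grid %in% segmented_indices(reader, entity, phase)
  df <- tibble::tibble(position = unname(labels), expert = exp_seg, reader = rdr_seg)
  per_pos <- dplyr::summarise(
    dplyr::group_by(df, .data$position),
    tp = sum(.data$expert & .data$reader),
    fp = sum(!.data$expert & .data$reader),
    fn = sum(.data$expert & !.data$reader),
    tn = sum(!.data$expert & !.data$reader),
    .groups = "drop")
  per_pos$precision_pct <- with(per_pos, ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_))
  per_pos$recall_pct <- with(per_pos, ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_))
  tp <- sum(per_pos$tp); fp <- sum(per_pos$fp); fn <- sum(per_pos$fn)
  list(by_position = per_pos,
       precision_pct = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       recall_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_)
}

#' Average Dice under the two conventions
#'
#' `all_slices` includes the decision-convention values (100 for slices
#' segmented by neither reader, 0 for slices segmented by only one) and
#' reports the mean only — the zero values distort the distribution, so no
#' standard deviation is given. `both_only` averages the slices segmented by
#' both readers and reports mean and standard deviation.
#'
#' @param records a tibble of per-slice records from [compare_stacks()] or
#'   [compare_slice()] (one bucket).
#' @param convention `"all_slices"` or `"both_only"`.
#' @return a list with `mean`, `sd` (`NA` for `all_slices`) and `n`;
#'   `mean` is `NA` when the record set is empty.
#' @export
dice_average <- function(records, convention = c("all_slices", "both_only")) {
  convention <- match.arg(convention)
  if (convention == "both_only") records <- records[records$decision == "both", ]
  n <- nrow(records)
  if (n == 0L) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(records$dice_pct),
       sd = if (convention == "both_only" && n > 1L) sd(records$dice_pct) else NA_real_,
       n = n)
}

#' Position-stratified segmentation metrics for a reader pair
#'
#' Pools ED and ES and produces one row per entity x position (basal,
#' midventricular, apical) plus overall rows pooled across entities:
#' precision/recall of the segmentation decision, the two Dice averages,
#' Hausdorff distance and absolute per-slice volume difference (mean and sd).
#' Rows for false-positive slices that could not be anchored (expert-empty
#' structure) appear under position `"unassigned"` when present.
#'
#' @param expert,reader aligned [contour_stack()]s.
#' @param records optional precomputed [compare_stacks()] output for the pair.
#' @param max_step_px Hausdorff boundary resampling step in pixels.
#' @return a tibble (the stratified table).
#' @export
stratified_metrics <- function(expert, reader, records = NULL, max_step_px = 0.25) {
  if (is.null(records)) records <- compare_stacks(expert, reader, max_step_px = max_step_px)
  positions <- c("basal", "midventricular", "apical")
  bucket_stats <- function(recs) {
    both <- recs[recs$decision == "both", ]
    tp <- sum(recs$decision == "both")
    fp <- sum(recs$decision == "only_b")
    fn <- sum(recs$decision == "only_a")
    tibble::tibble(
      n_slices = nrow(recs),
      tp = tp, fp = fp, fn = fn,
      precision_pct = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
      recall_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      dice_all_pct = if (nrow(recs)) mean(recs$dice_pct) else NA_real_,
      dice_both_mean_pct = if (nrow(both)) mean(both$dice_pct) else NA_real_,
      dice_both_sd_pct = if (nrow(both) > 1) sd(both$dice_pct) else NA_real_,
      hd_mean_mm = if (nrow(both)) mean(both$hausdorff_mm) else NA_real_,
      hd_sd_mm = if (nrow(both) > 1) sd(both$hausdorff_mm) else NA_real_,
      abs_vol_diff_mean_ml = if (nrow(recs)) mean(recs$abs_volume_diff_ml) else NA_real_,
      abs_vol_diff_sd_ml = if (nrow(recs) > 1) sd(recs$abs_volume_diff_ml) else NA_real_)
  }
  rows <- list()
  for (ent in ENTITIES) {
    for (pos in positions) {
      recs <- records[records$entity == ent & records$position == pos, ]
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(entity = ent, position = pos), bucket_stats(recs))
    }
  }
  for (pos in positions) {
    recs <- records[records$position == pos, ]
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(entity = "overall", position = pos), bucket_stats(recs))
  }
  # unassigned false positives (expert never segmented the structure)
  un <- records[records$position == "unassigned" & records$decision != "neither", ]
  if (nrow(un)) {
    for (ent in unique(un$entity)) {
      recs <- un[un$entity == ent, ]
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(entity = ent, position = "unassigned"), bucket_stats(recs))
    }
  }
  dplyr::bind_rows(rows)
}
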