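# End-to-end comparison driver and reporting: clinical-parameter tables,
# position-stratified metric tables, per-slice records, correlation scatter,
# candlelight boxplots, Bland-Altman and equivalence figures.

#' Run the full comparison pipeline for one or more evaluated readers
#'
#' For every case: clinical parameters for the expert and each evaluated
#' reader, per-slice comparison records with position labels, and the
#' position-stratified table pooled over cases. Per reader: the clinical
#' parameter comparison (mean difference, paired t-test, Pearson r) with the
#' Fisher-z pooled correlation, and equivalence tests when tolerance
#' intervals are configured. With two or more evaluated readers, ICC(3,1)
#' is computed per parameter among the readers and among readers + expert.
#'
#' @param expert_set list of expert [contour_stack()]s, one per case.
#' @param reader_sets one evaluated reader (list of stacks) or several
#'   (named list of such lists); case IDs must match the expert set.
#' @param tolerances optional named list of `c(low, high)` tolerance
#'   intervals per parameter (names from `lvedv_ml`, `lvesv_ml`, `lvef_pct`,
#'   `rvedv_ml`, `rvesv_ml`, `rvef_pct`, `lvm_g`).
#' @param density myocardial density in g/ml.
#' @param max_step_px Hausdorff boundary resampling step in pixels.
#' @return an object of class `cmr_comparison`.
#' @export
compare_readers <- function(expert_set, reader_sets, tolerances = NULL,
                            density = 1.05, max_step_px = 0.25) {
  if (length(reader_sets) && inherits(reader_sets[[1L]], "contour_stack")) {
    reader_sets <- list(reader = reader_sets)
  }
  if (is.null(names(reader_sets)) || any(names(reader_sets) == "")) {
    names(reader_sets) <- paste0("reader_", seq_along(reader_sets))
  }
  expert_ids <- vapply(expert_set, function(s) s$case_id, character(1))
  expert_params <- dplyr::bind_rows(lapply(expert_set, clinical_summary, density = density))

  slice_records <- list(); reader_params <- list(); comparisons <- list()
  stratified <- list(); equivalence <- list()
  for (rd in names(reader_sets)) {
    stacks <- reader_sets[[rd]]
    ids <- vapply(stacks, function(s) s$case_id, character(1))
    if (!setequal(ids, expert_ids)) {
      stop("alignment error: case IDs differ for reader ", rd, ": ",
           paste(symdiff_chr(ids, expert_ids), collapse = ", "), call. = FALSE)
    }
    stacks <- stacks[match(expert_ids, ids)]
    reader_params[[rd]] <- dplyr::bind_rows(lapply(stacks, clinical_summary, density = density))
    recs <- lapply(seq_along(stacks), function(j) {
      r <- compare_stacks(expert_set[[j]], stacks[[j]], max_step_px = max_step_px)
      r$case_id <- expert_ids[j]
      r
    })
    slice_records[[rd]] <- dplyr::bind_rows(recs)
    stratified[[rd]] <- stratified_from_records(slice_records[[rd]])
    cmp <- compare_clinical(expert_params, reader_params[[rd]])
    comparisons[[rd]] <- cmp
    if (!is.null(tolerances)) {
      eq <- lapply(intersect(names(tolerances), cmp$parameter), function(p) {
        d <- reader_params[[rd]][[p]] - expert_params[[p]]
        res <- equivalence_test(d[is.finite(d)], tolerances[[p]])
        tibble::tibble(parameter = p, mean_diff = res$mean_diff,
                       ci_low = res$ci_low, ci_high = res$ci_high,
                       tol_low = res$tol_low, tol_high = res$tol_high,
                       equivalent = res$equivalent)
      })
      equivalence[[rd]] <- dplyr::bind_rows(eq)
    }
  }

  icc <- NULL
  if (length(reader_sets) >= 2L) {
    icc <- dplyr::bind_rows(lapply(CLINICAL_PARAMS, function(p) {
      grid_r <- sapply(reader_params, function(tb) tb[[p]])
      keep <- complete.cases(grid_r, expert_params[[p]])
      r1 <- icc_3_1(grid_r[keep, , drop = FALSE])
      r2 <- icc_3_1(cbind(grid_r, expert = expert_params[[p]])[keep, , drop = FALSE])
      tibble::tibble(parameter = p,
                     raters = c("readers", "readers_plus_expert"),
                     icc = c(r1$icc, r2$icc),
                     ci_low = c(r1$ci_low, r2$ci_low),
                     ci_high = c(r1$ci_high, r2$ci_high),
                     n_subjects = c(r1$n_subjects, r2$n_subjects),
                     k_raters = c(r1$k_raters, r2$k_raters))
    }))
  }

  structure(list(expert_params = expert_params,
                 reader_params = reader_params,
                 comparisons = comparisons,
                 slice_records = slice_records,
                 stratified = stratified,
                 equivalence = if (length(equivalence)) equivalence else NULL,
                 icc = icc,
                 meta = list(package_version = as.character(utils::packageVersion("cmrqc")),
                             n_cases = length(expert_set),
                             readers = names(reader_sets),
                             density_g_per_ml = density,
                             hausdorff_max_step_px = max_step_px,
                             hausdorff_lvm_rings = "epicardial and endocardial rings pooled",
                             equivalence_ci = "t-based 95% CI",
                             timestamp = NA)),
            class = "cmr_comparison")
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

# Stratified table pooled over the cases already present in the records.
stratified_from_records <- function(records) {
  stratified_metrics(expert = NULL, reader = NULL, records = records)
}

#' @export
print.cmr_comparison <- function(x, ...) {
  cat(sprintf("<cmr_comparison> %d case(s), reader(s): %s\n",
              x$meta$n_cases, paste(x$meta$readers, collapse = ", ")))
  for (rd in names(x$comparisons)) {
    rs <- x$comparisons[[rd]]$pearson_r
    rs <- rs[is.finite(rs) & abs(rs) < 1]
    pooled <- if (length(rs)) fisher_z_mean(rs) else NA_real_
    cat(sprintf("  %s: pooled correlation r_z' = %s\n", rd,
                ifelse(is.na(pooled), "n/a (degenerate)", sprintf("%.3f", pooled))))
  }
  invisible(x)
}

#' Write the report file set for a comparison result
#'
#' Emits deterministic CSV tables (clinical-parameter comparison with the
#' pooled correlation, stratified position table, overall position table,
#' per-slice records, per-case parameters, ICC and equivalence tables when
#' available), a JSON metadata sidecar, a point index mapping scatter points
#' to (case, slice, phase), and static figures: candlelight boxplots of
#' per-case parameter errors and of the two Dice conventions, the
#' position-colored correlation scatter of per-slice volume difference vs
#' Dice (decision errors fall on the Dice-0 baseline; perfect and
#' neither-segmented slices at Dice 100 with zero volume difference),
#' Bland-Altman plots, and the CI-vs-tolerance equivalence chart.
#'
#' @param result a [compare_readers()] output.
#' @param outdir output directory (created if needed).
#' @param figures write PDF figures (set `FALSE` for tables only).
#' @return the vector of written file paths, invisibly.
#' @export
build_report <- function(result, outdir, figures = TRUE) {
  stopifnot(inherits(result, "cmr_comparison"))
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("I/O error: cannot create ", outdir, call. = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }

  params_tbl <- dplyr::bind_rows(lapply(names(result$comparisons), function(rd) {
    tb <- result$comparisons[[rd]]
    tb$reader <- rd
    rs <- tb$pearson_r[is.finite(tb$pearson_r) & abs(tb$pearson_r) < 1]
    tb$pooled_r_z <- if (length(rs)) fisher_z_mean(rs) else NA_real_
    tb
  }))
  emit(params_tbl, "clinical_comparison.csv")

  strat <- dplyr::bind_rows(lapply(names(result$stratified), function(rd) {
    tb <- result$stratified[[rd]]; tb$reader <- rd; tb
  }))
  emit(strat[strat$entity != "overall", ], "stratified_by_entity.csv")
  emit(strat[strat$entity == "overall", ], "stratified_overall.csv")

  per_case <- dplyr::bind_rows(c(list(result$expert_params), result$reader_params))
  emit(per_case, "clinical_params_per_case.csv")

  slices <- dplyr::bind_rows(lapply(names(result$slice_records), function(rd) {
    tb <- result$slice_records[[rd]]; tb$reader <- rd; tb
  }))
  emit(slices, "per_slice_records.csv")
  emit(slices[, c("reader", "case_id", "slice_index", "phase_label", "entity",
                  "dice_pct", "volume_diff_ml", "position")],
       "scatter_point_index.csv")

  if (!is.null(result$icc)) emit(result$icc, "icc.csv")
  if (!is.null(result$equivalence)) {
    emit(dplyr::bind_rows(lapply(names(result$equivalence), function(rd) {
      tb <- result$equivalence[[rd]]; tb$reader <- rd; tb
    })), "equivalence.csv")
  }

  meta_path <- file.path(outdir, "run_metadata.json")
  writeLines(jsonlite::toJSON(result$meta, auto_unbox = TRUE, pretty = TRUE, null = "null"),
             meta_path)
  written <- c(written, meta_path)

  if (figures) written <- c(written, report_figures(result, outdir,
                                                    params_tbl, slices))
  invisible(written)
}

report_figures <- function(result, outdir, params_tbl, slices) {
  written <- character(0)
  save_fig <- function(plot, name, width = 8, height = 5) {
    p <- file.path(outdir, name)
    ggplot2::ggsave(p, plot, width = width, height = height)
    written <<- c(written, p)
  }

  # per-case parameter errors, candlelight-style boxplots
  err <- dplyr::bind_rows(lapply(names(result$reader_params), function(rd) {
    rp <- result$reader_params[[rd]]; ep <- result$expert_params
    dplyr::bind_rows(lapply(CLINICAL_PARAMS, function(p) {
      tibble::tibble(reader = rd, parameter = p,
                     error = rp[[p]] - ep[[p]])
    }))
  }))
  save_fig(
    ggplot2::ggplot(err, ggplot2::aes(x = .data$reader, y = .data$error)) +
      ggplot2::geom_boxplot(outlier.size = 0.7) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(y = "reader - expert", x = NULL,
                    title = "Per-case clinical parameter errors"),
    "fig_parameter_errors.pdf")

  # the two Dice conventions per reader
  dice_df <- dplyr::bind_rows(lapply(names(result$slice_records), function(rd) {
    recs <- result$slice_records[[rd]]
    recs <- recs[recs$position != "unassigned", ]
    dplyr::bind_rows(
      tibble::tibble(reader = rd, convention = "all slices", dice = recs$dice_pct),
      tibble::tibble(reader = rd, convention = "segmented by both",
                     dice = recs$dice_pct[recs$decision == "both"]))
  }))
  save_fig(
    ggplot2::ggplot(dice_df, ggplot2::aes(x = .data$reader, y = .data$dice,
                                          fill = .data$convention)) +
      ggplot2::geom_boxplot(outlier.size = 0.7) +
      ggplot2::labs(y = "Dice [%]", x = NULL, title = "Dice averaging conventions"),
    "fig_dice_conventions.pdf")

  # position-colored correlation scatter: volume difference vs Dice
  save_fig(
    ggplot2::ggplot(slices[slices$position != "unassigned", ],
                    ggplot2::aes(x = .data$volume_diff_ml, y = .data$dice_pct,
                                 colour = .data$position)) +
      ggplot2::geom_point(alpha = 0.6, size = 1) +
      ggplot2::facet_grid(reader ~ entity) +
      ggplot2::labs(x = "volume difference (reader - expert) [ml]", y = "Dice [%]",
                    title = "Per-slice correlation plot by slice position"),
    "fig_correlation_by_position.pdf", width = 9, height = 6)

  # Bland-Altman per parameter (first reader set shown per facet via colour)
  ba <- dplyr::bind_rows(lapply(names(result$reader_params), function(rd) {
    rp <- result$reader_params[[rd]]; ep <- result$expert_params
    dplyr::bind_rows(lapply(CLINICAL_PARAMS, function(p) {
      tibble::tibble(reader = rd, parameter = p,
                     mean_val = (rp[[p]] + ep[[p]]) / 2,
                     diff_val = rp[[p]] - ep[[p]])
    }))
  }))
  ba_lines <- dplyr::summarise(
    dplyr::group_by(ba, .data$reader, .data$parameter),
    bias = mean(.data$diff_val, na.rm = TRUE),
    lo = bias - 1.96 * sd(.data$diff_val, na.rm = TRUE),
    hi = bias + 1.96 * sd(.data$diff_val, na.rm = TRUE), .groups = "drop")
  save_fig(
    ggplot2::ggplot(ba, ggplot2::aes(x = .data$mean_val, y = .data$diff_val,
                                     colour = .data$reader)) +
      ggplot2::geom_point(alpha = 0.6, size = 1) +
      ggplot2::geom_hline(data = ba_lines,
                          ggplot2::aes(yintercept = .data$bias, colour = .data$reader)) +
      ggplot2::geom_hline(data = ba_lines,
                          ggplot2::aes(yintercept = .data$lo, colour = .data$reader),
                          linetype = 2) +
      ggplot2::geom_hline(data = ba_lines,
                          ggplot2::aes(yintercept = .data$hi, colour = .data$reader),
                          linetype = 2) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "mean of readers", y = "difference", title = "Bland-Altman"),
    "fig_bland_altman.pdf", width = 9, height = 6)

  if (!is.null(result$equivalence)) {
    eq <- dplyr::bind_rows(lapply(names(result$equivalence), function(rd) {
      tb <- result$equivalence[[rd]]; tb$reader <- rd; tb
    }))
    save_fig(
      ggplot2::ggplot(eq, ggplot2::aes(x = .data$parameter)) +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$tol_low, ymax = .data$tol_high),
                               width = 0.45, colour = "steelblue", linewidth = 3, alpha = 0.35) +
        ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean_diff, ymin = .data$ci_low,
                                              ymax = .data$ci_high,
                                              colour = .data$equivalent)) +
        ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red")) +
        ggplot2::facet_wrap(~reader) +
        ggplot2::coord_flip() +
        ggplot2::labs(y = "mean difference with 95% CI vs tolerance band", x = NULL,
                      title = "Equivalence testing"),
      "fig_equivalence.pdf", width = 8, height = 5)
  }
  written
}
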