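test_that("slice positions follow the expert-anchored rule (hand-enumerated fixtures)", {
  e <- circle_stack(seg = 1:8, grid = 0:9)
  r <- circle_stack(seg = 2:9, grid = 0:9, reader_id = "ai")
  lab <- classify_slice_positions(e, r, "lv_endo", "ED")
  expect_identical(names(lab)[lab == "basal"], c("8", "9"))
  expect_identical(names(lab)[lab == "apical"], "1")
  expect_identical(names(lab)[lab == "midventricular"], as.character(2:7))
  expect_identical(names(lab)[lab == "unassigned"], "0")

  e2 <- circle_stack(seg = 3:8, grid = 0:9)
  r2 <- circle_stack(seg = 1:9, grid = 0:9, reader_id = "ai")
  lab2 <- classify_slice_positions(e2, r2, "lv_endo", "ED")
  expect_identical(names(lab2)[lab2 == "basal"], c("8", "9"))
  expect_identical(names(lab2)[lab2 == "apical"], as.character(1:3))
  expect_identical(names(lab2)[lab2 == "midventricular"], as.character(4:7))
})

test_that("an expert-empty structure leaves all slices unassigned", {
  e <- circle_stack(seg = integer(0), grid = 0:5)
  r <- circle_stack(seg = 2:4, grid = 0:5, reader_id = "ai")
  lab <- classify_slice_positions(e, r, "lv_endo", "ED")
  expect_true(all(lab == "unassigned"))
})

test_that("decision metrics count tp/fp/fn per bucket and overall", {
  e <- circle_stack(seg = 1:8, grid = 0:9)
  r <- circle_stack(seg = 2:9, grid = 0:9, reader_id = "ai")
  dm <- decision_metrics(e, r, "lv_endo", "ED")
  expect_equal(sum(dm$by_position$tp), 7)
  expect_equal(sum(dm$by_position$fp), 1)
  expect_equal(sum(dm$by_position$fn), 1)
  expect_equal(dm$precision_pct, 87.5)
  expect_equal(dm$recall_pct, 87.5)
  bas <- dm$by_position[dm$by_position$position == "basal", ]
  expect_equal(c(bas$tp, bas$fp, bas$fn), c(1, 1, 0))
  api <- dm$by_position[dm$by_position$position == "apical", ]
  expect_equal(c(api$tp, api$fp, api$fn), c(0, 0, 1))

  # identical readers: perfect decision metrics
  dm2 <- decision_metrics(e, e, "lv_endo", "ED")
  expect_equal(dm2$precision_pct, 100)
  expect_equal(dm2$recall_pct, 100)

  # empty denominators yield NA, never zero
  none <- circle_stack(seg = integer(0), grid = 0:3)
  dm3 <- decision_metrics(none, none, "lv_endo", "ED")
  expect_true(is.na(dm3$precision_pct))
  expect_true(is.na(dm3$recall_pct))
})

test_that("tp + fp + fn partitions the slices segmented by either reader", {
  set.seed(5)
  for (k in 1:10) {
    e_seg <- sort(sample(0:9, sample(3:8, 1)))
    e_seg <- min(e_seg):max(e_seg)
    r_seg <- sort(sample(0:9, sample(2:9, 1)))
    e <- circle_stack(seg = e_seg, grid = 0:9)
    r <- circle_stack(seg = r_seg, grid = 0:9, reader_id = "ai")
    dm <- decision_metrics(e, r, "lv_endo", "ED")
    expect_equal(sum(dm$by_position$tp + dm$by_position$fp + dm$by_position$fn),
                 length(union(e_seg, r_seg)))
    expect_equal(sum(dm$by_position$tp + dm$by_position$fn), length(e_seg))
  }
})

test_that("swapping readers keeps the anchors with the expert argument", {
  e <- circle_stack(seg = 1:8, grid = 0:9)
  r <- circle_stack(seg = 2:9, grid = 0:9, reader_id = "ai")
  lab_er <- classify_slice_positions(e, r, "lv_endo", "ED")
  lab_re <- classify_slice_positions(r, e, "lv_endo", "ED")
  # anchored to r: basal anchor 9, apical anchor 2; e's fp slice 1 absorbed apically
  expect_identical(names(lab_re)[lab_re == "basal"], "9")
  expect_identical(names(lab_re)[lab_re == "apical"], c("1", "2"))
  expect_false(identical(lab_er, lab_re))
})

test_that("the two Dice averaging conventions behave per their definitions", {
  meta <- list(pixel_spacing_mm = c(1, 1), slice_thickness_mm = 7, slice_gap_mm = 0)
  empty <- slice_annotation(0L, "ED", list())
  seg <- slice_annotation(0L, "ED", list(lv_endo = circle_poly()))
  recs <- dplyr::bind_rows(
    compare_slice(empty, empty, "lv_endo", meta),  # neither -> 100
    compare_slice(seg, seg, "lv_endo", meta),      # identical pair -> 100
    compare_slice(seg, empty, "lv_endo", meta))    # expert-only -> 0
  all_s <- dice_average(recs, "all_slices")
  expect_equal(all_s$mean, 200 / 3, tolerance = 1e-9)
  expect_true(is.na(all_s$sd))
  both <- dice_average(recs, "both_only")
  expect_equal(both$mean, 100)
  expect_equal(both$n, 1L)

  only <- dice_average(recs[3, ], "all_slices")
  expect_equal(only$mean, 0)
  expect_true(is.na(dice_average(recs[3, ], "both_only")$mean))
  expect_true(is.na(dice_average(recs[0, ], "all_slices")$mean))

  # with no decision errors the two conventions agree
  both_recs <- recs[2, ]
  expect_equal(dice_average(both_recs, "all_slices")$mean,
               dice_average(both_recs, "both_only")$mean)
})

test_that("stratified table has the contracted rows and is perfect for identical readers", {
  e <- circle_stack(seg = 1:8, grid = 0:9)
  tbl <- stratified_metrics(e, e)
  expect_equal(nrow(tbl), 12L)  # 3 entities x 3 positions + 3 overall rows
  expect_setequal(unique(tbl$entity), c("lv_endo", "lvm", "rv_endo", "overall"))
  lv <- tbl[tbl$entity == "lv_endo", ]
  expect_true(all(lv$precision_pct == 100))
  expect_true(all(lv$recall_pct == 100))
  expect_true(all(lv$dice_all_pct == 100))
  expect_true(all(lv$hd_mean_mm == 0))
  expect_true(all(lv$abs_vol_diff_mean_ml == 0))
})

test_that("basal-only decision errors leave mid and apical rows perfect", {
  ph <- generate_phantom(phantom_params(n_slices = 6L, boundary_vertices = 64L))
  res <- apply_error_model(ph$stack,
                           error_model("basal_decision", p_drop_anchor = 1,
                                       structures = c("lv_endo", "lv_epi", "rv_endo")),
                           seed = 3)
  tbl <- stratified_metrics(ph$stack, res$stack)
  lv <- function(pos) tbl[tbl$entity == "lv_endo" & tbl$position == pos, ]
  expect_lt(lv("basal")$recall_pct, 100)
  expect_equal(lv("midventricular")$recall_pct, 100)
  expect_equal(lv("midventricular")$precision_pct, 100)
  expect_equal(lv("apical")$recall_pct, 100)
  expect_equal(lv("apical")$precision_pct, 100)
  # the basal bucket holds only the dropped anchor: all-slices Dice collapses to 0
  expect_equal(lv("basal")$dice_all_pct, 0)
  expect_true(is.na(lv("basal")$dice_both_mean_pct))
})

test_that("unassigned false positives are reported in a separate bucket", {
  e <- circle_stack(seg = integer(0), grid = 0:5)
  r <- circle_stack(seg = 2:3, grid = 0:5, reader_id = "ai")
  tbl <- stratified_metrics(e, r)
  un <- tbl[tbl$position == "unassigned", ]
  expect_equal(nrow(un), 1L)
  expect_equal(un$fp, 4L)  # 2 slices x 2 phases
  expect_equal(un$entity, "lv_endo")
})
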