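test_that("phantom truth volumes match the closed-form cylinder", {
  pp <- phantom_params(n_slices = 8L, lv_endo_radius_profile = rep(20, 8),
                       pixel_spacing_mm = c(1, 1))
  ph <- generate_phantom(pp)
  lvedv <- ph$truth$volumes$volume_ml[ph$truth$volumes$entity == "lv_endo" &
                                      ph$truth$volumes$phase_label == "ED"]
  expect_equal(lvedv, 8 * pi * 400 * 7 / 1000, tolerance = 1e-6)
})

test_that("generation is deterministic byte-for-byte after serialization", {
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_contour_stack(generate_phantom(phantom_params(n_slices = 3L))$stack, f1)
  write_contour_stack(generate_phantom(phantom_params(n_slices = 3L))$stack, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("contraction fraction controls the ejection fraction quadratically", {
  eps <- 0.2
  pp <- phantom_params(contraction_fraction = c(lv = 1 - eps, rv = 1 - eps))
  ph <- generate_phantom(pp)
  expect_equal(ph$truth$lvef_pct, 100 * (1 - (1 - eps)^2), tolerance = 0.1 / 36)
  cs <- clinical_summary(ph$stack)
  expect_equal(cs$lvef_pct, 100 * (1 - (1 - eps)^2), tolerance = 0.1 / 36)
})

test_that("truth is consistent with the measurement pipeline within 1%", {
  ph <- generate_phantom(phantom_params())
  cs <- clinical_summary(ph$stack)
  v <- function(ent, phl) ph$truth$volumes$volume_ml[ph$truth$volumes$entity == ent &
                                                     ph$truth$volumes$phase_label == phl]
  expect_equal(cs$lvedv_ml, v("lv_endo", "ED"), tolerance = 0.01)
  expect_equal(cs$lvesv_ml, v("lv_endo", "ES"), tolerance = 0.01)
  expect_equal(cs$rvedv_ml, v("rv_endo", "ED"), tolerance = 0.01)
  expect_equal(cs$lvm_g, ph$truth$lvm_g, tolerance = 0.01)
})

test_that("radial bias injects the analytic volume offset", {
  pp <- phantom_params(n_slices = 8L, lv_endo_radius_profile = rep(20, 8),
                       pixel_spacing_mm = c(1, 1))
  ph <- generate_phantom(pp)
  res <- apply_error_model(ph$stack, error_model("radial_bias", delta_mm = -0.5),
                           seed = 5)
  offset <- clinical_summary(res$stack)$lvedv_ml - clinical_summary(ph$stack)$lvedv_ml
  expect_equal(offset, -8 * pi * (400 - 19.5^2) * 7 / 1000, tolerance = 0.01)
  # bookkeeping agrees with the measured change
  booked <- sum(res$events$expected_dvol_ml[res$events$phase_label == "ED"])
  expect_equal(booked, offset, tolerance = 1e-9)
})

test_that("translation produces the designed per-slice Dice and Hausdorff", {
  pp <- phantom_params(n_slices = 3L, lv_endo_radius_profile = rep(20, 3),
                       pixel_spacing_mm = c(1, 1), boundary_vertices = 512L)
  ph <- generate_phantom(pp)
  res <- apply_error_model(ph$stack, error_model("translation", d_mm = 5,
                                                 positions = "midventricular"),
                           seed = 6)
  recs <- compare_stacks(ph$stack, res$stack, phases = "ED")
  moved <- recs[recs$entity == "lv_endo" & recs$position == "midventricular" &
                recs$decision == "both", ]
  expect_equal(nrow(moved), 1L)
  expect_equal(moved$dice_pct, 84.13, tolerance = 0.2 / 84)
  expect_equal(moved$hausdorff_mm, 5, tolerance = 0.1 / 5)
})

test_that("a forced basal decision drop removes the anchor and hurts basal recall", {
  ph <- generate_phantom(phantom_params(n_slices = 5L, boundary_vertices = 64L))
  res <- apply_error_model(ph$stack,
                           error_model("basal_decision", p_drop_anchor = 1),
                           seed = 9)
  anchor <- max(segmented_indices(ph$stack, "lv_endo", "ED"))
  expect_false(anchor %in% segmented_indices(res$stack, "lv_endo", "ED"))
  dm <- decision_metrics(ph$stack, res$stack, "lv_endo", "ED")
  bas <- dm$by_position[dm$by_position$position == "basal", ]
  expect_lt(bas$recall_pct, 100)
})

test_that("position-targeted models never touch slices outside their stratum", {
  ph <- generate_phantom(phantom_params(n_slices = 6L, boundary_vertices = 64L))
  res <- apply_error_model(ph$stack,
                           error_model("radial_bias", delta_mm = 1, positions = "basal"),
                           seed = 4)
  labels <- classify_slice_positions(ph$stack, ph$stack, "lv_endo", "ED")
  touched <- unique(res$events$slice_index)
  expect_true(all(labels[as.character(touched)] == "basal"))
  # mid/apical contours are bit-identical to the expert's
  for (i in as.integer(names(labels)[labels %in% c("midventricular", "apical")])) {
    expect_identical(get_slice(res$stack, i, "ED")$contours$lv_endo,
                     get_slice(ph$stack, i, "ED")$contours$lv_endo)
  }
})

test_that("fragmentation and jitter are stochastic but seed-reproducible", {
  ph <- generate_phantom(phantom_params(n_slices = 4L, boundary_vertices = 64L))
  models <- list(error_model("fragmentation", p = 0.5, fragment_area_fraction = 0.2),
                 error_model("vertex_jitter", sd_mm = 0.3))
  r1 <- apply_error_model(ph$stack, models, seed = 77)
  r2 <- apply_error_model(ph$stack, models, seed = 77)
  expect_identical(r1$stack, r2$stack)
  expect_identical(r1$events, r2$events)
  frag <- r1$events[r1$events$kind == "fragmentation", ]
  if (nrow(frag)) expect_true(all(frag$expected_dvol_ml < 0))
})

test_that("error_model validates its configuration", {
  expect_error(error_model("radial_bias", nonsense = 1), "unknown parameter")
  expect_error(error_model("basal_decision", p_drop_anchor = 1.5), "probabilities")
  expect_error(error_model("radial_bias", structures = "aorta"), "structures")
})

test_that("identity cohorts are perfect and biased cohorts recover the sign", {
  coh <- make_cohort(n_cases = 3, seed = 21)
  for (j in 1:3) {
    recs <- compare_stacks(coh$experts[[j]], coh$readers[[j]])
    expect_true(all(recs$dice_pct[recs$position != "unassigned"] == 100))
  }
  biased <- make_cohort(n_cases = 5,
                        models = list(error_model("radial_bias", delta_mm = -0.5)),
                        seed = 21)
  d <- vapply(1:5, function(j) {
    clinical_summary(biased$readers[[j]])$lvedv_ml -
      clinical_summary(biased$experts[[j]])$lvedv_ml
  }, numeric(1))
  expect_true(all(d < 0))
})

test_that("cohorts are reproducible and the manifest matches the truths", {
  c1 <- make_cohort(n_cases = 3, seed = 33)
  c2 <- make_cohort(n_cases = 3, seed = 33)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$experts, c2$experts)
  expect_equal(c1$manifest$truth_lvedv_ml[1],
               c1$truths[[1]]$volumes$volume_ml[1])
  # a different seed changes the geometry
  c3 <- make_cohort(n_cases = 3, seed = 34)
  expect_false(identical(c1$manifest$lv_base_radius_mm, c3$manifest$lv_base_radius_mm))
})
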