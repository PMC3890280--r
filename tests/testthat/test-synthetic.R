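test_that("condition presets carry the published group-mean retentions", {
  ctrl <- condition_preset("Control")
  expect_equal(c(ctrl$retention_type1, ctrl$retention_type2b), c(1, 1))
  p8 <- condition_preset("8I")
  expect_equal(c(p8$retention_type2b, p8$retention_type1), c(0.291, 0.201))
  p9 <- condition_preset("9I")
  expect_equal(c(p9$retention_type2b, p9$retention_type1), c(0.155, 0.095))
  p4 <- condition_preset("4I")
  expect_equal(c(p4$retention_type2b, p4$retention_type1), c(0.619, 0.588))
  expect_error(condition_preset("10I"), "Control.*4I.*9IR")
})

test_that("reperfusion presets are flagged uncalibrated and configurable", {
  p8ir <- condition_preset("8IR")
  expect_true(p8ir$uncalibrated)
  expect_equal(p8ir$retention_type1, condition_preset("9I")$retention_type1)
  p9ir <- condition_preset("9IR")
  expect_equal(p9ir$retention_type1, 0.095 / 3)
  custom <- condition_preset("8IR", retention_type1 = 0.05,
                             retention_type2b = 0.08)
  expect_equal(custom$retention_type1, 0.05)
})

test_that("spec validation enforces invariants", {
  expect_error(synthetic_section_spec(retention_type1 = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_section_spec(p_type1 = -0.1), "\\[0, 1\\]")
  expect_error(synthetic_section_spec(control_coverage = 0), "\\(0, 1\\]")
  # stain colour must satisfy, background must violate, the default predicate
  expect_error(synthetic_section_spec(stain_color_type1 = c(250, 250, 250)),
               "must satisfy")
  expect_error(synthetic_section_spec(background_color = c(100, 80, 120)),
               "must violate")
})

test_that("extreme retentions give all-or-nothing ground truth", {
  full <- generate_section(tiny_spec(retention_type1 = 1, retention_type2b = 1,
                                     control_coverage = 1))
  expect_equal(full$truth$true_total_fraction, 1)
  none <- generate_section(tiny_spec(retention_type1 = 0, retention_type2b = 0))
  expect_equal(none$truth$true_total_fraction, 0)
  expect_false(any(none$truth$stained))
})

test_that("same seed reproduces a section bit for bit; RNG state untouched", {
  spec <- tiny_spec(retention_type1 = 0.5, retention_type2b = 0.7,
                    noise_sd = 3, seed = 7)
  set.seed(123); before <- runif(3)
  a <- generate_section(spec)
  b <- generate_section(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  set.seed(123)
  expect_identical(runif(3), before)   # generator used a private RNG stream
})

test_that("ground-truth fractions are recomputable from the rasters", {
  sec <- generate_section(tiny_spec(retention_type1 = 0.3,
                                    retention_type2b = 0.6, p_type1 = 0.5,
                                    seed = 13))
  tr <- sec$truth
  fiber <- tr$labels > 0
  expect_true(all(fiber[tr$stained]))   # stained ⊆ fiber
  t1 <- fiber & matrix(tr$types[pmax(tr$labels, 1)] == "TypeI", nrow(tr$labels))
  expect_equal(tr$true_total_fraction, sum(tr$stained) / sum(fiber))
  expect_equal(tr$true_type1_fraction, sum(tr$stained & t1) / sum(t1))
  expect_equal(tr$true_type2b_fraction,
               sum(tr$stained & fiber & !t1) / sum(fiber & !t1))
})

test_that("single-type sections hit the target fraction; absent type is NA", {
  sec <- generate_section(synthetic_section_spec(
    width_px = 256, height_px = 256, n_fibers = 60, p_type1 = 1,
    retention_type1 = 0.5, retention_type2b = 0.9, control_coverage = 1,
    noise_sd = 0, illumination_gradient = 0, seed = 4))
  expect_equal(sec$truth$true_type1_fraction, 0.5, tolerance = 0.03)
  expect_true(is.na(sec$truth$true_type2b_fraction))
})

test_that("per-fiber stained fractions converge to retention x coverage", {
  # tolerance shrinks with fiber count: per-fiber error is one pixel of
  # rounding, so the mean fraction tightens as fibers (hence pixels) grow
  res <- sapply(c(15, 60), function(nf) {
    sec <- generate_section(synthetic_section_spec(
      width_px = 256, height_px = 256, n_fibers = nf, p_type1 = 0,
      retention_type2b = 0.4, control_coverage = 0.8,
      noise_sd = 0, illumination_gradient = 0, seed = 2))
    abs(sec$truth$true_total_fraction - 0.4 * 0.8)
  })
  expect_lt(res[2], 0.01)
})

test_that("increasing retention never decreases the true total fraction", {
  fracs <- sapply(c(0.1, 0.3, 0.5, 0.8, 1), function(r)
    generate_section(tiny_spec(retention_type1 = r, retention_type2b = r,
                               seed = 11))$truth$true_total_fraction)
  expect_true(all(diff(fracs) >= 0))
})

test_that("noise-free stain colours pass, background fails, the predicate", {
  sec <- generate_section(tiny_spec(retention_type1 = 0.5,
                                    retention_type2b = 0.5, seed = 3))
  pos <- segment_positive(sec$image)
  expect_identical(pos, sec$truth$stained)   # exact round trip
})

test_that("overcrowded rasters are rejected", {
  expect_error(generate_section(synthetic_section_spec(
    width_px = 24, height_px = 24, n_fibers = 60,
    interstitium_width_px = 4, seed = 1)), "n_fibers too large")
})

test_that("generate_study layout, jitter centering and determinism", {
  des <- c(Control = 3, `9I` = 3)
  ov <- list(width_px = 96, height_px = 96, n_fibers = 12,
             interstitium_width_px = 2)
  st <- generate_study(des, fields_per_animal = 2, seed = 5, overrides = ov)
  expect_equal(nrow(st$manifest), 12)
  expect_equal(length(unique(st$manifest$animal)), 6)
  # fields of one animal share its jittered retentions
  specs <- st$specs[st$manifest$animal == st$manifest$animal[1]]
  expect_equal(specs[[1]]$retention_type1, specs[[2]]$retention_type1)
  # centering: group mean of per-animal targets equals the preset exactly
  r9 <- sapply(st$specs[st$manifest$condition == "9I"],
               function(s) s$retention_type1)
  expect_equal(mean(unique(r9)), 0.095 * 0.8)
  st2 <- generate_study(des, fields_per_animal = 2, seed = 5, overrides = ov)
  expect_identical(st, st2)
  # sd = 0: every animal sits exactly on the preset
  st0 <- generate_study(des, fields_per_animal = 1, seed = 5, animal_sd = 0,
                        overrides = ov)
  r0 <- sapply(st0$specs[st0$manifest$condition == "9I"],
               function(s) s$retention_type1)
  expect_true(all(r0 == 0.095 * 0.8))
  expect_error(generate_study(c(Control = 0), seed = 1), "n_animals >= 1")
})
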