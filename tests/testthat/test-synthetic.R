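test_that("zero-gradient noiseless phantom scores a flat slope", {
  sp <- small_phantom_spec(slope_s = 0, noise_sd = 0, nucleus_density = 0,
                           glycogen_density = 0, seed = 2)
  ph <- generate_phantom(sp)
  for (a in ph$annotations[1:5]) {
    r <- score_line(sample_line(ph$image, a))
    expect_equal(r$raw_slope, 0, tolerance = 1e-9)
    expect_equal(r$normalized_slope, 0, tolerance = 1e-9)
  }
})

test_that("noiseless artifact-free phantom recovers its slope exactly", {
  sp <- small_phantom_spec(basal_B = 8405.4, slope_s = 0.37, noise_sd = 0,
                           nucleus_density = 0, glycogen_density = 0,
                           seed = 3)
  ph <- generate_phantom(sp)
  res <- score_image(ph$image, ph$annotations)
  # segment boundaries of a scored line can sit a pixel off the generator's
  # height-based thirds, so recovery is exact only to ~1e-4 relative
  expect_equal(res$raw_slope, rep(8405.4 * 0.37, nrow(res)),
               tolerance = 1e-3)
  expect_equal(res$normalized_slope, rep(0.37, nrow(res)), tolerance = 1e-3)
  expect_equal(unname(as.matrix(res[, c("m1", "m2", "m3")])),
               matrix(ph$truth$plateaus, nrow(res), 3, byrow = TRUE),
               tolerance = 1e-3)
})

test_that("the same seed reproduces the phantom bit for bit", {
  sp <- small_phantom_spec(seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$annotations, b$annotations)
  c_ <- generate_phantom(small_phantom_spec(seed = 12))
  expect_false(identical(a$image$pixels, c_$image$pixels))
})

test_that("phantoms carry at least 20 in-bounds basal-to-surface lines", {
  ph <- generate_phantom(small_phantom_spec(seed = 4))
  expect_gte(length(ph$annotations), 20)
  for (a in ph$annotations) {
    validate_annotation(a, ph$image)
    expect_gt(a$start[1], a$end[1])  # basal is the lower (higher-row) end
    n <- abs(a$start[1] - a$end[1]) + 1
    expect_gte(n, 9)
  }
})

test_that("geometry violating the minimum thickness is refused", {
  expect_error(phantom_spec(thickness = 20), ">= 30")
  expect_error(phantom_spec(nrow = 100, thickness = 90), "too small")
})

test_that("top-decile filtering recovers plateaus that raw means miss", {
  # artifacts on, noise off: dark objects drag the unfiltered means down
  # while the q = 89 filter still finds the plateau pixels
  sp <- small_phantom_spec(slope_s = 0.19, noise_sd = 0, seed = 5)
  ph <- generate_phantom(sp)
  plate <- ph$truth$plateaus
  q0 <- score_image(ph$image, ph$annotations, q = 0)
  q89 <- score_image(ph$image, ph$annotations, q = 89)
  m0 <- colMeans(as.matrix(q0[, c("m1", "m2", "m3")]))
  m89 <- colMeans(as.matrix(q89[, c("m1", "m2", "m3")]))
  expect_true(all(m0 < 0.9 * plate))
  expect_equal(unname(m89), unname(plate), tolerance = 0.01)
})

test_that("with default noise the filtered means still track the plateaus", {
  sp <- small_phantom_spec(slope_s = 0.37, seed = 6)
  ph <- generate_phantom(sp)
  res <- score_image(ph$image, ph$annotations, q = 89)
  m <- colMeans(as.matrix(res[, c("m1", "m2", "m3")]))
  expect_equal(unname(m), unname(ph$truth$plateaus), tolerance = 0.015)
})

test_that("cohort generation writes a complete, reproducible bundle", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  small_cohort("cin3_siuh", n_samples = 3, base_seed = 9, out_dir = d1)
  small_cohort("cin3_siuh", n_samples = 3, base_seed = 9, out_dir = d2)
  expect_length(list.files(d1, pattern = "\\.tif$"), 3)
  man <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 3)
  expect_equal(man$group, rep("CIN_III", 3))
  truth <- read.csv(file.path(d1, "truth.csv"))
  expect_named(truth, c("sample_id", "true_s", "true_B", "scale_c", "seed"))
  anns <- read_annotations(file.path(d1, "annotations.json"))
  expect_gte(sum(vapply(anns, `[[`, "", "image_id") == man$image_id[1]), 20)
  # determinism across runs, byte for byte
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  expect_identical(readBin(file.path(d1, paste0(man$image_id[1], ".tif")),
                           "raw", 3e6),
                   readBin(file.path(d2, paste0(man$image_id[1], ".tif")),
                           "raw", 3e6))
  expect_error(small_cohort("cin3_siuh", 3, 9, out_dir = d1), "collision")
})

test_that("small cohorts recover the preset slope within tolerance", {
  co <- small_cohort("cin1_siuh", n_samples = 5, base_seed = 21)
  sc <- score_cohort_memory(co)
  expect_lt(abs(mean(sc$samples$mean_normalized_slope) - 0.19), 0.03)
  expect_lt(abs(mean(sc$samples$mean_raw_slope) / (6021.1 * 0.19) - 1), 0.10)
})

test_that("recovered group means preserve Normal > CIN I > CIN III", {
  for (seed in c(1, 5, 17)) {
    mu <- vapply(c("normal_siuh", "cin1_siuh", "cin3_siuh"), function(p) {
      sc <- score_cohort_memory(small_cohort(p, n_samples = 4,
                                             base_seed = seed))
      mean(sc$samples$mean_normalized_slope)
    }, 0)
    expect_true(all(diff(mu) < 0))
  }
})

test_that("normalized slopes are indistinguishable across intensity scales", {
  ps <- vapply(1:12, function(seed) {
    lo <- score_cohort_memory(small_cohort("normal_siuh", 6, seed,
                                           extra = list(scale_c = 0.5)))
    hi <- score_cohort_memory(small_cohort("normal_siuh", 6, seed + 1000,
                                           extra = list(scale_c = 2)))
    compare_cohorts(lo$samples, hi$samples)$p
  }, 0)
  expect_gt(mean(ps > 0.05), 0.75)
})

test_that("unknown presets are refused, known ones carry their cohort sizes", {
  expect_error(phantom_preset("cin2_siuh"), "unknown preset")
  expect_equal(phantom_preset("normal_siuh")$n_default, 13L)
  expect_equal(phantom_preset("cin1_cornell")$n_default, 16L)
  expect_setequal(phantom_presets(),
                  c("normal_siuh", "cin1_siuh", "cin3_siuh",
                    "normal_cornell", "cin1_cornell", "cin3_cornell"))
})
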