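test_that("slide generation is a pure function of its spec", {
  spec <- slide_spec("s1", "A", base_size = c(360, 360), seed = 7)
  p1 <- generate_slide(spec, n_levels = 2)
  p2 <- generate_slide(spec, n_levels = 2)
  expect_identical(p1, p2)
  expect_equal(length(p1$levels), 2)
  expect_equal(dim(p1$levels[[1]]), c(360, 360, 3))

  # tissue region (non-white) covers >= 60% of the base image
  expect_gte(build_tissue_mask(p1$levels[[1]])$tissue_fraction, 0.6)

  ood1 <- generate_ood_slide("o1", seed = 5, base_size = c(360, 360), n_levels = 1)
  ood2 <- generate_ood_slide("o1", seed = 5, base_size = c(360, 360), n_levels = 1)
  expect_identical(ood1, ood2)

  expect_error(generate_slide(slide_spec("tiny", "A", base_size = c(200, 200))),
               "too small")
})

test_that("OOD pyramids honour the shape contract", {
  p <- generate_ood_slide("o2", seed = 3, base_size = c(1024, 1024), n_levels = 2)
  expect_equal(dim(p$levels[[1]])[1:2], c(1024, 1024))
  expect_equal(dim(p$levels[[2]])[1:2], c(512, 512))
})

test_that("classes differ in morphology, not global colour statistics", {
  # per-channel global means of class-A and class-B slides agree within
  # +/- 0.02 across seeds (ring profile is area-balanced, coverage matched)
  diffs <- sapply(1:20, function(sd) {
    a <- generate_slide(slide_spec("a", "A", base_size = c(320, 320), seed = sd),
                        n_levels = 1)
    b <- generate_slide(slide_spec("b", "B", base_size = c(320, 320), seed = sd),
                        n_levels = 1)
    apply(a$levels[[1]], 3, mean) - apply(b$levels[[1]], 3, mean)
  })
  expect_lt(max(abs(diffs)), 0.02)
})

test_that("zero blob density gives a blob-free tissue background", {
  spec <- slide_spec("flat", "A", base_size = c(360, 360),
                     blob_density = 0, seed = 2)
  p <- generate_slide(spec, n_levels = 1)
  expect_equal(oracle_blob_count(p$levels[[1]]), 0L)
})

test_that("OOD texture is blob-free where class A is blob-rich", {
  for (sd in 1:10) {
    a <- generate_slide(slide_spec("a", "A", base_size = c(480, 480), seed = sd),
                        n_levels = 1)
    o <- generate_ood_slide("o", seed = sd, base_size = c(480, 480), n_levels = 1)
    na <- oracle_blob_count(a$levels[[1]], lo = 30, hi = 3000)
    no <- oracle_blob_count(o$levels[[1]], lo = 30, hi = 3000)
    expect_gt(na - no, 0)
  }
})

test_that("stain shifts behave analytically", {
  spec <- slide_spec("s", "B", base_size = c(360, 360), seed = 11)
  pyr <- generate_slide(spec, n_levels = 2)

  # identity shift is bit-identical
  ident <- stain_shift(c(1, 1, 1), c(0, 0, 0), 0)
  expect_identical(apply_stain_shift(pyr, ident), pyr)

  # pure offset adds exactly 0.1 to every non-saturated pixel
  off <- apply_stain_shift(pyr, stain_shift(c(1, 1, 1), c(0.1, 0.1, 0.1), 0))
  sat <- pyr$levels[[1]] > 0.9
  expect_equal(off$levels[[1]][!sat], pyr$levels[[1]][!sat] + 0.1)
  expect_true(all(off$levels[[1]] <= 1))

  # gains scale channel means exactly on a constant-grey slide
  grey <- build_pyramid(array(0.5, c(64, 64, 3)), 1, slide_id = "grey")
  g <- c(1.2, 0.9, 1.0)
  shifted <- apply_stain_shift(grey, stain_shift(g, c(0, 0, 0), 0))
  expect_equal(apply(shifted$levels[[1]], 3, mean), 0.5 * g)

  # dimensions never change; invalid gains are rejected
  blur <- apply_stain_shift(pyr, stain_shift(blur_sigma = 2))
  expect_equal(lapply(blur$levels, dim), lapply(pyr$levels, dim))
  expect_error(stain_shift(c(0, 1, 1)), "positive")
})

test_that("the default stain shift preserves labels and the tissue partition", {
  spec <- slide_spec("s", "A", base_size = c(640, 640), seed = 4)
  pyr <- generate_slide(spec, n_levels = 1)
  shifted <- apply_stain_shift(pyr, stain_shift())
  f0 <- build_tissue_mask(pyr$levels[[1]])$tissue_fraction
  f1 <- build_tissue_mask(shifted$levels[[1]])$tissue_fraction
  expect_lt(abs(f1 - f0) / f0, 0.01)
})

test_that("cohort generation writes a well-formed, reproducible cohort", {
  d0 <- withr::local_tempdir()

  # empty cohort: header-only manifest
  m0 <- generate_cohort(0, seed = 1, out_dir = file.path(d0, "empty"),
                        base_size = c(360, 360), n_levels = 1)
  expect_equal(nrow(m0), 0)
  expect_equal(readLines(file.path(d0, "empty", "manifest.csv")),
               "slide_id,class_label,centre,split,path")

  # 8 per class at the 50/25/25 split -> 4 train, 2 val, 2 test per class
  m8 <- generate_cohort(8, seed = 9, out_dir = file.path(d0, "c8"),
                        base_size = c(360, 360), n_levels = 1)
  counts <- table(m8$class_label, m8$split)
  expect_equal(unname(counts["A", c("train", "val", "test")]), c(4, 2, 2))
  expect_equal(unname(counts["B", c("train", "val", "test")]), c(4, 2, 2))
  expect_true(all(file.exists(file.path(d0, "c8", m8$path, "level_0.ppm"))))

  # same seed twice -> byte-identical manifest
  generate_cohort(8, seed = 9, out_dir = file.path(d0, "c8b"),
                  base_size = c(360, 360), n_levels = 1)
  expect_identical(readLines(file.path(d0, "c8", "manifest.csv")),
                   readLines(file.path(d0, "c8b", "manifest.csv")))
})

test_that("cohort_specs is the plan generate_cohort executes", {
  specs <- cohort_specs(4, seed = 3, ring_fraction_sd = 0.2,
                        external_test_per_class = 1, n_ood = 2)
  expect_equal(nrow(specs), 4 * 2 + 2 + 2)
  expect_false(any(duplicated(specs$slide_id)))
  expect_true(all(specs$split[specs$centre == "external"] == "test"))
  expect_true(all(specs$ring_fraction >= 0 & specs$ring_fraction <= 1))
  # spread pulls per-slide fractions away from the class centres
  expect_gt(stats::sd(specs$ring_fraction[specs$class_label == "A"]), 0)
})

test_that("ring contrast acts as a separability dial", {
  # a fixed pre-trained classifier scores fixed small cohorts rendered at
  # increasing ring contrast: AUC must be non-decreasing
  model <- world_clean(1)$model
  auc_at <- function(contrast) {
    dg <- lapply(1:6, function(i) {
      cl <- if (i <= 3) "A" else "B"
      spec <- slide_spec(paste0("dial", i), cl, base_size = c(640, 640),
                         ring_contrast = contrast, seed = 900 + i)
      pyr <- quantize_levels(generate_slide(spec, n_levels = 1))
      ps <- extract_patches(pyr, 0, max_patches = 4, seed = 1)
      mean(predict_deterministic(model, ps)[, 1])
    })
    roc_auc(unlist(dg), rep(c("A", "B"), each = 3))$auc
  }
  aucs <- vapply(c(0.1, 0.6, 1.0), auc_at, 0)
  expect_true(all(diff(aucs) >= 0))
})
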