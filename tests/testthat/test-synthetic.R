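# Synthetic scene generator and the fixture/loader round trip.

test_that("scenes are reproducible and respect the lesion-count contract", {
  sp <- scene_spec(image_size = 96L)
  s1 <- sample_polyp_scene(sp, seed = 42)
  s2 <- sample_polyp_scene(sp, seed = 42)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_polyp_scene(sp, seed = 43)))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  expect_true(all(s1$mask %in% c(0, 1)))
  empty <- sample_polyp_scene(scene_spec(image_size = 96L, n_lesions = 0L),
                              seed = 1)
  expect_equal(sum(empty$mask), 0)
  two <- sample_polyp_scene(scene_spec(image_size = 128L, n_lesions = 2L,
                                       area_frac_range = c(0.01, 0.03)),
                            seed = 3)
  expect_gt(sum(two$mask), 0)
  expect_error(sample_polyp_scene(scene_spec(image_size = 64L,
                                             area_frac_range = c(0.9, 0.95)),
                                  seed = 1),
               "fit")
})

test_that("realised lesion area tracks the requested fraction", {
  # oracle: count mask pixels over many seeds at a pinned 1% request
  sp <- scene_spec(area_frac_range = c(0.01, 0.01))
  fr <- vapply(1:40, function(s) mean(sample_polyp_scene(sp, seed = s)$mask),
               numeric(1))
  expect_true(all(fr > 0.005 & fr < 0.02))
})

test_that("generated contrast reaches the low-contrast regime", {
  sp <- scene_spec(image_size = 96L)
  deltas <- vapply(1:30, function(s) {
    sc <- sample_polyp_scene(sp, seed = s)
    lum <- apply(sc$image, c(2, 3), mean)
    abs(mean(lum[sc$mask == 1]) - mean(lum[sc$mask == 0]))
  }, numeric(1))
  expect_true(any(deltas < 0.05))    # hard low-contrast cases exist
  expect_true(any(deltas > 0.10))    # alongside easy ones
})

test_that("fixture sets round-trip losslessly and regenerate identically", {
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  unlink(c(d1, d2), recursive = TRUE)
  sp <- scene_spec(image_size = 64L)
  build_fixture_set(8, sp, d1, master_seed = 7)
  build_fixture_set(8, sp, d2, master_seed = 7)
  f1 <- list.files(d1, recursive = TRUE)
  expect_length(grep("images/", f1), 8)
  expect_length(grep("masks/", f1), 8)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
  ds <- load_seg_folder(d1, image_size = 64L)
  expect_equal(dim(ds$images), c(8, 3, 64, 64))
  expect_equal(dim(ds$masks), c(8, 1, 64, 64))
  expect_true(all(ds$masks %in% c(0, 1)))
  # masks survive the PNG round trip exactly at native resolution
  sc <- sample_polyp_scene(sp, seed = 7 + 1)
  expect_equal(ds$masks[1, 1, , ], sc$mask)
})

test_that("the loader resizes external folders to the working resolution", {
  d <- file.path(tempdir(), "fix3")
  unlink(d, recursive = TRUE)
  build_fixture_set(2, scene_spec(image_size = 96L), d, master_seed = 1)
  ds <- load_seg_folder(d, image_size = 64L)
  expect_equal(dim(ds$images), c(2, 3, 64, 64))
  expect_true(all(ds$masks %in% c(0, 1)))
  expect_error(load_seg_folder(file.path(tempdir(), "nope")), "no images")
})
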