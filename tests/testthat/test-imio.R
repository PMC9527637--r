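test_that("label volumes round-trip through TIFF bit-identically", {
  lab <- label_volume(array(sample(0:3, 4 * 32 * 32, TRUE), c(4, 32, 32)),
                      voxel_size_um = c(0.05, 0.02, 0.02))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(lab, path)
  back <- read_volume(path)
  expect_s3_class(back, "LabelVolume")
  expect_identical(back$data, lab$data)
  expect_equal(back$voxel_size_um, lab$voxel_size_um)
})

test_that("intensity volumes round-trip with float precision and page count", {
  vol <- intensity_volume(array(runif(5 * 16 * 16), c(5, 16, 16)),
                          voxel_size_um = 0.01)
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_s3_class(back, "IntensityVolume")
  expect_identical(dim(back$data)[1], 5L)  # one page per slice
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_error(read_volume(tempfile()), "not found")
})

test_that("patch extraction respects footprint capacity and non-overlap", {
  ## a single 2922 x 1166 slice holds at most 10 disjoint 512px squares,
  ## so a 30-patch request must fail
  big <- array(0, c(1, 2922, 1166))
  expect_error(extract_patches(big, 512, 30), "capacity is 10")
  expect_silent(fp10 <- extract_patches(big, 512, 10, seed = 1))
  expect_identical(nrow(fp10), 10L)
  ## whole-slice request returns the full footprint
  one <- extract_patches(array(0, c(1, 64, 64)), 64, 1)
  expect_identical(c(one$slice, one$y, one$x), c(1L, 1L, 1L))
  ## non-overlap within slices, checked by interval arithmetic
  ph <- generate_phantom(training_phantom_config(3, c(10L, 160L, 160L), mito_count = 0L))
  fp <- extract_patches(ph$intensity, 64, 30, seed = 7)
  expect_identical(nrow(fp), 30L)
  ps <- attr(fp, "patch_size")
  for (z in unique(fp$slice)) {
    sub <- fp[fp$slice == z, ]
    if (nrow(sub) < 2) next
    for (i in 1:(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
      expect_true(abs(sub$y[i] - sub$y[j]) >= ps ||
                    abs(sub$x[i] - sub$x[j]) >= ps)
    }
  }
  ## reproducible under the seed
  expect_identical(fp, extract_patches(ph$intensity, 64, 30, seed = 7))
  ## cropping returns matching intensity/label patches
  smp <- crop_patch(ph$labels, fp[1, , drop = FALSE], ps)
  expect_identical(dim(smp), c(64L, 64L))
})

test_that("splits partition the ids with exact counts across folds", {
  sp <- make_split(1:30, c(20, 5, 5), n_folds = 1, seed = 0)[[1]]
  expect_length(sp$train, 20)
  expect_length(sp$val, 5)
  expect_length(sp$test, 5)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:30)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  ## degenerate split: everything in train
  sp0 <- make_split(1:30, c(30, 0, 0))[[1]]
  expect_length(sp0$val, 0)
  expect_length(sp0$test, 0)
  ## repeat call with same seed is identical
  expect_identical(make_split(1:30, c(20, 5, 5), 2, seed = 4),
                   make_split(1:30, c(20, 5, 5), 2, seed = 4))
  ## validation folds are disjoint while k * val <= n
  folds <- make_split(1:30, c(20, 5, 5), n_folds = 6, seed = 1)
  vals <- lapply(folds, `[[`, "val")
  expect_length(unique(unlist(vals)), 30)
  for (f in folds) {
    expect_length(f$train, 20)
    expect_setequal(c(f$train, f$val, f$test), 1:30)
  }
  expect_error(make_split(1:30, c(20, 5, 4)), "sum")
})

test_that("slice-pair records are consecutive, one-hot and in stack order", {
  st <- translate_slice_sequence(make_disc(10, 20, 20, 48), 5, 1)
  recs <- build_slice_pair_records(st)
  expect_length(recs, 4)
  for (i in seq_along(recs)) {
    expect_length(recs[[i]]$pair_label, 4)
    expect_identical(sum(recs[[i]]$pair_label != 0), 1L)
    expect_identical(which(recs[[i]]$pair_label == 1), i)
    expect_identical(recs[[i]]$slice_a, st[[i]])
    expect_identical(recs[[i]]$slice_b, st[[i + 1]])
  }
  ## record i's second slice is record i+1's first slice
  for (i in 1:3) expect_identical(recs[[i]]$slice_b, recs[[i + 1]]$slice_a)
  expect_length(build_slice_pair_records(st[1:2]), 1)
  expect_error(build_slice_pair_records(slice_stack(st[1])), "at least 2")
  ## pairs spanning a missing slice are dropped with a warning
  st2 <- slice_stack(list(st[[1]], st[[2]], NULL, st[[4]], st[[5]]))
  expect_warning(r2 <- build_slice_pair_records(st2), "dropped")
  expect_length(r2, 2)
})
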