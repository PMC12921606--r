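test_that("extended maxima honor the prominence criterion", {
  # background 10, bumps peaking at 110 and 40: prominences 100 and 30
  px <- matrix(10, 30, 30)
  px[10, 10] <- 110; px[9:11, 9:11][px[9:11, 9:11] == 10] <- 60
  px[22, 22] <- 40
  im <- calibrated_image(px, 1, "t")
  rng <- max(px) - min(px)  # 100
  lab_h50 <- extended_maxima(im, 50 / rng)
  expect_equal(max(lab_h50), 1L)
  expect_true(lab_h50[10, 10] > 0)
  lab_h15 <- extended_maxima(im, 15 / rng)
  expect_equal(max(lab_h15), 2L)
  expect_true(lab_h15[22, 22] > 0)
})

test_that("flat images and whole-image components yield no maxima", {
  flat <- calibrated_image(matrix(9, 12, 12), 1, "t")
  expect_equal(max(extended_maxima(flat, 0.5)), 0L)
  # at dynamic 1, h equals the range: even the global maximum is flattened
  # to the background level and the resulting whole-image plateau is
  # discarded as non-localized
  px <- matrix(0, 15, 15); px[8, 8] <- 100; px[2, 2] <- 120
  im <- calibrated_image(px, 1, "t")
  expect_equal(max(extended_maxima(im, 1)), 0L)
})

test_that("extended maxima match the flood-based prominence oracle", {
  set.seed(42)
  for (i in 1:6) {
    nb <- sample(1:5, 1)
    bumps <- lapply(seq_len(nb), function(j)
      c(sample(8:40, 1), sample(8:40, 1), sample(30:200, 1),
        runif(1, 1.5, 3)))
    im <- bump_image(48, 48, bumps, bg = sample(5:20, 1))
    im$pixels <- im$pixels + round(matrix(2 * sin(1:48), 48, 48))  # ripple
    for (dyn in c(0.05, 0.15, 0.4)) {
      got <- canonical_components(extended_maxima(im, dyn))
      want <- oracle_emax_components(im$pixels, dyn)
      expect_identical(got, want)
    }
  }
})

test_that("component count is non-increasing in the dynamic", {
  set.seed(5)
  for (i in 1:5) {
    bumps <- lapply(1:4, function(j)
      c(sample(6:42, 1), sample(6:42, 1), sample(20:250, 1), runif(1, 1, 3)))
    im <- bump_image(48, 48, bumps, bg = 10)
    counts <- vapply(c(0.01, 0.05, 0.15, 0.4, 0.9), function(d)
      max(extended_maxima(im, d)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detection is invariant to adding a constant to all intensities", {
  im <- bump_image(40, 40, list(c(12, 12, 120, 2), c(30, 28, 60, 2)),
                   bg = 15)
  im2 <- calibrated_image(im$pixels + 500, 1, "t", bit_depth = 16L)
  expect_identical(extended_maxima(im, 0.1), extended_maxima(im2, 0.1))
})

test_that("objects straddling or inside the mask are dropped entirely", {
  im <- bump_image(40, 40, list(c(10, 10, 150, 2),   # inside mask
                                c(10, 30, 150, 2),   # straddles mask edge
                                c(32, 20, 150, 2)),  # outside
                   bg = 10)
  g <- matrix(FALSE, 40, 40); g[1:16, 1:31] <- TRUE
  m <- mask_from_grid(g)
  lab <- extended_maxima(im, 0.2)
  expect_equal(max(lab), 3L)
  objs <- objects_outside_mask(lab, m)
  expect_length(objs, 1L)
  ctr <- colMeans(objs[[1]]$pixels)
  expect_equal(unname(ctr), c(32, 20), tolerance = 0.1)
  # all inside -> empty
  expect_length(objects_outside_mask(lab, mask_from_grid(matrix(TRUE, 40, 40))),
                0L)
})

test_that("artifact exclusion equals brute-force disk containment", {
  set.seed(9)
  for (i in 1:25) {
    pix <- random_blob(30, 30, sample(20:120, 1))
    for (r in c(2L, 4L, 6L)) {
      ob <- spheroidquant:::new_detected_object(1L, pix)
      got <- exclude_artifacts(list(ob), artifact_radius_um = r,
                               pixel_size_um = 1)[[1]]$excluded_as_artifact
      expect_identical(got, oracle_contains_disk(pix, r))
    }
  }
})

test_that("artifact rule behaves at the extremes", {
  single <- spheroidquant:::new_detected_object(1L, cbind(5L, 5L))
  expect_false(exclude_artifacts(list(single), 5, 1)[[1]]$excluded_as_artifact)
  # filled disk r=10 contains a disk r=5
  g <- matrix(FALSE, 25, 25)
  g[(row(g) - 13)^2 + (col(g) - 13)^2 <= 100] <- TRUE
  diskobj <- spheroidquant:::new_detected_object(1L, which(g, arr.ind = TRUE))
  expect_true(exclude_artifacts(list(diskobj), 5, 1)[[1]]$excluded_as_artifact)
  # a 3 x 50 bar cannot contain it
  bar <- as.matrix(expand.grid(row = 10:12, col = 1:50))
  barobj <- spheroidquant:::new_detected_object(1L, bar)
  expect_false(exclude_artifacts(list(barobj), 5, 1)[[1]]$excluded_as_artifact)
  # radius 0 disables exclusion
  expect_false(exclude_artifacts(list(diskobj), 0, 1)[[1]]$excluded_as_artifact)
})

test_that("detect_objects composes the stages deterministically", {
  fx <- fixture_cached("disintegrating_invasion")
  masks <- build_masks(fx$dataset, mode = "disintegrating")
  p <- emax_params(0.001)
  o1 <- detect_objects(fx$dataset$followups[[1]], masks[[2]], p)
  o2 <- detect_objects(fx$dataset$followups[[1]], masks[[2]], p)
  expect_identical(objects_to_df(o1), objects_to_df(o2))
  expect_gt(length(o1), 0L)
  # no object pixel may fall inside the mask
  for (ob in o1) expect_false(any(masks[[2]]$grid[ob$pixels]))
})

test_that("emax_params validates its ranges", {
  expect_error(emax_params(0), "\\(0, 1\\]")
  expect_error(emax_params(1.5), "\\(0, 1\\]")
  expect_error(emax_params(0.001, -1), ">= 0")
})
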