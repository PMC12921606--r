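test_that("smoothing removes thin spikes but preserves bulk geometry", {
  n <- 261L
  g <- matrix(FALSE, n, n)
  d2 <- (row(g) - 131)^2 + (col(g) - 131)^2
  g[d2 <= 100^2] <- TRUE
  disk <- mask_from_grid(g, pixel_size_um = 1)
  sm <- smooth_mask(disk, detail_um = 15)
  expect_lt(abs(sm$area_px - disk$area_px) / disk$area_px, 0.01)

  spiked <- g
  spiked[130:131, 232:261] <- TRUE  # 2 px wide, 30 px long spike
  smsp <- smooth_mask(mask_from_grid(spiked, 1), detail_um = 15)
  expect_false(any(smsp$grid[130:131, 240:261]))
  p_disk <- mask_perimeter(smooth_mask(disk, 15))
  p_spk <- mask_perimeter(smsp)
  expect_lt(abs(p_spk - p_disk) / p_disk, 0.02)

  # idempotence, and empty masks pass through
  expect_identical(smooth_mask(sm, 15)$grid, sm$grid)
  empty <- mask_from_grid(matrix(FALSE, 8, 8))
  expect_identical(smooth_mask(empty, 15)$grid, empty$grid)
})

test_that("traced perimeter follows the axial/diagonal step convention", {
  g <- matrix(FALSE, 60, 60); g[6:55, 6:55] <- TRUE
  expect_equal(mask_perimeter(mask_from_grid(g, 1)), 4 * 49)
  # calibration scales lengths
  expect_equal(mask_perimeter(mask_from_grid(g, 2.5)), 4 * 49 * 2.5)

  d <- matrix(FALSE, 120, 120)
  d[(row(d) - 60)^2 + (col(d) - 60)^2 <= 50^2] <- TRUE
  p <- mask_perimeter(mask_from_grid(d, 1))
  expect_lt(abs(p - 2 * pi * 50) / (2 * pi * 50), 0.05)

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(mask_perimeter(mask_from_grid(one, 1)), 0)
  expect_warning(p0 <- mask_perimeter(mask_from_grid(matrix(FALSE, 4, 4))),
                 "empty")
  expect_equal(p0, 0)
  # two components sum their perimeters
  g2 <- matrix(FALSE, 30, 30)
  g2[2:11, 2:11] <- TRUE; g2[15:24, 15:24] <- TRUE
  expect_equal(mask_perimeter(mask_from_grid(g2, 1)), 2 * 4 * 9)
  # an enclosed hole contributes an inner boundary
  ring <- matrix(FALSE, 30, 30); ring[5:25, 5:25] <- TRUE
  ring[10:20, 10:20] <- FALSE
  expect_gt(mask_perimeter(mask_from_grid(ring, 1)),
            mask_perimeter(mask_from_grid((row(ring) >= 5 & row(ring) <= 25 &
                                           col(ring) >= 5 & col(ring) <= 25), 1)))
})

test_that("distance to boundary matches straight-edge geometry and oracle", {
  g <- matrix(FALSE, 80, 80); g[, 1:51] <- TRUE
  m <- mask_from_grid(g, 1)
  ob <- spheroidquant:::new_detected_object(1L, cbind(41L, 61L))
  expect_equal(distance_to_boundary(ob, m), 10)
  on_bd <- spheroidquant:::new_detected_object(1L, cbind(41L, 51L))
  expect_equal(distance_to_boundary(on_bd, m), 0)
  expect_error(distance_to_boundary(ob, mask_from_grid(matrix(FALSE, 8, 8))),
               "empty")

  set.seed(14)
  for (i in 1:20) {
    mg <- matrix(FALSE, 40, 40)
    blob <- random_blob(40, 40, 150)
    mg[blob] <- TRUE
    obpix <- random_blob(40, 40, 10)
    obpix <- obpix[!mg[obpix], , drop = FALSE]
    if (nrow(obpix) == 0L) next
    obj <- spheroidquant:::new_detected_object(1L, obpix)
    got <- distance_to_boundary(obj, mask_from_grid(mg, 1))
    bd <- which(spheroidquant:::mask_boundary(mg), arr.ind = TRUE)
    ctr <- colMeans(obpix)
    brute <- Inf
    for (j in seq_len(nrow(bd)))
      brute <- min(brute, sqrt(sum((bd[j, ] - ctr)^2)))
    expect_equal(got, brute, tolerance = 1e-9)
  }
})

test_that("edge-referenced distance is never larger than centroid distance", {
  g <- matrix(FALSE, 60, 60); g[20:40, 1:20] <- TRUE
  m <- mask_from_grid(g, 1)
  pix <- as.matrix(expand.grid(row = 28:33, col = 40:48))
  ob <- spheroidquant:::new_detected_object(1L, pix)
  expect_lte(distance_to_boundary(ob, m, "edge"),
             distance_to_boundary(ob, m, "centroid"))
  expect_equal(distance_to_boundary(ob, m, "edge"), 40 - 20)
})

test_that("shape descriptors follow the particle-analysis conventions", {
  d <- matrix(FALSE, 80, 80)
  d[(row(d) - 40)^2 + (col(d) - 40)^2 <= 30^2] <- TRUE
  sd_disk <- shape_descriptors(which(d, arr.ind = TRUE))
  expect_gte(sd_disk["circularity"], 0.9)
  # hull over pixel-square corners: the digitized disk's jagged rim leaves
  # real concavities, so the exact value sits just below 0.97
  expect_gte(sd_disk["solidity"], 0.96)
  expect_equal(sd_disk["roundness"], 1, tolerance = 0.05,
               ignore_attr = TRUE)

  sq <- as.matrix(expand.grid(row = 1:40, col = 1:40))
  sd_sq <- shape_descriptors(sq)
  expect_equal(unname(sd_sq["circularity"]), 4 * pi * 1600 / (4 * 39)^2,
               tolerance = 0.05 / (pi / 4))
  expect_equal(unname(sd_sq["solidity"]), 1, tolerance = 0.02)

  expect_equal(unname(shape_descriptors(cbind(5L, 9L))),
               c(1, 1, 1))  # single pixel convention

  # elongated bar: low roundness, solidity ~ 1
  bar <- as.matrix(expand.grid(row = 10:12, col = 1:45))
  sd_bar <- shape_descriptors(bar)
  expect_lt(sd_bar["roundness"], 0.25)
  expect_gt(sd_bar["solidity"], 0.95)
})

test_that("descriptors are invariant under integer translation", {
  set.seed(3)
  pix <- random_blob(30, 30, 60)
  moved <- cbind(pix[, 1] + 7L, pix[, 2] + 11L)
  expect_equal(shape_descriptors(pix), shape_descriptors(moved))
})

test_that("doubling the calibration doubles lengths and quadruples areas", {
  fx <- fixture_cached("suppressed_invasion")
  im <- fx$dataset$followups[[1]]
  m1 <- largest_component(segment_compact(im))
  im2 <- calibrated_image(im$pixels, im$pixel_size_um * 2, "x",
                          im$bit_depth)
  m2 <- largest_component(segment_compact(im2))
  expect_equal(m2$area_um2, 4 * m1$area_um2)
  expect_equal(mask_perimeter(smooth_mask(m2)),
               2 * mask_perimeter(smooth_mask(m1)))
  o1 <- detect_objects(im, m1, emax_params(0.001))
  o2 <- detect_objects(im2, m2, emax_params(0.001))
  expect_equal(vapply(o2, `[[`, numeric(1), "distance_um"),
               2 * vapply(o1, `[[`, numeric(1), "distance_um"))
  expect_equal(vapply(o2, `[[`, numeric(1), "area_um2"),
               4 * vapply(o1, `[[`, numeric(1), "area_um2"))
})

test_that("summarize_image aggregates object statistics correctly", {
  g <- matrix(FALSE, 60, 150); g[20:40, 20:40] <- TRUE
  m <- mask_from_grid(g, 1)
  mk <- function(lab, row, col) {
    ob <- spheroidquant:::new_detected_object(lab, cbind(row, col))
    spheroidquant:::measure_objects(list(ob), m, 1)[[1]]
  }
  # objects at known straight-line distances right of the mask edge col 40
  objs <- list(mk(1L, 30L, 50L), mk(2L, 30L, 60L),
               mk(3L, 30L, 70L), mk(4L, 30L, 140L))
  s <- summarize_image(m, objs, "24h")
  expect_equal(s$n_objects, 4L)
  expect_equal(s$mean_distance_um, mean(c(10, 20, 30, 100)))
  expect_equal(s$median_distance_um, 25)
  expect_equal(s$n_objects_per_mm,
               4 / (mask_perimeter(smooth_mask(m)) / 1000))
  # zero objects
  s0 <- summarize_image(m, list(), "START")
  expect_equal(s0$n_objects, 0L)
  expect_equal(s0$total_object_area_um2, 0)
  expect_true(is.na(s0$mean_distance_um) && is.na(s0$median_distance_um))
  # excluded artifacts leave the statistics entirely
  art <- mk(5L, 5L, 5L); art$excluded_as_artifact <- TRUE
  s1 <- summarize_image(m, c(objs, list(art)), "24h")
  expect_equal(s1$n_objects, 4L)
  expect_equal(s1$n_excluded_artifacts, 1L)
  expect_equal(s1$mean_distance_um, s$mean_distance_um)
})
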