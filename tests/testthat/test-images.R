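test_that("radial kymograph isolates ring and uniform intensities", {
  n <- 64
  ctr <- (n + 1) / 2
  xg <- matrix(seq_len(n), n, n, byrow = TRUE)
  yg <- matrix(seq_len(n), n, n)
  d <- sqrt((xg - ctr)^2 + (yg - ctr)^2)

  # intensity 1 exactly on the 4th 3-px ring (9 <= d < 12), 0 elsewhere
  img <- (d >= 9 & d < 12) * 1
  k <- radial_kymograph(img, centre = c(ctr, ctr))
  expect_equal(k$intensity[1, 4], 1)
  expect_equal(k$intensity[1, 2], 0)

  # a uniform image averages to v in every bin
  ku <- radial_kymograph(matrix(3.7, n, n), centre = c(ctr, ctr))
  expect_equal(as.vector(ku$intensity), rep(3.7, ncol(ku$intensity)))

  # centre outside the image: frame skipped with a warning
  expect_warning(
    ks <- radial_kymograph(list(img, img), centre = rbind(c(ctr, ctr),
                                                          c(-5, 10))),
    "outside image")
  expect_true(all(is.na(ks$intensity[2, ])))
})

test_that("radial binning conserves mass", {
  set.seed(44)
  n <- 50
  img <- matrix(runif(n * n), n, n)
  ctr <- (n + 1) / 2
  k <- radial_kymograph(img, centre = c(ctr, ctr))
  binned <- sum(k$intensity[1, ] * k$npix[1, ])
  xg <- matrix(seq_len(n), n, n, byrow = TRUE)
  yg <- matrix(seq_len(n), n, n)
  d <- sqrt((xg - ctr)^2 + (yg - ctr)^2)
  covered <- d < length(k$radius) * k$ring_width
  expect_equal(binned, sum(img[covered]), tolerance = 1e-9)
})

test_that("the contour tracks a shrinking synthetic ring", {
  st <- gen_radial_stack(ring_radius = seq(15, 5, by = -1), medial_level = 5,
                         image_size = 64, noise_sd = 0.05, seed = 2)
  k <- radial_kymograph(st$signal, centre = st$centre, junction = st$junction)
  expect_true(all(diff(k$contour_radius) <= 1e-9))
  expect_lte(abs(k$contour_radius[1] - 15), 3)
  expect_lte(abs(k$contour_radius[11] - 5), 3)
})

test_that("region intensities separate medial, junctional and total signal", {
  n <- 60
  xg <- matrix(seq_len(n), n, n, byrow = TRUE)
  yg <- matrix(seq_len(n), n, n)
  d <- sqrt((xg - 30)^2 + (yg - 30)^2)
  mask <- (d <= 12) * 1

  # uniform disk of intensity 5 on background 0
  img <- mask * 5
  ri <- region_intensities(mask, img)
  expect_equal(ri$medial, 5)
  expect_lt(ri$junctional, 5)
  expect_gt(ri$junctional, 0)
  expect_lt(ri$total, 5)

  # ring-only signal: medial sees none of it
  ring_img <- (abs(d - 12) <= 2) * 8
  ri2 <- region_intensities(mask, ring_img)
  expect_equal(ri2$medial, 0)
  expect_gt(ri2$junctional, 0)

  # disk of 10 on a background plane of 2, subtracted from a corner ROI
  img3 <- matrix(2, n, n)
  img3[mask > 0] <- 10
  ri3 <- region_intensities(mask, img3,
                            background = list(x = 1, y = 1, size = 15))
  expect_equal(ri3$medial, 8)
  expect_equal(ri3$background, 2)

  # over-erosion empties the mask
  tiny <- matrix(0, 20, 20); tiny[10, 10] <- 1
  expect_warning(ri4 <- region_intensities(tiny, matrix(1, 20, 20)),
                 "emptied")
  expect_true(is.na(ri4$medial))
})

test_that("apicobasal profiles align the reference maximum at zero", {
  prof <- tibble::tibble(cell_id = 1, z = 1:7,
                         reference = c(1, 2, 5, 9, 4, 2, 1),
                         signal = c(2, 6, 10, 8, 6, 4, 2))
  ap <- apicobasal_profile(prof)
  expect_equal(ap$members$rel_z[which.max(prof$reference)], 0)
  expect_equal(max(ap$members$signal_norm), 1)
  expect_equal(min(ap$members$signal_norm), 0)

  # (2, 6, 10) min-max normalises to (0, 0.5, 1)
  p2 <- tibble::tibble(cell_id = 1, z = 1:3, reference = c(1, 3, 2),
                       signal = c(2, 6, 10))
  expect_equal(apicobasal_profile(p2)$members$signal_norm, c(0, 0.5, 1))

  # jittered reference maxima land at rel_z = 0 for every cell
  set.seed(6)
  cohort <- purrr::map_dfr(1:12, function(cell) {
    shift <- sample(-2:2, 1)
    z <- 1:9
    tibble::tibble(cell_id = cell, z = z,
                   reference = exp(-(z - 5 - shift)^2) + rnorm(9, 0, 0.01),
                   signal = exp(-(z - 5 - shift)^2 / 4))
  })
  apc <- apicobasal_profile(cohort)
  peak_by_cell <- apc$members |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(peak = rel_z[which.max(signal_norm)])
  expect_true(all(peak_by_cell$peak == 0))
  s <- apc$summary
  expect_equal(s$rel_z[which.max(s$mean)], 0)

  # flat reference: flagged, tie broken to the most apical plane
  pf <- tibble::tibble(cell_id = "flat", z = 1:4, reference = rep(1, 4),
                       signal = c(1, 2, 3, 4))
  apf <- apicobasal_profile(pf)
  expect_equal(apf$flags, "flat")
  expect_equal(apf$members$rel_z[1], 0)

  expect_error(apicobasal_profile(tibble::tibble(cell_id = 1, z = 1:2,
                                                 reference = 1:2,
                                                 signal = 1:2)),
               class = "extrudr_parameter_error")
})
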