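uniform_image <- function(rgb, width = 10, height = 8) {
  array(rep(rgb, each = width * height), dim = c(height, width, 3))
}

test_that("rasterization counts pixel centers inside the polygon", {
  rect <- roi_polygon("r", rbind(c(0.5, 0.5), c(10.5, 0.5),
                                 c(10.5, 5.5), c(0.5, 5.5)))
  mask <- rasterize_roi(rect, 20, 20)
  expect_equal(sum(mask), 50) # centers x in 1..10, y in 1..5

  full <- roi_polygon("f", rbind(c(-0.5, -0.5), c(19.5, -0.5),
                                 c(19.5, 19.5), c(-0.5, 19.5)))
  expect_true(all(rasterize_roi(full, 20, 20)))

  outside <- roi_polygon("o", rbind(c(100, 100), c(110, 100), c(105, 110)))
  expect_error(rasterize_roi(outside, 20, 20), class = "phenoring_coverage")
})

test_that("self-intersecting polygons are rejected", {
  expect_error(roi_polygon("bowtie", rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               class = "phenoring_geometry")
})

test_that("mask area agrees with an independent point-in-polygon oracle", {
  phenoring:::with_seed(7, {
    for (i in 1:20) {
      # random convex polygon (convex hull of random points), vertices kept
      # off pixel centers to avoid boundary-convention ambiguity
      pts <- cbind(runif(8, 0.3, 29.3), runif(8, 0.3, 24.3))
      hull <- pts[chull(pts), , drop = FALSE]
      roi <- roi_polygon(paste0("p", i), hull)
      mask <- tryCatch(rasterize_roi(roi, 30, 25), error = function(e) NULL)
      oracle <- oracle_mask_count(hull, 30, 25)
      if (is.null(mask)) {
        expect_equal(oracle, 0)
      } else {
        expect_equal(sum(mask), oracle)
      }
    }
  })
})

test_that("chromatic coordinates use the ratio-of-means convention", {
  mask <- matrix(TRUE, 8, 10)
  green <- chromatic_coordinates(uniform_image(c(0, 255, 0)), mask)
  expect_equal(unname(green["gcc"]), 1)
  expect_equal(unname(green["rcc"]), 0)

  gray <- chromatic_coordinates(uniform_image(c(100, 100, 100)), mask)
  expect_equal(unname(gray), rep(1 / 3, 3))

  # two-pixel ROI separating the two conventions: channel means (150,100,0)
  # so ratio-of-means gcc = 100/250 = 0.4 (mean-of-ratios would give 1/3)
  img <- array(0, dim = c(1, 2, 3))
  img[1, 1, ] <- c(100, 200, 0)
  img[1, 2, ] <- c(200, 0, 0)
  cc <- chromatic_coordinates(img, matrix(TRUE, 1, 2))
  expect_equal(unname(cc["gcc"]), 0.4)
  expect_equal(unname(cc["rcc"]), 0.6)
})

test_that("chromatic coordinates sum to 1 and are brightness-invariant", {
  phenoring:::with_seed(11, {
    for (i in 1:50) {
      img <- array(runif(12 * 12 * 3, 0, 255), dim = c(12, 12, 3))
      mask <- matrix(runif(144) < 0.5, 12, 12)
      if (!any(mask)) mask[1, 1] <- TRUE
      cc <- chromatic_coordinates(img, mask)
      expect_lt(abs(sum(cc) - 1), 1e-9)
      k <- runif(1, 0.2, 4)
      cc2 <- chromatic_coordinates(img * k, mask)
      expect_equal(unname(cc2), unname(cc), tolerance = 1e-12)
    }
  })
})

test_that("degenerate chromatic inputs are handled", {
  mask <- matrix(TRUE, 4, 4)
  black <- chromatic_coordinates(uniform_image(c(0, 0, 0), 4, 4), mask)
  expect_true(all(is.na(black)))
  expect_error(chromatic_coordinates(uniform_image(c(1, 2, 3), 4, 4),
                                     matrix(TRUE, 5, 5)),
               class = "phenoring_dimension")
  expect_error(chromatic_coordinates(uniform_image(c(1, 2, 3), 4, 4),
                                     matrix(FALSE, 4, 4)),
               class = "phenoring_coverage")
})

test_that("daily compositing supports mean, median and percentile", {
  one <- data.frame(year = 2013, doy = 1, gcc = 0.37)
  for (m in c("mean", "median", "percentile")) {
    expect_equal(daily_composite(one, m)$gcc, 0.37)
  }
  three <- data.frame(year = 2013, doy = c(1, 1, 1), gcc = c(0.3, 0.4, 0.5))
  expect_equal(daily_composite(three, "mean")$gcc, 0.4)

  five <- data.frame(year = 2013, doy = 1, gcc = c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(daily_composite(five, "percentile", p = 90)$gcc, 0.46)

  expect_error(daily_composite(five, "percentile", p = 100),
               class = "phenoring_parameter")
  expect_error(daily_composite(five, "percentile", p = 0),
               class = "phenoring_parameter")

  # NA samples are ignored; all-NA days stay missing
  mixed <- data.frame(year = 2013, doy = c(1, 1, 2), gcc = c(0.2, NA, NA))
  out <- daily_composite(mixed, "mean")
  expect_equal(out$gcc, c(0.2, NA))
})

test_that("extraction names variables per ROI and handles zero frames", {
  rois <- list(roi_polygon("a", rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5))),
               roi_polygon("b", rbind(c(7, 0), c(11, 0), c(11, 5), c(7, 5))))
  empty <- extract_series(list(), rois)
  expect_equal(nrow(empty), 0)
  expect_equal(pheno_vars(empty), c("gcc_a", "gcc_b"))

  img <- uniform_image(c(50, 150, 50), width = 12, height = 8)
  frames <- list(list(year = 2013, doy = 10, seq = 1, image = img))
  tab <- extract_series(frames, rois, indices = c("gcc", "rcc"))
  expect_equal(pheno_vars(tab), c("gcc_a", "rcc_a", "gcc_b", "rcc_b"))
  expect_equal(tab$gcc_a, 150 / 250)
  expect_equal(tab$rcc_b, 50 / 250)
})

test_that("frame timestamps parse from filenames", {
  got <- parse_frame_filename(c("cam1_2013_060_2.png", "x_2012_366_1.png",
                                "notaframe.txt"))
  expect_equal(got$year, c(2013L, 2012L, NA))
  expect_equal(got$doy, c(60L, 366L, NA))
  expect_equal(got$seq, c(2L, 1L, NA))
})
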