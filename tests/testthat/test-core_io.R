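test_that("fundus_image enforces its invariants", {
  expect_error(fundus_image(matrix(0, 10, 10)), "32")
  expect_error(fundus_image(array(0, c(64, 64, 2))), "channel|1,3")
  m <- matrix(100, 40, 40); m[1, 1] <- NA
  expect_error(fundus_image(m), "finite")
  img <- fundus_image(matrix(128, 40, 50), image_id = "a")
  expect_equal(dim(img), c(40L, 50L, 1L))
  rgb <- fundus_image(array(seq(0, 255, length.out = 64 * 64 * 3),
                            c(64, 64, 3)))
  expect_equal(dim(as_gray(rgb)), c(64L, 64L))
  expect_equal(as_gray(rgb), rgb$pixels[, , 2]) # green channel
})

test_that("mask, junction and correspondence containers validate inputs", {
  expect_error(vessel_mask(matrix(2, 4, 4)), "0 or 1")
  expect_error(junction_points(row = -1, col = 3), ">= 1")
  expect_warning(jp <- junction_points(row = 3, col = 4, kind = "weird"),
                 "unknown")
  expect_equal(jp$kind, "unknown")
  expect_error(correspondence_set(matrix(0, 0, 2), matrix(0, 0, 2)),
               "at least one")
  expect_error(confusion_counts(-1, 0, 0), ">= 0")
  cc <- confusion_counts(3, 1, 2)
  expect_true(is.na(cc$tn))
})

test_that("homography normalizes its last element and rejects singularity", {
  h <- homography(matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2), 3, 3))
  expect_equal(unclass(h)[3, 3], 1)
  expect_equal(unclass(h)[1, 1], 1)
  expect_error(homography(matrix(1, 3, 3)), "invertible")
  expect_error(homography(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)),
               "nonzero")
})

test_that("raster/geometric coordinate converters are inverse bijections", {
  xy <- rc_to_xy(row = c(3L, 10L), col = c(7L, 1L))
  expect_equal(unname(xy[, 1]), c(7, 1)) # x = col
  rc <- xy_to_rc(xy)
  expect_equal(rc$row, c(3L, 10L))
  expect_equal(rc$col, c(7L, 1L))
})

test_that("images round-trip through PNG and TIFF losslessly", {
  px <- matrix(sample(0:255, 48 * 40, replace = TRUE), 48, 40)
  img <- fundus_image(px)
  for (ext in c("png", "tiff")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_image(img, f)
    back <- read_image(f)
    expect_equal(back$pixels, img$pixels, info = ext)
  }
  rgb <- fundus_image(array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3)))
  f <- tempfile(fileext = ".png")
  write_image(rgb, f)
  expect_equal(read_image(f)$pixels, rgb$pixels)
  expect_error(read_image("no/such/file.png"), "not found")
})

test_that("grayscale TIFF reads with one channel and masks round-trip", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64 * 64), 64, 64), f, bits.per.sample = 8L)
  expect_equal(dim(read_image(f))[3], 1L)
  m <- vessel_mask(matrix(rbinom(40 * 40, 1, 0.2), 40, 40))
  fm <- tempfile(fileext = ".png")
  write_mask(m, fm)
  expect_equal(unclass(read_mask(fm)), unclass(m), ignore_attr = TRUE)
})

test_that("point files parse, convert origin, and round-trip", {
  f <- tempfile(fileext = ".csv")
  writeLines("row,col,kind\n10,20,bifurcation", f)
  pts <- read_points(f) # 0-based on disk -> 1-based in memory
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$row, 11L)
  expect_equal(pts$col, 21L)
  expect_equal(pts$kind, "bifurcation")
  writeLines("row,col,kind", f)
  expect_equal(nrow(read_points(f)), 0L)
  writeLines("row,col,kind\n-3,5,crossover", f)
  expect_error(read_points(f), "line 1")
  jp <- junction_points(row = c(5L, 9L), col = c(2L, 30L),
                        kind = c("bifurcation", "crossover"),
                        score = c(1, 0.5))
  write_points(jp, f)
  back <- read_points(f)
  expect_equal(back$row, jp$row)
  expect_equal(back$col, jp$col)
  expect_equal(back$kind, jp$kind)
  expect_equal(back$score, jp$score)
  # JSON variant
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(row = 4, col = 6, kind = "crossover"), fj)
  pj <- read_points(fj)
  expect_equal(pj$row, 5L)
  expect_equal(pj$kind, "crossover")
})

test_that("correspondence files parse both delimiters and report bad lines", {
  f <- tempfile()
  writeLines("0 0 5 5", f)
  cs <- read_correspondences(f)
  expect_equal(nrow(cs$ref), 1L)
  expect_equal(unname(cs$ref[1, ]), c(1, 1))    # 0-based file -> 1-based
  expect_equal(unname(cs$sensed[1, ]), c(6, 6))
  writeLines(apply(matrix(round(runif(40, 0, 99), 2), 10, 4), 1, paste,
                   collapse = ","), f)
  expect_equal(nrow(read_correspondences(f)$ref), 10L)
  writeLines(c("1 2 3 4", "5 6 7"), f)
  expect_error(read_correspondences(f), "line 2")
  cs <- correspondence_set(cbind(runif(5, 1, 50), runif(5, 1, 50)),
                           cbind(runif(5, 1, 50), runif(5, 1, 50)))
  write_correspondences(cs, f)
  back <- read_correspondences(f)
  expect_equal(back$ref, cs$ref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$sensed, cs$sensed, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("homography text files round-trip at full precision", {
  h <- compose_homography(256, rotation = 17, translation = c(3.5, -2),
                          scale = 1.07, perspective = c(1e-4, -5e-5))
  f <- tempfile(fileext = ".txt")
  write_homography(h, f)
  expect_equal(unclass(read_homography(f)), unclass(h), tolerance = 1e-12)
})
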