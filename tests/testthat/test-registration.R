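test_that("transform_point evaluates the projective map", {
  expect_equal(unname(transform_point(homography(diag(3)), c(3, 4))[1, ]),
               c(3, 4))
  tr <- homography(matrix(c(1, 0, 0, 0, 1, 0, 10, -5, 1), 3, 3))
  expect_equal(unname(transform_point(tr, c(3, 4))[1, ]), c(13, -1))
  hp <- homography(matrix(c(1, 0, 0.001, 0, 1, 0, 0, 0, 1), 3, 3))
  expect_equal(unname(transform_point(hp, c(100, 0))[1, ]),
               c(100 / 1.1, 0), tolerance = 1e-12)
  bad <- homography(matrix(c(1, 0, -0.01, 0, 1, 0, 0, 0, 1), 3, 3))
  expect_error(transform_point(bad, c(100, 0)), "infinity")
})

test_that("forward and inverse transforms compose to the identity", {
  set.seed(11)
  for (i in 1:100) {
    h <- compose_homography(256, rotation = runif(1, -40, 40),
                            translation = runif(2, -50, 50),
                            scale = runif(1, 0.8, 1.25),
                            perspective = runif(2, -2e-4, 2e-4))
    hinv <- homography(solve(unclass(h)))
    p <- cbind(runif(20, 1, 256), runif(20, 1, 256))
    expect_lt(max(abs(transform_point(h, transform_point(hinv, p)) - p)),
              1e-9)
  }
})

test_that("warp_image resamples through the inverse map", {
  tr <- test_tree()
  img <- render_fundus(tr$mask, seed = 1)
  idw <- warp_image(homography(diag(3)), img)
  expect_equal(idw$pixels, img$pixels, tolerance = 1e-12)
  sh <- homography(matrix(c(1, 0, 0, 0, 1, 0, 10, 0, 1), 3, 3))
  w <- warp_image(sh, img)
  expect_equal(w$pixels[, 51:200, 1], img$pixels[, 41:190, 1],
               tolerance = 1e-9)
  # warping a pair's sensed image with true_H reproduces the reference
  pair <- generate_pair(vascular_tree_params(seed = 4), rotation = 10,
                        translation = c(12, -6), seed = 4)
  back <- warp_image(pair$true_H, pair$sensed_image)
  fov <- fundusreg:::fov_mask(256) == 1
  ok <- fov & back$pixels[, , 1] > 0
  mad <- mean(abs(back$pixels[, , 1][ok] - pair$ref_image$pixels[, , 1][ok]))
  expect_lt(mad, 15) # independent texture/noise draws, under vessel contrast
})

test_that("keypoints come from junctions with stable multi-peak orientations", {
  tr <- test_tree()
  img <- apply_clahe(render_fundus(tr$mask, seed = 1))
  cal <- calibrate_junctions(detect_junctions_skeleton(tr$mask), tr$mask)
  expect_equal(nrow(extract_keypoints(junction_points(), img)), 0L)
  kp0 <- extract_keypoints(cal, img, radius = 0L, n_aux = 0L)
  # one keypoint position per interior junction (orientation variants share it)
  expect_equal(nrow(unique(kp0[, c("x", "y")])),
               sum(cal$row > 14 & cal$row <= 256 - 14 &
                   cal$col > 14 & cal$col <= 256 - 14))
  expect_true(all(kp0$orientation >= 0 & kp0$orientation < 2 * pi))
  # border junctions are skipped with a warning
  edge <- junction_points(row = 5L, col = 5L, provenance = "detected")
  expect_warning(extract_keypoints(edge, img), "border")
})

test_that("rotating the image rotates keypoint orientations accordingly", {
  tr <- test_tree()
  img <- render_fundus(tr$mask, seed = 1, noise_sd = 0)
  cal <- calibrate_junctions(detect_junctions_skeleton(tr$mask), tr$mask)
  rot <- augment(img, tr$mask, rotation = 90)
  cal2 <- calibrate_junctions(detect_junctions_skeleton(rot$mask), rot$mask)
  k1 <- suppressWarnings(extract_keypoints(cal, img, n_aux = 0L))
  k2 <- suppressWarnings(extract_keypoints(cal2, rot$image, n_aux = 0L))
  # rotated position: (x, y) -> (N + 1 - y, x)
  x2 <- 257 - k1$y; y2 <- k1$x
  checked <- 0L; consistent <- 0L
  bin <- 2 * pi / 36
  for (i in seq_len(nrow(k1))) {
    j <- which(abs(k2$x - x2[i]) <= 1.5 & abs(k2$y - y2[i]) <= 1.5)
    if (!length(j)) next
    dth <- abs(((k2$orientation[j] - k1$orientation[i] - pi / 2 + pi) %%
                  (2 * pi)) - pi)
    checked <- checked + 1L
    if (min(dth) <= 1.5 * bin) consistent <- consistent + 1L
  }
  expect_gt(checked, 10L)
  expect_gte(consistent / checked, 0.8)
})

test_that("descriptors are unit-norm, deterministic, and rotation invariant", {
  tr <- test_tree()
  img <- render_fundus(tr$mask, seed = 1, noise_sd = 0)
  cal <- calibrate_junctions(detect_junctions_skeleton(tr$mask), tr$mask)
  kp <- suppressWarnings(extract_keypoints(cal, img, n_aux = 0L))
  d1 <- compute_descriptors(img, kp)
  expect_equal(ncol(d1$descriptors), 128L)
  expect_true(all(abs(sqrt(rowSums(d1$descriptors^2)) - 1) < 1e-6))
  expect_true(all(d1$descriptors >= 0))
  d2 <- compute_descriptors(img, kp)
  expect_identical(d1$descriptors, d2$descriptors)
  # flat patch: no gradients -> keypoint dropped
  flat <- fundus_image(matrix(50, 64, 64))
  kflat <- data.frame(x = 32, y = 32, scale = 2, orientation = 0, junction = 1)
  class(kflat) <- c("keypoints", "data.frame")
  expect_equal(nrow(compute_descriptors(flat, kflat)$descriptors), 0L)
  # rotation invariance: descriptors at matched positions in a rotated copy
  rot <- augment(img, tr$mask, rotation = 90)
  cal2 <- calibrate_junctions(detect_junctions_skeleton(rot$mask), rot$mask)
  kp2 <- suppressWarnings(extract_keypoints(cal2, rot$image, n_aux = 0L))
  d3 <- compute_descriptors(rot$image, kp2)
  x2 <- 257 - d1$keypoints$y; y2 <- d1$keypoints$x
  dists <- c()
  for (i in seq_len(nrow(d1$keypoints))) {
    j <- which(abs(d3$keypoints$x - x2[i]) <= 1.5 &
               abs(d3$keypoints$y - y2[i]) <= 1.5)
    if (!length(j)) next
    dd <- sqrt(colSums((t(d3$descriptors[j, , drop = FALSE]) -
                          d1$descriptors[i, ])^2))
    dists <- c(dists, min(dd))
  }
  expect_gt(length(dists), 10L)
  expect_lt(median(dists), 0.2)
})

test_that("ratio-test matching accepts, rejects, and stays one-to-one", {
  mk <- function(...) { v <- c(...); v / sqrt(sum(v^2)) }
  ref <- rbind(mk(1, 0, 0))
  good <- rbind(mk(0.995, 0.1, 0), mk(0, 1, 0), mk(0, 0, 1))
  m <- match_descriptors(ref, good, ratio = 0.84)
  expect_equal(nrow(m), 1L)
  expect_equal(m$sensed_idx, 1L)
  expect_true(m$d1 <= m$d2)
  # chords 0.9 and 1.0 from the reference: ratio 0.9 > 0.84 -> rejected
  close2 <- rbind(mk(0.595, sqrt(1 - 0.595^2), 0), mk(0.5, sqrt(0.75), 0))
  expect_equal(nrow(match_descriptors(ref, close2, ratio = 0.84)), 0L)
  dup <- rbind(mk(1, 0, 0), mk(1, 0, 0))
  expect_equal(nrow(match_descriptors(ref, dup, ratio = 0.84)), 0L) # d1 = d2
  expect_error(match_descriptors(ref, ref, ratio = 0.84), "at least 2")
  # monotonicity: matches at a tighter threshold are a subset
  set.seed(4)
  A <- matrix(abs(rnorm(20 * 128)), 20); A <- A / sqrt(rowSums(A^2))
  B <- matrix(abs(rnorm(30 * 128)), 30); B <- B / sqrt(rowSums(B^2))
  lo <- match_descriptors(A, B, ratio = 0.7)
  hi <- match_descriptors(A, B, ratio = 0.95)
  expect_true(all(paste(lo$ref_idx, lo$sensed_idx) %in%
                  paste(hi$ref_idx, hi$sensed_idx)))
  expect_false(any(duplicated(hi$sensed_idx)))
})

test_that("homography estimation is exact, robust, and flags degeneracy", {
  set.seed(5)
  h <- compose_homography(256, rotation = 10, translation = c(5, -3),
                          scale = 1.05, perspective = c(1e-4, -5e-5))
  p4 <- cbind(runif(4, 10, 240), runif(4, 10, 240))
  est <- estimate_homography(p4, transform_point(h, p4), seed = 7)
  expect_equal(est$status, "ok")
  expect_lt(max(abs(transform_point(est$h, p4) - transform_point(h, p4))),
            1e-6)
  col <- cbind(1:10, 2 * (1:10) + 1)
  expect_equal(estimate_homography(col, col + 5, seed = 1)$status,
               "degenerate")
  few <- cbind(runif(3), runif(3))
  expect_equal(estimate_homography(few, few, seed = 1)$status,
               "insufficient_matches")
})

test_that("RANSAC tolerates 40% gross outliers across seeds", {
  for (s in 1:20) {
    set.seed(s)
    h <- compose_homography(256, rotation = runif(1, -15, 15),
                            translation = runif(2, -20, 20),
                            scale = runif(1, 0.9, 1.1),
                            perspective = runif(2, -1e-4, 1e-4))
    sensed <- cbind(runif(60, 10, 240), runif(60, 10, 240))
    ref <- transform_point(h, sensed)
    out <- 1:24
    ref[out, ] <- ref[out, ] +
      matrix(runif(48, 20, 80) * sample(c(-1, 1), 48, TRUE), 24, 2)
    est <- estimate_homography(sensed, ref, seed = s)
    expect_equal(est$status, "ok")
    err <- sqrt(rowSums((transform_point(est$h, sensed[-out, , drop = FALSE]) -
                         transform_point(h, sensed[-out, , drop = FALSE]))^2))
    expect_lte(mean(err), 1)
  }
})

test_that("register_pair handles self-registration and a synthetic pair", {
  tr <- test_tree()
  img <- render_fundus(tr$mask, seed = 1)
  self <- register_pair(img, img, ref_mask = tr$mask, sensed_mask = tr$mask)
  expect_equal(self$status, "ok")
  expect_lt(control_point_error(self$homography, homography(diag(3))), 0.5)
  err <- registration_error_for_seed(5)
  expect_lt(err, 2)
})

test_that("disjoint vasculature never registers with a silent tiny error", {
  a <- generate_vascular_tree(vascular_tree_params(seed = 101))
  b <- generate_vascular_tree(vascular_tree_params(seed = 202))
  res <- register_pair(render_fundus(a$mask, seed = 1),
                       render_fundus(b$mask, seed = 2),
                       ref_mask = a$mask, sensed_mask = b$mask)
  if (res$status == "ok") {
    # no true transform exists; any accepted model must be visibly wrong
    expect_gte(control_point_error(res$homography, homography(diag(3))), 25)
  } else {
    expect_true(res$status %in% c("insufficient_matches", "degenerate"))
  }
})
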