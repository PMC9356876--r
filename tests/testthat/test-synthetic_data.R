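test_that("tree generation is deterministic and respects depth", {
  p <- vascular_tree_params(seed = 42)
  a <- generate_vascular_tree(p)
  b <- generate_vascular_tree(p)
  expect_identical(unclass(a$mask), unclass(b$mask))
  expect_identical(a$junctions, b$junctions)
  # a depth-1 single root never branches
  single <- generate_vascular_tree(vascular_tree_params(n_roots = 1L,
                                                        max_depth = 1L,
                                                        seed = 4))
  expect_equal(nrow(single$junctions), 0L)
  expect_gt(sum(single$mask), 0)
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(vascular_tree_params(image_size = 32), ">= 64")
  expect_error(vascular_tree_params(max_depth = 0), ">= 1")
  expect_error(vascular_tree_params(initial_width = 0.5), ">= 1")
  expect_error(vascular_tree_params(width_decay = 0), "\\(0,1\\]")
})

test_that("recorded junctions carry >= 3 skeleton branches", {
  tr <- generate_vascular_tree(vascular_tree_params(branch_prob = 1,
                                                    n_roots = 2L,
                                                    max_depth = 5L,
                                                    seed = 8))
  skel <- prune_spurs(skeletonize_region(tr$mask), 4L)
  idx <- which(unclass(skel) == 1L, arr.ind = TRUE)
  ok <- 0L
  for (i in seq_len(nrow(tr$junctions))) {
    d2 <- (idx[, 1] - tr$junctions$row[i])^2 + (idx[, 2] - tr$junctions$col[i])^2
    near <- idx[d2 <= 9, , drop = FALSE]
    cn <- apply(near, 1, function(px) count_branch_neighbors(skel, px))
    if (length(cn) && max(cn) >= 3) ok <- ok + 1L
  }
  expect_gte(ok / nrow(tr$junctions), 0.95)
})

test_that("rendering honors the stated contrast contracts", {
  tr <- test_tree()
  img <- render_fundus(tr$mask, "fundus", seed = 1)
  m <- unclass(tr$mask) == 1L
  g <- fundusreg:::fov_mask(nrow(m)) == 1L
  px <- img$pixels[, , 1]
  expect_gt(mean(px[!m & g]) - mean(px[m]), 20)
  ang <- render_fundus(tr$mask, "angiography", seed = 1)
  pa <- ang$pixels[, , 1]
  expect_gt(mean(pa[m]) - mean(pa[!m & g]), 20)
  # empty mask renders background only, deterministically
  empty <- vessel_mask(matrix(0L, 128, 128))
  e1 <- render_fundus(empty, seed = 2)
  e2 <- render_fundus(empty, seed = 2)
  expect_identical(e1$pixels, e2$pixels)
  # background only: no vessel-dark pixels inside the field of view
  expect_gt(min(e1$pixels[, , 1][fundusreg:::fov_mask(128) == 1]), 100)
})

test_that("identity and translation pairs behave as their transforms say", {
  p <- vascular_tree_params(seed = 6)
  idp <- generate_pair(p, seed = 9)
  expect_equal(unclass(idp$true_H), diag(3), ignore_attr = TRUE)
  expect_identical(unclass(idp$true_mask_ref), unclass(idp$true_mask_sensed))
  tp <- generate_pair(p, translation = c(10, -5), seed = 9)
  # sensed junction = reference junction shifted by the inverse translation
  jr <- tp$true_junctions_ref
  js <- tp$true_junctions_sensed
  for (i in seq_len(nrow(js))) {
    d <- sqrt((jr$col - (js$col[i] + 10))^2 + (jr$row - (js$row[i] - 5))^2)
    expect_lt(min(d), 1.01)
  }
})

test_that("the composed homography matches an independent composition", {
  s <- 256
  rot <- 15 * pi / 180
  # oracle: compose center-rotation and perspective matrices by hand
  c0 <- (s + 1) / 2
  R <- rbind(c(cos(rot), -sin(rot), 0), c(sin(rot), cos(rot), 0), c(0, 0, 1))
  Tc <- rbind(c(1, 0, c0), c(0, 1, c0), c(0, 0, 1))
  Tmc <- rbind(c(1, 0, -c0), c(0, 1, -c0), c(0, 0, 1))
  P <- rbind(c(1, 0, 0), c(0, 1, 0), c(1e-4, 0, 1))
  Ho <- Tc %*% R %*% Tmc %*% P
  Ho <- Ho / Ho[3, 3]
  h <- compose_homography(s, rotation = 15, perspective = c(1e-4, 0))
  corners <- rbind(c(1, 1), c(s, 1), c(1, s), c(s, s))
  expect_lt(max(abs(transform_point(h, corners) -
                    transform_point(homography(Ho), corners))), 1e-9)
})

test_that("pairs reject transforms outside the realistic envelope", {
  p <- vascular_tree_params(seed = 2)
  expect_error(generate_pair(p, rotation = 60), "45")
  expect_error(generate_pair(p, scale = 1.5), "scale")
  expect_error(generate_pair(p, perspective = c(1e-3, 0)), "perspective")
  expect_error(generate_pair(p, translation = c(240, 240)), "out of frame")
})

test_that("every generated pair satisfies the geometric consistency invariant", {
  worst <- 0
  for (s in 1:20) {
    pair <- generate_pair(vascular_tree_params(seed = s), rotation = 10,
                          translation = c(8, -5), scale = 1.02, seed = s)
    if (!nrow(pair$true_junctions_sensed)) next
    xy <- transform_point(pair$true_H,
                          rc_to_xy(pair$true_junctions_sensed$row,
                                   pair$true_junctions_sensed$col))
    d <- sqrt(outer(xy[, 2], pair$true_junctions_ref$row, "-")^2 +
              outer(xy[, 1], pair$true_junctions_ref$col, "-")^2)
    worst <- max(worst, max(apply(d, 1, min)))
  }
  expect_lt(worst, 1.5)
})

test_that("blurred and inverted qualities alter only the sensed image", {
  p <- vascular_tree_params(seed = 5)
  good <- generate_pair(p, rotation = 5, seed = 3)
  bl <- generate_pair(p, rotation = 5, quality = "blurred", seed = 3)
  inv <- generate_pair(p, rotation = 5, quality = "inverted", seed = 3)
  expect_identical(good$ref_image$pixels, bl$ref_image$pixels)
  expect_lt(sd(bl$sensed_image$pixels), sd(good$sensed_image$pixels))
  m <- unclass(inv$true_mask_sensed) == 1L
  g <- fundusreg:::fov_mask(256) == 1L
  expect_gt(mean(inv$sensed_image$pixels[, , 1][m]),
            mean(inv$sensed_image$pixels[, , 1][!m & g]))
})

test_that("write_pair produces the full artifact set", {
  d <- file.path(tempdir(), "pair_out")
  pair <- generate_pair(vascular_tree_params(seed = 1), rotation = 8, seed = 2)
  write_pair(pair, d)
  expect_true(all(file.exists(file.path(d, c("ref.png", "sensed.png",
                                             "mask_ref.png", "mask_sensed.png",
                                             "junctions_ref.csv",
                                             "junctions_sensed.csv",
                                             "H.txt", "manifest.yaml")))))
  expect_equal(unclass(read_homography(file.path(d, "H.txt"))),
               unclass(pair$true_H), tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
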