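ns <- asNamespace("fundusreg")

test_that("anchor generation follows the area-preserving parameterization", {
  a <- make_anchors(4, 4, stride = 8, base_anchor = 32)
  expect_equal(nrow(a), 4 * 4 * 6) # 2 scales x 3 ratios per location
  sq <- a[a$anchor == 1, ][1, ]
  expect_equal(sq$w, 32)
  expect_equal(sq$h, 32)
  # AR = 2, S = 1: area preserved, aspect ratio exact
  ar2 <- a[a$anchor == 3, ][1, ] # scale index 1, ratio index 2
  expect_equal(ar2$w * ar2$h, 32^2, tolerance = 1e-9)
  expect_equal(ar2$w / ar2$h, 2, tolerance = 1e-9)
  # pinned regression of the chosen formula reading
  expect_equal(ar2$w, 32 * sqrt(2), tolerance = 1e-12)
  expect_equal(ar2$h, 32 / sqrt(2), tolerance = 1e-12)
  expect_error(make_anchors(4, 4, 8, base_anchor = 0), "positive")
})

test_that("per-image anchor totals match the combinatorial count", {
  cfg <- jdn_config()
  anchors <- ns$jdn_anchors(cfg, 128L)
  strides <- 2^(3:7)
  for (l in 1:5) {
    cells <- (128 %/% strides[l])^2
    expect_equal(nrow(anchors[[l]]), cells * 6L)
  }
})

test_that("residual blocks satisfy the identity-plus-residual contract", {
  set.seed(3)
  p <- ns$res_init(4L, 8L, stride = 1L)
  x <- array(rnorm(12 * 12 * 4), c(12, 12, 4))
  y <- residual_block(x, p)
  expect_true(all(y >= 0)) # final ReLU
  # zero residual weights leave ReLU(I(x))
  pz <- p
  pz$r1$W[] <- 0; pz$r2$W[] <- 0; pz$r3$W[] <- 0
  yz <- residual_block(x, pz)
  idn <- ns$conv_fwd(x, p$sc, stride = 1L, pad = 0L)$y
  expect_equal(yz, pmax(idn, 0), tolerance = 1e-12)
  # stride-2 block halves the spatial size
  p2 <- ns$res_init(4L, 8L, stride = 2L)
  expect_equal(dim(residual_block(x, p2))[1:2], c(6L, 6L))
})

test_that("the feature pyramid has the stated shapes and information flow", {
  set.seed(4)
  p <- ns$pyramid_init(8L, 16L, 32L, 8L)
  C3 <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  C4 <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  C5 <- array(rnorm(8 * 8 * 32), c(8, 8, 32))
  P <- build_pyramid(C3, C4, C5, p)
  expect_equal(sapply(P, function(x) dim(x)[1]), c(32L, 16L, 8L, 4L, 2L))
  # all-zero inputs with zero biases give an all-zero pyramid
  P0 <- build_pyramid(0 * C3, 0 * C4, 0 * C5, p)
  expect_true(all(vapply(P0, function(x) max(abs(x)), numeric(1)) == 0))
  # top-down flow: perturbing C5 changes M4 and hence P4
  C5b <- C5; C5b[1, 1, 1] <- C5b[1, 1, 1] + 1
  Pb <- build_pyramid(C3, C4, C5b, p)
  expect_gt(max(abs(Pb[[2]] - P[[2]])), 0)
  expect_error(build_pyramid(C3, C3, C5, p), "4:2:1")
})

test_that("focal loss matches its closed form and cross-entropy limit", {
  expect_lt(focal_loss(1 - 1e-9, 1, gamma = 2, alpha = 0.25), 1e-12)
  expect_equal(focal_loss(0.5, 1, gamma = 0, alpha = 1), log(2))
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha = 0.25),
               -0.25 * 0.1^2 * log(0.9))
  p <- seq(0.01, 0.99, by = 0.01)
  expect_lt(max(abs(focal_loss(p, 1, gamma = 0, alpha = 1) - (-log(p)))),
            1e-12)
  expect_lt(max(abs(focal_loss(p, 0, gamma = 0, alpha = 1) - (-log(1 - p)))),
            1e-12)
  expect_error(focal_loss(1, 1), "inside")
  expect_error(focal_loss(0.5, 1, gamma = -1), ">= 0")
})

test_that("smooth L1 matches its closed form on a grid", {
  d <- seq(-3, 3, by = 0.25)
  expect_equal(smooth_l1(d), ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5))
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(1), 0.5)
  expect_equal(smooth_l1(2), 1.5)
  # continuity at the branch point
  expect_equal(smooth_l1(1 - 1e-9), smooth_l1(1 + 1e-9), tolerance = 1e-8)
})

test_that("decoding respects threshold, suppression, and the 200-box cap", {
  cfg <- jdn_config()
  # empty: nothing above threshold
  cls <- list(array(-20, c(4, 4, 6)))
  reg <- list(array(0, c(4, 4, 24)))
  anchors <- list(make_anchors(4, 4, 8, 16))
  expect_equal(nrow(decode_detections(cls, reg, anchors)), 0L)
  # 96 identical high-score boxes collapse to one under NMS
  cls1 <- list(array(8, c(4, 4, 6)))
  reg1 <- list(array(0, c(4, 4, 24)))
  one <- make_anchors(4, 4, 8, 16)
  one$cx <- 20; one$cy <- 20; one$w <- 16; one$h <- 16
  expect_equal(nrow(decode_detections(cls1, reg1, list(one))), 1L)
  # 250 disjoint boxes above threshold: exactly the 200 best survive
  n <- 250L
  grid <- expand.grid(gx = 1:16, gy = 1:16)[1:n, ]
  aset <- data.frame(cx = grid$gx * 40, cy = grid$gy * 40, w = 16, h = 16,
                     anchor = 1L)
  scores <- seq(0.99, 0.2, length.out = n)
  clsn <- list(array(log(scores / (1 - scores)), c(n, 1, 1)))
  regn <- list(array(0, c(n, 1, 4)))
  out <- decode_detections(clsn, regn, list(aset), cap = 200L)
  expect_equal(nrow(out), 200L)
  expect_true(all(diff(out$score) <= 0))
  expect_equal(out$score[1], max(scores), tolerance = 1e-9)
  expect_gte(min(out$score), sort(scores, decreasing = TRUE)[200] - 1e-9)
})

test_that("boxes reduce to rounded junction points", {
  boxes <- data.frame(cx = c(10.4, 3.2), cy = c(20.6, 7.5), w = 16, h = 16,
                      score = c(0.9, 0.4), level = 3L)
  pts <- boxes_to_points(boxes)
  expect_equal(nrow(pts), 2L)
  expect_equal(pts$row[1], 21L)
  expect_equal(pts$col[1], 10L)
  expect_equal(pts$provenance, rep("detected", 2))
  expect_equal(pts$score, boxes$score)
  expect_equal(nrow(boxes_to_points(boxes[0, ])), 0L)
})

test_that("the cosine schedule hits its endpoints", {
  expect_equal(cosine_lr(0, 300, 0.01, 1e-4), 0.01)
  expect_equal(cosine_lr(300, 300, 0.01, 1e-4), 1e-4)
  expect_equal(cosine_lr(150, 300, 0.01, 1e-4), (0.01 + 1e-4) / 2)
})

test_that("the initial training loss equals an independent evaluation", {
  cfg <- jdn_config(base_channels = 4, fpn_channels = 8, head_convs = 1,
                    head_channels = 8, box_size = 16, seed = 3)
  model <- build_jdn(cfg)
  set.seed(2)
  img <- matrix(rbinom(128 * 128, 1, 0.1), 128, 128)
  jp <- junction_points(row = c(40L, 80L), col = c(50L, 90L))
  tg <- ns$jdn_targets(jp, 128L, cfg)
  fw <- ns$jdn_forward(model, img)
  lg <- ns$jdn_loss_grad(fw$cls, fw$reg, tg, cfg)
  # oracle: exported focal_loss + smooth_l1 summed over the same assignment
  npos <- max(1, sum(sapply(tg, function(t) sum(t$labels == 1L))))
  oracle <- 0
  for (l in 1:5) {
    sc <- as.numeric(fw$cls[[l]])
    pr <- pmin(pmax(1 / (1 + exp(-sc)), 1e-7), 1 - 1e-7)
    use <- tg[[l]]$labels >= 0
    oracle <- oracle + sum(focal_loss(pr[use], tg[[l]]$labels[use],
                                      cfg$gamma, cfg$alpha)) / npos
    pos <- which(tg[[l]]$labels == 1L)
    if (length(pos)) {
      d <- dim(fw$reg[[l]])
      rg <- matrix(fw$reg[[l]], ncol = d[3])
      ncell <- d[1] * d[2]
      aidx <- (pos - 1L) %/% ncell + 1L
      cidx <- (pos - 1L) %% ncell + 1L
      for (k in 1:4) {
        pred <- rg[cbind(cidx, (aidx - 1L) * 4L + k)]
        oracle <- oracle +
          sum(smooth_l1(pred - tg[[l]]$targets[pos, k])) / npos
      }
    }
  }
  expect_equal(lg$loss, oracle, tolerance = 1e-12)
})

test_that("detector gradients match finite differences", {
  cfg <- jdn_config(base_channels = 4, fpn_channels = 8, head_convs = 1,
                    head_channels = 8, box_size = 16, seed = 3)
  model <- build_jdn(cfg)
  set.seed(2)
  img <- matrix(runif(128 * 128), 128, 128)
  tg <- ns$jdn_targets(junction_points(row = 40L, col = 50L), 128L, cfg)
  loss_of <- function(m) {
    f <- ns$jdn_forward(m, img)
    ns$jdn_loss_grad(f$cls, f$reg, tg, cfg)$loss
  }
  fw <- ns$jdn_forward(model, img)
  lg <- ns$jdn_loss_grad(fw$cls, fw$reg, tg, cfg)
  gr <- ns$jdn_backward(model, fw$caches, lg$dcls, lg$dreg)
  v <- model$params$fpn$up54$W
  eps <- 1e-5
  for (i in sample(length(v), 3)) {
    mp <- model; mp$params$fpn$up54$W[i] <- v[i] + eps
    mm <- model; mm$params$fpn$up54$W[i] <- v[i] - eps
    num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
    expect_equal(gr$fpn$up54$W[i], num, tolerance = 1e-3)
  }
})

test_that("training requires data and records a decreasing loss", {
  model <- build_jdn(jdn_config(box_size = 16, seed = 1))
  expect_error(train_jdn(model, list()), "empty")
  ds <- jdn_toy_dataset(2)
  m2 <- train_jdn(model, ds, steps = 40)
  expect_length(m2$history, 40)
  expect_lt(mean(tail(m2$history, 5)), mean(head(m2$history, 5)))
})
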