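#' Junction detection network configuration
#'
#' An anchor-based one-stage detector (RetinaNet family): a residual
#' downsampling backbone producing C1-C5 (spatial size halved per level), a
#' feature pyramid P3-P7 built from C3-C5 by 1x1 laterals, x2
#' transposed-convolution upsampling with element-wise addition, and 3x3
#' output convolutions, plus classification and box-regression subnets shared
#' across levels. Anchors come in two scales `{1, sqrt(2)}` and three aspect
#' ratios `{1, 2, 0.5}` (6 per location); decoding keeps at most
#' `max_boxes = 200` detections. Training uses the focal loss for
#' classification, smooth L1 for regression, and momentum with cosine
#' learning-rate decay.
#'
#' @param base_channels backbone channel count at C1 (doubled per level).
#' @param fpn_channels pyramid channel count.
#' @param head_convs,head_channels subnet depth/width (the full-scale
#'   configuration uses 5 convolutions).
#' @param base_anchors base anchor lengths for P3..P7, pixels.
#' @param scales,ratios anchor scale and aspect-ratio sets.
#' @param box_size side of the square ground-truth box drawn around each
#'   junction point, pixels.
#' @param gamma,alpha focal-loss focusing and balance parameters.
#' @param score_thresh,nms_iou,max_boxes decoding parameters.
#' @param lr_max,lr_min,momentum optimizer settings (cosine decay endpoints).
#' @param clip_norm global gradient-norm clip (stabilizes the focal loss on
#'   small batches).
#' @param seed integer seed for initialization and training order.
#' @return list of class `jdn_config`.
#' @export
jdn_config <- function(base_channels = 8L, fpn_channels = 16L,
                       head_convs = 2L, head_channels = 16L,
                       base_anchors = c(16, 32, 64, 128, 256),
                       scales = c(1, sqrt(2)), ratios = c(1, 2, 0.5),
                       box_size = 24, gamma = 2, alpha = 0.25,
                       score_thresh = 0.05, nms_iou = 0.3, max_boxes = 200L,
                       lr_max = 0.01, lr_min = 1e-4, momentum = 0.9,
                       clip_norm = 5, seed = 1L) {
  if (any(base_anchors <= 0)) stop("base anchors must be positive")
  if (length(base_anchors) != 5) stop("need one base anchor per level P3..P7")
  structure(list(base_channels = as.integer(base_channels),
                 fpn_channels = as.integer(fpn_channels),
                 head_convs = as.integer(head_convs),
                 head_channels = as.integer(head_channels),
                 base_anchors = base_anchors, scales = scales,
                 ratios = ratios, box_size = box_size, gamma = gamma,
                 alpha = alpha, score_thresh = score_thresh,
                 nms_iou = nms_iou, max_boxes = as.integer(max_boxes),
                 lr_max = lr_max, lr_min = lr_min, momentum = momentum,
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "jdn_config")
}

#' Focal loss
#'
#' `FL = -alpha (1 - p_t)^gamma log(p_t)` with `p_t = p` for positives and
#' `1 - p` for negatives; the negative branch is weighted by `1 - alpha`.
#' At `gamma = 0`, `alpha = 1` this reduces to plain cross-entropy.
#'
#' @param p predicted probabilities in the open interval (0, 1).
#' @param y labels in {0, 1}.
#' @param gamma focusing parameter (>= 0).
#' @param alpha positive-class balance in (0, 1].
#' @return vector of per-example losses (>= 0).
#' @export
focal_loss <- function(p, y, gamma = 2, alpha = 0.25) {
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly inside (0, 1)")
  if (gamma < 0) stop("gamma must be >= 0")
  n <- max(length(p), length(y))
  p <- rep_len(p, n)
  y <- rep_len(y, n)
  pt <- ifelse(y == 1, p, 1 - p)
  a <- ifelse(y == 1, alpha, 1 - alpha)
  # alpha = 1 means unweighted on both branches (plain cross-entropy scaling)
  if (alpha == 1) a <- 1
  -a * (1 - pt)^gamma * log(pt)
}

#' Smooth L1 loss
#'
#' `0.5 d^2` for `|d| < 1`, `|d| - 0.5` otherwise; continuous with continuous
#' first derivative at `|d| = 1`.
#'
#' @param d numeric residuals.
#' @return vector of losses (>= 0).
#' @export
smooth_l1 <- function(d) ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)

smooth_l1_grad <- function(d) ifelse(abs(d) < 1, d, sign(d))

# d(focal)/d(logit) for sigmoid probabilities
focal_grad_logit <- function(p, y, gamma, alpha) {
  eps <- 1e-12
  pos <- alpha * (1 - p)^gamma * (gamma * p * log(pmax(p, eps)) + p - 1)
  neg <- (1 - alpha) * p^gamma * (p - gamma * (1 - p) * log(pmax(1 - p, eps)))
  ifelse(y == 1, pos, neg)
}

#' Generate anchor boxes for a pyramid level
#'
#' Six anchors per feature cell (2 scales x 3 aspect ratios) with the
#' area-preserving parameterization `H = BA * S / sqrt(AR)`,
#' `W = BA * S * sqrt(AR)`; centers sit at feature-cell centers mapped to
#' image coordinates by the level stride.
#'
#' @param feat_h,feat_w feature-map size in cells.
#' @param stride level stride in pixels.
#' @param base_anchor base anchor length `BA`, pixels (> 0).
#' @param scales,ratios scale set `S` and aspect-ratio set `AR`.
#' @return data.frame with columns `cx`, `cy`, `w`, `h`, `anchor`; rows are
#'   ordered anchor-major, cells column-major (rows fastest), matching the
#'   network's output array layout.
#' @export
make_anchors <- function(feat_h, feat_w, stride, base_anchor,
                         scales = c(1, sqrt(2)), ratios = c(1, 2, 0.5)) {
  if (base_anchor <= 0) stop("base anchor must be positive")
  cys <- (seq_len(feat_h) - 0.5) * stride + 0.5
  cxs <- (seq_len(feat_w) - 0.5) * stride + 0.5
  grid_cy <- rep(cys, times = feat_w)
  grid_cx <- rep(cxs, each = feat_h)
  combos <- data.frame(scale = rep(scales, times = length(ratios)),
                       ratio = rep(ratios, each = length(scales)))
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(a) {
    s <- combos$scale[a]; ar <- combos$ratio[a]
    data.frame(cx = grid_cx, cy = grid_cy,
               w = base_anchor * s * sqrt(ar),
               h = base_anchor * s / sqrt(ar),
               anchor = a)
  }))
  rownames(out) <- NULL
  out
}

res_init <- function(cin, cout, stride) {
  mid <- max(4L, cout %/% 2L)
  p <- list(r1 = conv_init(cin, mid, 1L),
            r2 = conv_init(mid, mid, 3L),
            r3 = conv_init(mid, cout, 1L),
            stride = stride, cin = cin, cout = cout)
  if (stride != 1L || cin != cout) p$sc <- conv_init(cin, cout, 1L)
  p
}

res_fwd <- function(x, p) {
  a1 <- conv_fwd(x, p$r1)
  a1r <- relu_fwd(a1$y)
  a2 <- conv_fwd(a1r$y, p$r2, stride = p$stride, pad = 1L)
  a2r <- relu_fwd(a2$y)
  a3 <- conv_fwd(a2r$y, p$r3)
  if (!is.null(p$sc)) {
    sc <- conv_fwd(x, p$sc, stride = p$stride, pad = 0L)
    idn <- sc$y
    sc_cache <- sc$cache
  } else {
    idn <- x
    sc_cache <- NULL
  }
  out <- relu_fwd(a3$y + idn)
  list(y = out$y,
       cache = list(a1 = a1$cache, a1r = a1r$cache, a2 = a2$cache,
                    a2r = a2r$cache, a3 = a3$cache, sc = sc_cache,
                    outr = out$cache))
}

res_bwd <- function(dy, cache, p) {
  d <- relu_bwd(dy, cache$outr)
  b3 <- conv_bwd(d, cache$a3, p$r3)
  d2 <- relu_bwd(b3$dx, cache$a2r)
  b2 <- conv_bwd(d2, cache$a2, p$r2)
  d1 <- relu_bwd(b2$dx, cache$a1r)
  b1 <- conv_bwd(d1, cache$a1, p$r1)
  g <- list(r1 = b1$g, r2 = b2$g, r3 = b3$g)
  dx <- b1$dx
  if (!is.null(p$sc)) {
    bsc <- conv_bwd(d, cache$sc, p$sc)
    g$sc <- bsc$g
    dx <- dx + bsc$dx
  } else {
    dx <- dx + d
  }
  list(dx = dx, g = g)
}

#' Residual block (forward)
#'
#' `y = ReLU(R(x) + I(x))` where the residual function `R` is the conv
#' sequence 1x1, 3x3, 1x1 with interleaved ReLU, and the identity map `I` is
#' a dimension-matching 1x1 shortcut (plain identity when shapes already
#' match). A stride-2 middle convolution halves the spatial size.
#'
#' @param x H x W x C feature array.
#' @param params parameters from the internal initializer (networks built by
#'   [build_jdn()] store them under `params$backbone`).
#' @return feature array with the block's output shape.
#' @export
residual_block <- function(x, params) res_fwd(x, params)$y

pyramid_init <- function(cin3, cin4, cin5, f) {
  list(lat3 = conv_init(cin3, f, 1L), lat4 = conv_init(cin4, f, 1L),
       lat5 = conv_init(cin5, f, 1L),
       up54 = conv_init(f, f, 3L), up43 = conv_init(f, f, 3L),
       p3 = conv_init(f, f, 3L), p4 = conv_init(f, f, 3L),
       p5 = conv_init(f, f, 3L), p6 = conv_init(f, f, 3L),
       p7 = conv_init(f, f, 3L))
}

pyr_fwd <- function(C3, C4, C5, p) {
  d3 <- dim(C3); d4 <- dim(C4); d5 <- dim(C5)
  if (!(all(d3[1:2] == 2 * d4[1:2]) && all(d4[1:2] == 2 * d5[1:2])))
    stop("C3, C4, C5 spatial sizes must be in ratio 4:2:1")
  l5 <- conv_fwd(C5, p$lat5, pad = 0L)
  m5 <- l5$y
  u5 <- convt_fwd(m5, p$up54, stride = 2L, pad = 1L, outpad = 1L)
  l4 <- conv_fwd(C4, p$lat4, pad = 0L)
  m4 <- l4$y + u5$y
  u4 <- convt_fwd(m4, p$up43, stride = 2L, pad = 1L, outpad = 1L)
  l3 <- conv_fwd(C3, p$lat3, pad = 0L)
  m3 <- l3$y + u4$y
  o3 <- conv_fwd(m3, p$p3)
  o4 <- conv_fwd(m4, p$p4)
  o5 <- conv_fwd(m5, p$p5)
  o6 <- conv_fwd(o5$y, p$p6, stride = 2L, pad = 1L)
  o7 <- conv_fwd(o6$y, p$p7, stride = 2L, pad = 1L)
  list(P = list(o3$y, o4$y, o5$y, o6$y, o7$y),
       cache = list(l3 = l3$cache, l4 = l4$cache, l5 = l5$cache,
                    u5 = u5$cache, u4 = u4$cache, o3 = o3$cache,
                    o4 = o4$cache, o5 = o5$cache, o6 = o6$cache,
                    o7 = o7$cache))
}

pyr_bwd <- function(dP, cache, p) {
  g <- list()
  b7 <- conv_bwd(dP[[5]], cache$o7, p$p7)
  g$p7 <- b7$g
  d6 <- dP[[4]] + b7$dx
  b6 <- conv_bwd(d6, cache$o6, p$p6)
  g$p6 <- b6$g
  d5o <- dP[[3]] + b6$dx
  b5 <- conv_bwd(d5o, cache$o5, p$p5)
  g$p5 <- b5$g
  b4 <- conv_bwd(dP[[2]], cache$o4, p$p4)
  g$p4 <- b4$g
  b3 <- conv_bwd(dP[[1]], cache$o3, p$p3)
  g$p3 <- b3$g
  dm3 <- b3$dx
  bl3 <- conv_bwd(dm3, cache$l3, p$lat3)
  g$lat3 <- bl3$g
  bu4 <- convt_bwd(dm3, cache$u4, p$up43)
  g$up43 <- bu4$g
  dm4 <- b4$dx + bu4$dx
  bl4 <- conv_bwd(dm4, cache$l4, p$lat4)
  g$lat4 <- bl4$g
  bu5 <- convt_bwd(dm4, cache$u5, p$up54)
  g$up54 <- bu5$g
  dm5 <- b5$dx + bu5$dx
  bl5 <- conv_bwd(dm5, cache$l5, p$lat5)
  g$lat5 <- bl5$g
  list(dC3 = bl3$dx, dC4 = bl4$dx, dC5 = bl5$dx, g = g)
}

#' Build a feature pyramid from backbone levels (forward)
#'
#' `M_i = conv1x1(C_i) + upsample2(M_{i+1})` (transposed 3x3 convolution,
#' element-wise addition; the top level has no upsampled term),
#' `P_i = conv3x3(M_i)` for i in 3..5, and `P6`/`P7` by stride-2 3x3
#' convolutions of `P5`/`P6`.
#'
#' @param C3,C4,C5 backbone feature arrays with spatial sizes in ratio 4:2:1.
#' @param params pyramid parameters (`params$fpn` of a built network).
#' @return list of the five pyramid maps `P3..P7`.
#' @export
build_pyramid <- function(C3, C4, C5, params) pyr_fwd(C3, C4, C5, params)$P

head_init <- function(f, nconvs, hc, cout, final_bias) {
  convs <- list()
  cin <- f
  for (i in seq_len(nconvs)) {
    convs[[i]] <- conv_init(cin, hc, 3L)
    cin <- hc
  }
  fin <- conv_init(cin, cout, 3L)
  fin$b <- rep(final_bias, cout)
  list(convs = convs, final = fin)
}

head_fwd <- function(x, hp) {
  caches <- list()
  cur <- x
  for (i in seq_along(hp$convs)) {
    cv <- conv_fwd(cur, hp$convs[[i]])
    rl <- relu_fwd(cv$y)
    caches[[i]] <- list(conv = cv$cache, relu = rl$cache)
    cur <- rl$y
  }
  fin <- conv_fwd(cur, hp$final)
  list(y = fin$y, cache = list(convs = caches, final = fin$cache))
}

head_bwd <- function(dy, cache, hp) {
  bf <- conv_bwd(dy, cache$final, hp$final)
  g <- list(convs = vector("list", length(hp$convs)), final = bf$g)
  d <- bf$dx
  for (i in rev(seq_along(hp$convs))) {
    dr <- relu_bwd(d, cache$convs[[i]]$relu)
    bc <- conv_bwd(dr, cache$convs[[i]]$conv, hp$convs[[i]])
    g$convs[[i]] <- bc$g
    d <- bc$dx
  }
  list(dx = d, g = g)
}

#' Build a junction detection network
#'
#' @param config a [jdn_config()].
#' @return list of class `jdn_model` with `params` (backbone, fpn, heads) and
#'   `config`. The classification head's final bias is initialized so initial
#'   foreground probability is about 0.01, the usual focal-loss prior.
#' @export
build_jdn <- function(config = jdn_config()) {
  withr::with_seed(config$seed, {
    b <- config$base_channels
    ch <- b * 2^(0:4)
    backbone <- list(stem = conv_init(1L, ch[1], 3L))
    prev <- ch[1]
    for (i in 1:5) {
      backbone[[paste0("res", i)]] <- res_init(prev, ch[i], stride = 2L)
      prev <- ch[i]
    }
    f <- config$fpn_channels
    na <- length(config$scales) * length(config$ratios)
    params <- list(backbone = backbone,
                   fpn = pyramid_init(ch[3], ch[4], ch[5], f),
                   cls_head = head_init(f, config$head_convs,
                                        config$head_channels, na,
                                        final_bias = -log(99)),
                   reg_head = head_init(f, config$head_convs,
                                        config$head_channels, 4L * na,
                                        final_bias = 0))
    structure(list(params = params, config = config), class = "jdn_model")
  })
}

#' @export
print.jdn_model <- function(x, ...) {
  cat(sprintf("<jdn_model base=%d fpn=%d params=%d>\n",
              x$config$base_channels, x$config$fpn_channels, n_params(x)))
  invisible(x)
}

jdn_forward <- function(model, x, training = FALSE) {
  p <- model$params
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix")
  if (any(d[1:2] %% 128 != 0))
    stop("input size must be divisible by 128 (stride of P7)")
  dim(x) <- c(d[1], d[2], 1L)
  bb <- p$backbone
  stem <- conv_fwd(x, bb$stem)
  cur <- stem$y
  Cs <- vector("list", 5)
  rcaches <- vector("list", 5)
  for (i in 1:5) {
    r <- res_fwd(cur, bb[[paste0("res", i)]])
    Cs[[i]] <- r$y
    rcaches[[i]] <- r$cache
    cur <- r$y
  }
  pyr <- pyr_fwd(Cs[[3]], Cs[[4]], Cs[[5]], p$fpn)
  cls <- vector("list", 5)
  reg <- vector("list", 5)
  ccache <- vector("list", 5)
  rgcache <- vector("list", 5)
  for (l in 1:5) {
    hc <- head_fwd(pyr$P[[l]], p$cls_head)
    hr <- head_fwd(pyr$P[[l]], p$reg_head)
    cls[[l]] <- hc$y
    reg[[l]] <- hr$y
    ccache[[l]] <- hc$cache
    rgcache[[l]] <- hr$cache
  }
  list(cls = cls, reg = reg,
       caches = list(stem = stem$cache, res = rcaches, pyr = pyr$cache,
                     cls = ccache, reg = rgcache))
}

jdn_backward <- function(model, caches, dcls, dreg) {
  p <- model$params
  g <- tree_zeros(p)
  dP <- vector("list", 5)
  for (l in 1:5) {
    bc <- head_bwd(dcls[[l]], caches$cls[[l]], p$cls_head)
    br <- head_bwd(dreg[[l]], caches$reg[[l]], p$reg_head)
    g$cls_head <- grads_add(if (l == 1) NULL else g$cls_head, bc$g)
    g$reg_head <- grads_add(if (l == 1) NULL else g$reg_head, br$g)
    dP[[l]] <- bc$dx + br$dx
  }
  pb <- pyr_bwd(dP, caches$pyr, p$fpn)
  g$fpn <- pb$g
  dC <- list(NULL, NULL, pb$dC3, pb$dC4, pb$dC5)
  cur <- NULL
  for (i in 5:1) {
    dy <- dC[[i]]
    if (!is.null(cur)) dy <- if (is.null(dy)) cur else dy + cur
    if (is.null(dy)) stop("internal: no gradient reached backbone level ", i)
    rb <- res_bwd(dy, caches$res[[i]], p$backbone[[paste0("res", i)]])
    g$backbone[[paste0("res", i)]] <- rb$g
    cur <- rb$dx
  }
  sb <- conv_bwd(cur, caches$stem, p$backbone$stem)
  g$backbone$stem <- sb$g
  g
}

jdn_anchors <- function(config, image_size) {
  strides <- 2^(3:7)
  lapply(1:5, function(l) {
    fs <- image_size %/% strides[l]
    make_anchors(fs, fs, strides[l], config$base_anchors[l],
                 config$scales, config$ratios)
  })
}

box_iou <- function(a, b) {
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  iw <- pmax(outer(ax1, bx1, pmin) - outer(ax0, bx0, pmax), 0)
  ih <- pmax(outer(ay1, by1, pmin) - outer(ay0, by0, pmax), 0)
  inter <- iw * ih
  inter / (outer(a$w * a$h, b$w * b$h, "+") - inter)
}

# anchor labels (1 pos, 0 neg, -1 ignore) and regression targets per level
jdn_targets <- function(junctions, image_size, config) {
  anchors <- jdn_anchors(config, image_size)
  gt <- if (nrow(junctions)) {
    data.frame(cx = junctions$col, cy = junctions$row,
               w = config$box_size, h = config$box_size)
  } else NULL
  lapply(anchors, function(a) {
    n <- nrow(a)
    lab <- rep(0L, n)
    tgt <- matrix(0, n, 4)
    if (!is.null(gt)) {
      iou <- box_iou(a, gt)
      best <- apply(iou, 1, max)
      bidx <- max.col(iou)
      lab[best >= 0.4] <- -1L
      lab[best >= 0.5] <- 1L
      # guarantee every ground-truth box its best anchor
      for (j in seq_len(nrow(gt))) {
        i <- which.max(iou[, j])
        if (iou[i, j] > 0.1) { lab[i] <- 1L; bidx[i] <- j }
      }
      pos <- which(lab == 1L)
      if (length(pos)) {
        gsel <- gt[bidx[pos], ]
        tgt[pos, 1] <- (gsel$cx - a$cx[pos]) / a$w[pos]
        tgt[pos, 2] <- (gsel$cy - a$cy[pos]) / a$h[pos]
        tgt[pos, 3] <- log(gsel$w / a$w[pos])
        tgt[pos, 4] <- log(gsel$h / a$h[pos])
      }
    }
    list(labels = lab, targets = tgt, anchors = a)
  })
}

# total loss and per-level gradients w.r.t. the raw head outputs
jdn_loss_grad <- function(cls, reg, targets, config) {
  total_pos <- max(1, sum(vapply(targets, function(t) sum(t$labels == 1L),
                                 numeric(1))))
  loss <- 0
  dcls <- vector("list", 5)
  dreg <- vector("list", 5)
  for (l in 1:5) {
    sc <- as.numeric(cls[[l]])            # (cell, anchor) column-major
    lab <- targets[[l]]$labels
    pr <- 1 / (1 + exp(-sc))
    pr <- pmin(pmax(pr, 1e-7), 1 - 1e-7)
    use <- lab >= 0L
    fl <- focal_loss(pr[use], lab[use], config$gamma, config$alpha)
    loss <- loss + sum(fl) / total_pos
    dsc <- numeric(length(sc))
    dsc[use] <- focal_grad_logit(pr[use], lab[use], config$gamma,
                                 config$alpha) / total_pos
    dc <- array(dsc, dim(cls[[l]]))
    # regression on positives
    d <- dim(reg[[l]])
    na <- d[3] %/% 4L
    rg <- matrix(reg[[l]], ncol = d[3])
    drg <- matrix(0, nrow(rg), d[3])
    pos <- which(lab == 1L)
    if (length(pos)) {
      ncell <- d[1] * d[2]
      aidx <- (pos - 1L) %/% ncell + 1L   # which anchor
      cidx <- (pos - 1L) %% ncell + 1L    # which cell
      for (k in 1:4) {
        col <- (aidx - 1L) * 4L + k
        pred <- rg[cbind(cidx, col)]
        dres <- pred - targets[[l]]$targets[pos, k]
        loss <- loss + sum(smooth_l1(dres)) / total_pos
        drg[cbind(cidx, col)] <- smooth_l1_grad(dres) / total_pos
      }
    }
    dcls[[l]] <- dc
    dreg[[l]] <- array(drg, d)
  }
  list(loss = loss, dcls = dcls, dreg = dreg)
}

#' Decode raw detector outputs into detection boxes
#'
#' Applies regression deltas to the anchors, drops boxes below the score
#' threshold, runs non-maximum suppression at the configured IoU, and returns
#' at most `cap` boxes ordered by descending score.
#'
#' @param cls,reg lists of per-level classification/regression arrays from
#'   the network forward pass.
#' @param anchors list of per-level anchor tables (see [make_anchors()]).
#' @param score_thresh minimum sigmoid score.
#' @param nms_iou suppression IoU threshold.
#' @param cap maximum number of boxes returned (200 by default: junction
#'   counts on fundus images stay below this).
#' @return data.frame with columns `cx`, `cy`, `w`, `h`, `score`, `level`.
#' @export
decode_detections <- function(cls, reg, anchors, score_thresh = 0.05,
                              nms_iou = 0.3, cap = 200L) {
  all <- list()
  for (l in seq_along(cls)) {
    sc <- 1 / (1 + exp(-as.numeric(cls[[l]])))
    a <- anchors[[l]]
    d <- dim(reg[[l]])
    ncell <- d[1] * d[2]
    na <- d[3] %/% 4L
    rg <- matrix(reg[[l]], ncol = d[3])
    keep <- which(sc >= score_thresh)
    if (!length(keep)) next
    aidx <- (keep - 1L) %/% ncell + 1L
    cidx <- (keep - 1L) %% ncell + 1L
    dx <- rg[cbind(cidx, (aidx - 1L) * 4L + 1L)]
    dy <- rg[cbind(cidx, (aidx - 1L) * 4L + 2L)]
    dw <- pmin(rg[cbind(cidx, (aidx - 1L) * 4L + 3L)], 4)
    dh <- pmin(rg[cbind(cidx, (aidx - 1L) * 4L + 4L)], 4)
    all[[length(all) + 1L]] <- data.frame(
      cx = a$cx[keep] + dx * a$w[keep],
      cy = a$cy[keep] + dy * a$h[keep],
      w = a$w[keep] * exp(dw),
      h = a$h[keep] * exp(dh),
      score = sc[keep], level = l + 2L)
  }
  if (!length(all))
    return(data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), score = numeric(), level = integer()))
  boxes <- do.call(rbind, all)
  keep <- cpp_nms(boxes$cx, boxes$cy, boxes$w, boxes$h, boxes$score, nms_iou)
  boxes <- boxes[keep, , drop = FALSE]
  boxes <- boxes[seq_len(min(nrow(boxes), cap)), , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}

#' Convert detection boxes to junction points
#'
#' Each box yields its center rounded to the nearest pixel, with the score
#' copied and provenance `"detected"`.
#'
#' @param boxes data.frame from [decode_detections()].
#' @return a [junction_points()] table.
#' @export
boxes_to_points <- function(boxes) {
  keep <- round(boxes$cy) >= 1 & round(boxes$cx) >= 1
  boxes <- boxes[keep, , drop = FALSE]
  if (!nrow(boxes)) return(junction_points(provenance = "detected"))
  junction_points(row = round(boxes$cy), col = round(boxes$cx),
                  kind = "unknown", score = pmin(pmax(boxes$score, 0), 1),
                  provenance = "detected")
}

jdn_prepare_image <- function(image) {
  m <- if (inherits(image, "fundus_image")) as_gray(image) / 255 else {
    mm <- unclass(as.matrix(image))
    if (max(mm) > 1) mm / 255 else mm * 1.0
  }
  m
}

#' Train a junction detection network
#'
#' Total loss is focal (classification) + smooth L1 (box regression),
#' normalized by the number of positive anchors, minimized by SGD with
#' momentum under cosine learning-rate decay. One image per step, cycling
#' through the dataset in seeded random order.
#'
#' @param model a `jdn_model` from [build_jdn()].
#' @param dataset list of `list(image=, junctions=)`; images are binary
#'   vessel masks (the input representation with the best detection scores)
#'   or grayscale images, square with side divisible by 128.
#' @param steps number of optimization steps.
#' @return the model with trained `params` plus `history` (loss per step).
#' @export
train_jdn <- function(model, dataset, steps = 300L) {
  stopifnot(inherits(model, "jdn_model"))
  if (!length(dataset)) stop("empty training dataset")
  cfg <- model$config
  prep <- lapply(dataset, function(s) {
    m <- jdn_prepare_image(s$image)
    list(img = m, targets = jdn_targets(s$junctions, nrow(m), cfg))
  })
  state <- sgdm_init(model$params)
  history <- numeric(steps)
  withr::with_seed(cfg$seed + 1L, {
    order_pool <- integer(0)
    for (t in seq_len(steps)) {
      if (!length(order_pool)) order_pool <- sample(length(prep))
      j <- order_pool[1]
      order_pool <- order_pool[-1]
      fw <- jdn_forward(model, prep[[j]]$img, training = TRUE)
      lg <- jdn_loss_grad(fw$cls, fw$reg, prep[[j]]$targets, cfg)
      history[t] <- lg$loss
      gr <- jdn_backward(model, fw$caches, lg$dcls, lg$dreg)
      if (is.finite(cfg$clip_norm) && cfg$clip_norm > 0) {
        ss <- 0
        apply_update(gr, function(x, path) { ss <<- ss + sum(x^2); x })
        gn <- sqrt(ss)
        if (gn > cfg$clip_norm)
          gr <- apply_update(gr, function(x, path) x * (cfg$clip_norm / gn))
      }
      lr <- cosine_lr(t - 1L, steps, cfg$lr_max, cfg$lr_min)
      st <- sgdm_step(model$params, gr, state, lr, cfg$momentum)
      model$params <- st$params
      state <- st$state
    }
  })
  model$history <- history
  model
}

#' Detect junction points with a trained detector
#'
#' Runs the network, decodes boxes (score threshold, NMS, 200-box cap) and
#' reduces them to points.
#'
#' @param model a trained `jdn_model`.
#' @param image binary vessel mask (preferred input representation) or
#'   grayscale image, side divisible by 128.
#' @return a [junction_points()] table with provenance `"detected"`.
#' @export
detect_junctions_jdn <- function(model, image) {
  m <- jdn_prepare_image(image)
  fw <- jdn_forward(model, m, training = FALSE)
  anchors <- jdn_anchors(model$config, nrow(m))
  boxes <- decode_detections(fw$cls, fw$reg, anchors,
                             model$config$score_thresh,
                             model$config$nms_iou, model$config$max_boxes)
  boxes_to_points(boxes)
}
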