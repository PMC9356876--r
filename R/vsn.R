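#' Vessel segmentation network configuration
#'
#' An encoder-decoder segmentation network (U-Net family) with two structural
#' additions: a multi-input module that feeds the resized raw image into the
#' front of every encoder level, and a connected convolution module that
#' concatenates each level's input feature map with its second
#' conv-batchnorm-ReLU stage. Downsampling halves the spatial size per level;
#' transposed-convolution upsampling restores it, with same-level skip
#' concatenations. The per-pixel head has 2 logits (background/vessel) under
#' a softmax cross-entropy loss with the Adam optimizer.
#'
#' @param levels number of down-steps (>= 2); inputs must be divisible by
#'   `2^levels`.
#' @param base base channel count (>= 4), doubled per level.
#' @param use_multi_input,use_connected_conv module flags.
#' @param mi_channels channels of the image branch in the multi-input module.
#' @param epochs default training epochs (100 for full-scale training).
#' @param lr learning rate (5e-6 for full-scale training; desk-scale runs use
#'   a larger value).
#' @param batch_size gradient-accumulation batch size.
#' @param seed integer seed for weight initialization and training order.
#' @return list of class `vsn_config`. Optimizer is Adam and the loss is
#'   per-pixel cross entropy; both are fixed.
#' @export
vsn_config <- function(levels = 4L, base = 16L, use_multi_input = TRUE,
                       use_connected_conv = TRUE, mi_channels = 4L,
                       epochs = 100L, lr = 5e-6, batch_size = 2L, seed = 1L) {
  if (levels < 2) stop("levels must be >= 2")
  if (base < 4) stop("base channels must be >= 4")
  if (lr <= 0) stop("learning rate must be > 0")
  structure(list(levels = as.integer(levels), base = as.integer(base),
                 use_multi_input = isTRUE(use_multi_input),
                 use_connected_conv = isTRUE(use_connected_conv),
                 mi_channels = as.integer(mi_channels),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 optimizer = "adam", loss = "cross entropy",
                 seed = as.integer(seed)),
            class = "vsn_config")
}

block_init <- function(cin, ch, connected) {
  list(c1 = conv_init(cin, ch, 3L), bn1 = bn_init(ch),
       c2 = conv_init(ch, ch, 3L), bn2 = bn_init(ch),
       cin = cin, ch = ch, connected = connected)
}

block_out_ch <- function(bp) if (bp$connected) bp$cin + bp$ch else bp$ch

block_fwd <- function(x, bp, training) {
  f1c <- conv_fwd(x, bp$c1)
  f1b <- bn_fwd(f1c$y, bp$bn1, training)
  f1r <- relu_fwd(f1b$y)
  f2c <- conv_fwd(f1r$y, bp$c2)
  f2b <- bn_fwd(f2c$y, bp$bn2, training)
  f2r <- relu_fwd(f2b$y)
  y <- if (bp$connected) concat_c(x, f2r$y) else f2r$y
  list(y = y,
       cache = list(f1c = f1c$cache, f1b = f1b$cache, f1r = f1r$cache,
                    f2c = f2c$cache, f2b = f2b$cache, f2r = f2r$cache),
       p = list(bn1 = f1b$p, bn2 = f2b$p))
}

block_bwd <- function(dy, cache, bp) {
  if (bp$connected) {
    sp <- split_c(dy, bp$cin)
    dx_direct <- sp$a
    d2 <- sp$b
  } else {
    dx_direct <- 0
    d2 <- dy
  }
  d2 <- relu_bwd(d2, cache$f2r)
  b2 <- bn_bwd(d2, cache$f2b, bp$bn2)
  c2 <- conv_bwd(b2$dx, cache$f2c, bp$c2)
  d1 <- relu_bwd(c2$dx, cache$f1r)
  b1 <- bn_bwd(d1, cache$f1b, bp$bn1)
  c1 <- conv_bwd(b1$dx, cache$f1c, bp$c1)
  list(dx = c1$dx + dx_direct,
       g = list(c1 = c1$g, bn1 = b1$g, c2 = c2$g, bn2 = b2$g))
}

#' Connected convolution module (forward)
#'
#' Two successive conv(3x3) + batch-norm + ReLU stages whose second output is
#' concatenated with the block input, so the output has
#' `cin + ch` channels.
#'
#' @param x H x W x C feature array.
#' @param params block parameters from the internal initializer; networks
#'   built by [build_vsn()] store them under `params$enc[[i]]$block`.
#' @param training logical; batch statistics vs running statistics.
#' @return H x W x (C + ch) feature array.
#' @export
connected_conv_block <- function(x, params, training = FALSE) {
  if (!isTRUE(params$connected))
    stop("params describe a plain (non-connected) block")
  block_fwd(x, params, training)$y
}

#' Multi-input fusion (forward)
#'
#' Resizes the preprocessed image to the spatial size of a level's features
#' (mean pooling by the level's downsampling factor), applies a 3x3
#' convolution + ReLU, and concatenates the result with the level's input
#' features along channels.
#'
#' @param image numeric matrix (preprocessed image, values in `[0, 1]`).
#' @param features H x W x C feature array at the level's resolution.
#' @param params multi-input conv parameters (`params$enc[[i]]$mi` of a built
#'   network).
#' @return H x W x (C + mi_channels) feature array.
#' @export
multi_input_fuse <- function(image, features, params) {
  d <- dim(features)
  img <- image
  while (nrow(img) > d[1]) img <- pool2_mean(img)
  if (!identical(dim(img), d[1:2]))
    stop("image cannot be pooled to the feature map's spatial size")
  dim(img) <- c(d[1], d[2], 1L)
  br <- relu_fwd(conv_fwd(img, params)$y)
  concat_c(features, br$y)
}

#' Build a vessel segmentation network
#'
#' @param config a [vsn_config()].
#' @return list of class `vsn_model` with `params`, `config`, and channel
#'   bookkeeping. Weights are He-initialized under `config$seed`.
#' @export
build_vsn <- function(config = vsn_config()) {
  L <- config$levels
  B <- config$base
  withr::with_seed(config$seed, {
    ch <- B * 2^(0:L) # level channels C_i, i = 1..L+1
    enc <- vector("list", L + 1L)
    out_ch <- numeric(L + 1L)
    # level 1: stem + block
    stem <- conv_init(1L, B, 3L)
    enc[[1]] <- list(block = block_init(B, ch[1], config$use_connected_conv))
    out_ch[1] <- block_out_ch(enc[[1]]$block)
    for (i in 2:(L + 1L)) {
      lvl <- list(down = conv_init(out_ch[i - 1], ch[i], 3L),
                  dbn = bn_init(ch[i]))
      cin <- ch[i]
      if (config$use_multi_input) {
        lvl$mi <- conv_init(1L, config$mi_channels, 3L)
        cin <- cin + config$mi_channels
      }
      lvl$block <- block_init(cin, ch[i], config$use_connected_conv)
      enc[[i]] <- lvl
      out_ch[i] <- block_out_ch(lvl$block)
    }
    dec <- vector("list", L)
    prev <- out_ch[L + 1L]
    for (i in L:1) {
      dec[[i]] <- list(up = conv_init(prev, ch[i], 2L),
                       c1 = conv_init(ch[i] + out_ch[i], ch[i], 3L),
                       bn1 = bn_init(ch[i]),
                       c2 = conv_init(ch[i], ch[i], 3L),
                       bn2 = bn_init(ch[i]))
      prev <- ch[i]
    }
    head <- conv_init(ch[1], 2L, 1L)
    structure(list(params = list(stem = stem, enc = enc, dec = dec,
                                 head = head),
                   config = config, out_ch = out_ch),
              class = "vsn_model")
  })
}

#' @export
print.vsn_model <- function(x, ...) {
  cat(sprintf("<vsn_model levels=%d base=%d params=%d multi_input=%s connected_conv=%s>\n",
              x$config$levels, x$config$base, n_params(x),
              x$config$use_multi_input, x$config$use_connected_conv))
  invisible(x)
}

vsn_forward <- function(model, x, training = FALSE) {
  p <- model$params
  cfg <- model$config
  L <- cfg$levels
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix")
  if (any(d[1:2] %% 2^L != 0))
    stop(sprintf("input size must be divisible by 2^levels = %d", 2^L))
  img <- x
  dim(x) <- c(d[1], d[2], 1L)
  caches <- list(enc = vector("list", L + 1L), dec = vector("list", L))
  stem <- conv_fwd(x, p$stem)
  enc_out <- vector("list", L + 1L)
  # encoder
  b1 <- block_fwd(stem$y, p$enc[[1]]$block, training)
  p$enc[[1]]$block$bn1 <- b1$p$bn1; p$enc[[1]]$block$bn2 <- b1$p$bn2
  enc_out[[1]] <- b1$y
  caches$stem <- stem$cache
  caches$enc[[1]] <- list(block = b1$cache)
  imgs <- list(img)
  for (i in 2:(L + 1L)) {
    lvl <- p$enc[[i]]
    dn <- conv_fwd(enc_out[[i - 1]], lvl$down, stride = 2L, pad = 1L)
    dbn <- bn_fwd(dn$y, lvl$dbn, training)
    p$enc[[i]]$dbn <- dbn$p
    dr <- relu_fwd(dbn$y)
    feat <- dr$y
    ci <- list(down = dn$cache, dbn = dbn$cache, drelu = dr$cache)
    if (cfg$use_multi_input) {
      imgs[[i]] <- pool2_mean(imgs[[i - 1]])
      im <- imgs[[i]]
      dim(im) <- c(nrow(im), ncol(im), 1L)
      mic <- conv_fwd(im, lvl$mi)
      mir <- relu_fwd(mic$y)
      feat <- concat_c(feat, mir$y)
      ci$mi <- mic$cache
      ci$mirelu <- mir$cache
    }
    bf <- block_fwd(feat, lvl$block, training)
    p$enc[[i]]$block$bn1 <- bf$p$bn1; p$enc[[i]]$block$bn2 <- bf$p$bn2
    enc_out[[i]] <- bf$y
    ci$block <- bf$cache
    caches$enc[[i]] <- ci
  }
  # decoder
  cur <- enc_out[[L + 1L]]
  for (i in L:1) {
    dp <- p$dec[[i]]
    up <- convt_fwd(cur, dp$up, stride = 2L, pad = 0L)
    upr <- relu_fwd(up$y)
    cat_ <- concat_c(upr$y, enc_out[[i]])
    c1 <- conv_fwd(cat_, dp$c1)
    b1d <- bn_fwd(c1$y, dp$bn1, training)
    p$dec[[i]]$bn1 <- b1d$p
    r1 <- relu_fwd(b1d$y)
    c2 <- conv_fwd(r1$y, dp$c2)
    b2d <- bn_fwd(c2$y, dp$bn2, training)
    p$dec[[i]]$bn2 <- b2d$p
    r2 <- relu_fwd(b2d$y)
    caches$dec[[i]] <- list(up = up$cache, uprelu = upr$cache, c1 = c1$cache,
                            bn1 = b1d$cache, r1 = r1$cache, c2 = c2$cache,
                            bn2 = b2d$cache, r2 = r2$cache,
                            up_ch = dim(upr$y)[3])
    cur <- r2$y
  }
  hd <- conv_fwd(cur, p$head)
  caches$head <- hd$cache
  model$params <- p
  list(logits = hd$y, caches = caches, model = model)
}

vsn_backward <- function(model, caches, dlogits) {
  p <- model$params
  L <- model$config$levels
  g <- tree_zeros(p)
  hb <- conv_bwd(dlogits, caches$head, p$head)
  g$head <- hb$g
  d_skip <- vector("list", L + 1L)
  cur <- hb$dx
  # decoder backward: forward ran i = L..1, so reverse is i = 1..L
  for (i in 1:L) {
    dc <- caches$dec[[i]]
    dp <- p$dec[[i]]
    d2 <- relu_bwd(cur, dc$r2)
    b2 <- bn_bwd(d2, dc$bn2, dp$bn2)
    c2 <- conv_bwd(b2$dx, dc$c2, dp$c2)
    d1 <- relu_bwd(c2$dx, dc$r1)
    b1 <- bn_bwd(d1, dc$bn1, dp$bn1)
    c1 <- conv_bwd(b1$dx, dc$c1, dp$c1)
    sp <- split_c(c1$dx, dc$up_ch)
    d_skip[[i]] <- if (is.null(d_skip[[i]])) sp$b else d_skip[[i]] + sp$b
    dup <- relu_bwd(sp$a, dc$uprelu)
    ub <- convt_bwd(dup, dc$up, dp$up)
    g$dec[[i]] <- list(up = ub$g, c1 = c1$g, bn1 = b1$g, c2 = c2$g,
                       bn2 = b2$g)
    cur <- ub$dx
  }
  d_skip[[L + 1L]] <- cur
  # encoder backward: i = L+1 .. 2, then level 1 + stem
  d_prev <- NULL
  for (i in (L + 1L):2) {
    ci <- caches$enc[[i]]
    lvl <- p$enc[[i]]
    dout <- d_skip[[i]]
    if (!is.null(d_prev)) dout <- dout + d_prev
    bb <- block_bwd(dout, ci$block, lvl$block)
    gl <- list(block = bb$g)
    dfeat <- bb$dx
    if (model$config$use_multi_input) {
      sp <- split_c(dfeat, dim(dfeat)[3] - model$config$mi_channels)
      dmi <- relu_bwd(sp$b, ci$mirelu)
      mib <- conv_bwd(dmi, ci$mi, lvl$mi)
      gl$mi <- mib$g
      dfeat <- sp$a
    }
    ddr <- relu_bwd(dfeat, ci$drelu)
    dbb <- bn_bwd(ddr, ci$dbn, lvl$dbn)
    dnb <- conv_bwd(dbb$dx, ci$down, lvl$down)
    gl$down <- dnb$g
    gl$dbn <- dbb$g
    g$enc[[i]] <- gl
    d_prev <- dnb$dx
  }
  dout1 <- d_skip[[1]] + d_prev
  bb1 <- block_bwd(dout1, caches$enc[[1]]$block, p$enc[[1]]$block)
  g$enc[[1]] <- list(block = bb1$g)
  sb <- conv_bwd(bb1$dx, caches$stem, p$stem)
  g$stem <- sb$g
  g
}

softmax2 <- function(logits) {
  m <- pmax(logits[, , 1], logits[, , 2])
  e1 <- exp(logits[, , 1] - m)
  e2 <- exp(logits[, , 2] - m)
  e2 / (e1 + e2)
}

vsn_loss_grad <- function(logits, mask) {
  p2 <- softmax2(logits)
  npx <- length(mask)
  eps <- 1e-12
  loss <- -mean(mask * log(p2 + eps) + (1 - mask) * log(1 - p2 + eps))
  dl <- array(0, dim(logits))
  dl[, , 2] <- (p2 - mask) / npx
  dl[, , 1] <- -dl[, , 2]
  list(loss = loss, dlogits = dl)
}

#' Train a vessel segmentation network
#'
#' Per-pixel softmax cross-entropy minimized with Adam; random flip and
#' 90-degree-rotation augmentation is applied per epoch. Deterministic given
#' the config seed.
#'
#' @param model a `vsn_model` from [build_vsn()].
#' @param dataset list of `list(image=, mask=)` pairs; images are
#'   [fundus_image()]s (or plain matrices on the `[0,255]` scale), masks
#'   binary [vessel_mask()]s of the same size.
#' @param epochs number of passes over the data; default from the config.
#' @param lr learning rate; default from the config.
#' @param augment_data logical; apply random flips/90-degree rotations.
#' @param verbose print per-epoch losses.
#' @return the model with trained `params` plus a `history` element (mean
#'   training loss per epoch).
#' @export
train_vsn <- function(model, dataset, epochs = NULL, lr = NULL,
                      augment_data = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "vsn_model"))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(lr)) lr <- cfg$lr
  if (!length(dataset)) stop("need at least one training pair")
  prep <- lapply(dataset, function(s) {
    img <- if (inherits(s$image, "fundus_image")) as_gray(s$image) else
      as.matrix(s$image)
    msk <- unclass(as.matrix(s$mask))
    if (!all(msk %in% c(0, 1))) stop("training masks must be binary")
    if (!identical(dim(img), dim(msk))) stop("image/mask size mismatch")
    list(img = img / 255, msk = msk)
  })
  model$history <- numeric(0)
  if (epochs == 0) return(model)
  state <- adam_init(model$params)
  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(prep))
      losses <- numeric(0)
      acc <- NULL
      nacc <- 0L
      for (j in ord) {
        img <- prep[[j]]$img
        msk <- prep[[j]]$msk
        if (augment_data) {
          fl <- sample(c("none", "h", "v", "hv"), 1)
          qt <- sample(0:3, 1)
          aug <- augment(fundus_image(img * 255),
                         vessel_mask(msk), flip = fl, rotation = 90 * qt)
          img <- as_gray(aug$image) / 255
          msk <- unclass(aug$mask)
        }
        fw <- vsn_forward(model, img, training = TRUE)
        model <- fw$model
        lg <- vsn_loss_grad(fw$logits, msk)
        losses <- c(losses, lg$loss)
        gr <- vsn_backward(model, fw$caches, lg$dlogits)
        acc <- grads_add(acc, gr)
        nacc <- nacc + 1L
        if (nacc == cfg$batch_size || j == ord[length(ord)]) {
          acc <- tree_map(function(x) x / nacc, acc)
          st <- adam_step(model$params, acc, state, lr)
          model$params <- st$params
          state <- st$state
          acc <- NULL
          nacc <- 0L
        }
      }
      model$history <- c(model$history, mean(losses))
      if (verbose)
        message(sprintf("epoch %d/%d loss %.5f", ep, epochs, mean(losses)))
    }
  })
  model
}

# ---- classical fallback segmenter -------------------------------------------

hessian_maps <- function(g) {
  H <- nrow(g); W <- ncol(g)
  hxx <- matrix(0, H, W); hyy <- matrix(0, H, W); hxy <- matrix(0, H, W)
  hxx[, 2:(W - 1)] <- g[, 3:W] - 2 * g[, 2:(W - 1)] + g[, 1:(W - 2)]
  hyy[2:(H - 1), ] <- g[3:H, ] - 2 * g[2:(H - 1), ] + g[1:(H - 2), ]
  hxy[2:(H - 1), 2:(W - 1)] <-
    (g[3:H, 3:W] + g[1:(H - 2), 1:(W - 2)] -
     g[3:H, 1:(W - 2)] - g[1:(H - 2), 3:W]) / 4
  list(hxx = hxx, hyy = hyy, hxy = hxy)
}

vesselness_response <- function(gray, scales, dark = TRUE) {
  resp <- matrix(0, nrow(gray), ncol(gray))
  for (s in scales) {
    g <- cpp_gauss_blur(gray, s)
    h <- hessian_maps(g)
    hxx <- h$hxx * s^2; hyy <- h$hyy * s^2; hxy <- h$hxy * s^2
    tmp <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    la <- (hxx + hyy) / 2 + tmp
    lb <- (hxx + hyy) / 2 - tmp
    big <- ifelse(abs(la) >= abs(lb), la, lb)
    small <- ifelse(abs(la) >= abs(lb), lb, la)
    sign_ok <- if (dark) big > 0 else big < 0
    rb2 <- (small / pmax(abs(big), 1e-9))^2
    s2 <- hxx^2 + hyy^2 + 2 * hxy^2
    cpar <- max(sqrt(max(s2)), 1e-9) / 2
    v <- exp(-rb2 / (2 * 0.5^2)) * (1 - exp(-s2 / (2 * cpar^2)))
    v[!sign_ok] <- 0
    resp <- pmax(resp, v)
  }
  resp
}

#' Segment vessels with a trained network or the classical fallback
#'
#' With a trained `vsn_model`, the softmax vessel probability is computed
#' (inputs are reflect-padded to the required `2^levels` divisibility and the
#' output cropped back). Without a model, a multiscale Hessian ridge
#' (vesselness) filter is used so the pipeline runs untrained; its polarity
#' (dark vs bright vessels) is chosen automatically.
#'
#' @param model a trained `vsn_model`, or `NULL` for the fallback.
#' @param img a preprocessed [fundus_image()].
#' @param threshold probability threshold for the binary mask.
#' @param scales fallback filter scales, pixels.
#' @return list with `map` (probability matrix in `[0,1]`) and `mask`
#'   (a [vessel_mask()], `map >= threshold`).
#' @export
segment_vessels <- function(model = NULL, img, threshold = 0.5,
                            scales = c(1, 1.5, 2, 3)) {
  gray <- as_gray(img) / 255
  if (!is.null(model)) {
    stopifnot(inherits(model, "vsn_model"))
    L <- model$config$levels
    H <- nrow(gray); W <- ncol(gray)
    Hp <- ceiling(H / 2^L) * 2^L
    Wp <- ceiling(W / 2^L) * 2^L
    gp <- matrix(0, Hp, Wp)
    gp[1:H, 1:W] <- gray
    if (Hp > H) gp[(H + 1):Hp, 1:W] <- gray[H:(2 * H - Hp + 1), ]
    if (Wp > W) gp[, (W + 1):Wp] <- gp[, W:(2 * W - Wp + 1)]
    fw <- vsn_forward(model, gp, training = FALSE)
    map <- softmax2(fw$logits)[1:H, 1:W]
  } else {
    # the dark rim of the circular field of view is itself a strong ridge;
    # estimate the FOV (near-zero exterior) and erode it before filtering
    fov <- (gray > 0.02) * 1
    fov_er <- (cpp_gauss_blur(fov, 3) > 0.98) * 1
    if (mean(fov) > 0.95) fov_er <- fov # full-frame image, no FOV rim
    dark <- vesselness_response(gray, scales, dark = TRUE) * fov_er
    bright <- vesselness_response(gray, scales, dark = FALSE) * fov_er
    pick_dark <- sum(dark[dark > quantile(dark, 0.99)]) >=
      sum(bright[bright > quantile(bright, 0.99)])
    map <- if (pick_dark) dark else bright
    mx <- max(map)
    if (mx > 0) map <- map / mx
  }
  map <- pmin(pmax(map, 0), 1)
  list(map = map, mask = vessel_mask((map >= threshold) * 1L))
}

#' Dice coefficient between two binary masks
#'
#' @param a,b binary masks of equal size.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- unclass(as.matrix(a)); b <- unclass(as.matrix(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}
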