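# Minimal convolutional-network engine: feature maps are H x W x C arrays,
# convolutions run as im2col (C++) + BLAS matmul, and every layer provides an
# explicit backward pass. Networks are nested lists of parameter tensors;
# gradients mirror that structure.

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

conv_init <- function(cin, cout, k = 3L, bias = 0) {
  list(W = matrix(he_init(k * k * cin, k * k * cin * cout), k * k * cin, cout),
       b = rep(bias, cout), k = as.integer(k), cin = cin, cout = cout)
}

conv_fwd <- function(x, p, stride = 1L, pad = (p$k - 1L) %/% 2L) {
  d <- dim(x)
  cols <- cpp_im2col(x, d[1], d[2], d[3], p$k, stride, pad)
  Ho <- (d[1] + 2 * pad - p$k) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - p$k) %/% stride + 1L
  y <- cols %*% p$W
  if (any(p$b != 0)) y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(Ho, Wo, p$cout)
  list(y = y, cache = list(cols = cols, d = d, stride = stride, pad = pad))
}

conv_bwd <- function(dy, cache, p) {
  dm <- matrix(dy, ncol = p$cout)
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dcols <- tcrossprod(dm, p$W)
  dx <- cpp_col2im(dcols, cache$d[1], cache$d[2], cache$d[3], p$k,
                   cache$stride, cache$pad)
  list(dx = dx, g = list(W = dW, b = db))
}

# transposed convolution as zero-stuffing + stride-1 convolution;
# (k = 2, pad = 0) and (k = 3, pad = 1, outpad = 1) both give exact x2 upsampling
convt_fwd <- function(x, p, stride = 2L, pad = 0L, outpad = 0L) {
  d <- dim(x)
  Hs <- stride * (d[1] - 1L) + 1L + outpad
  Ws <- stride * (d[2] - 1L) + 1L + outpad
  xz <- array(0, c(Hs, Ws, d[3]))
  xz[seq(1, by = stride, length.out = d[1]),
     seq(1, by = stride, length.out = d[2]), ] <- x
  out <- conv_fwd(xz, p, stride = 1L, pad = p$k - 1L - pad)
  out$cache$stuff <- list(d = d, stride = stride, Hs = Hs, Ws = Ws)
  out
}

convt_bwd <- function(dy, cache, p) {
  b <- conv_bwd(dy, cache, p)
  st <- cache$stuff
  dx <- b$dx[seq(1, by = st$stride, length.out = st$d[1]),
             seq(1, by = st$stride, length.out = st$d[2]), , drop = FALSE]
  list(dx = dx, g = b$g)
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(x, p, training = TRUE) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    p$rmean <- (1 - BN_MOMENTUM) * p$rmean + BN_MOMENTUM * mu
    p$rvar <- (1 - BN_MOMENTUM) * p$rvar + BN_MOMENTUM * v
  } else {
    mu <- p$rmean; v <- p$rvar
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- cpp_scale_shift(xm, invstd, -mu * invstd)
  y <- cpp_scale_shift(xhat, p$gamma, p$beta)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d,
                           training = training),
       p = p)
}

bn_bwd <- function(dy, cache, p) {
  d <- cache$d
  dym <- matrix(dy, d[1] * d[2], d[3])
  dyx <- dym * cache$xhat
  dgamma <- .colSums(dyx, nrow(dym), ncol(dym))
  dbeta <- .colSums(dym, nrow(dym), ncol(dym))
  N <- d[1] * d[2]
  if (cache$training) {
    # dx = invstd * gamma * (dy - mean(dy) - xhat * mean(dy * xhat))
    t2 <- cpp_scale_shift(cache$xhat, dgamma / N, dbeta / N)
    dxm <- cpp_scale_shift(dym - t2, p$gamma * cache$invstd, rep(0, d[3]))
  } else {
    dxm <- cpp_scale_shift(dym, p$gamma * cache$invstd, rep(0, d[3]))
  }
  dx <- dxm
  dim(dx) <- d
  list(dx = dx, g = list(gamma = dgamma, beta = dbeta,
                         rmean = rep(0, d[3]), rvar = rep(0, d[3])))
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

split_c <- function(d, ca) {
  list(a = d[, , seq_len(ca), drop = FALSE],
       b = d[, , -seq_len(ca), drop = FALSE])
}

# 2x2 mean pooling used to resize the raw image for the multi-input branches
pool2_mean <- function(m) {
  H <- nrow(m); W <- ncol(m)
  (m[seq(1, H, 2), seq(1, W, 2), drop = FALSE] +
   m[seq(2, H, 2), seq(1, W, 2), drop = FALSE] +
   m[seq(1, H, 2), seq(2, W, 2), drop = FALSE] +
   m[seq(2, H, 2), seq(2, W, 2), drop = FALSE]) / 4
}

# ---- parameter-tree utilities ----------------------------------------------

is_param_leaf <- function(x) is.numeric(x)

tree_map <- function(f, a) {
  if (!is.list(a)) return(if (is_param_leaf(a)) f(a) else a)
  lapply(a, tree_map, f = f)
}

tree_map2 <- function(f, a, b) {
  if (!is.list(a)) return(if (is_param_leaf(a)) f(a, b) else a)
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
  out
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

#' Count trainable parameters of a network
#'
#' @param model a model from [build_vsn()] or [build_jdn()].
#' @return integer number of scalar parameters.
#' @export
n_params <- function(model) {
  n <- 0L
  apply_update(model$params, function(x, path) {
    n <<- n + length(x)
    x
  })
  n
}

# ---- optimizers -------------------------------------------------------------

# conv/convt params carry structural metadata (k, cin, cout) that must not be
# touched by updates; strip them from the gradient walk
trainable_names <- c("W", "b", "gamma", "beta")

apply_update <- function(params, f) {
  walk <- function(p, path) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        p[[i]] <- walk(p[[i]], c(path, list(key)))
      }
      return(p)
    }
    last <- path[[length(path)]]
    if (is.character(last) && last %in% trainable_names) f(p, path) else p
  }
  walk(params, list())
}

get_leaf <- function(tree, path) {
  for (nm in path) tree <- tree[[nm]]
  tree
}

adam_init <- function(params) {
  z <- apply_update(params, function(x, path) x * 0)
  list(m = z, v = z, t = 0L)
}

# walks params/grads/m/v in parallel (same shape), updating trainable leaves
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v, key) {
    if (is.list(p)) {
      nms <- names(p)
      ms <- m; vs <- v
      for (i in seq_along(p)) {
        # gradient subtrees may list named fields in a different order
        j <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        r <- walk(p[[i]], g[[j]], m[[j]], v[[j]],
                  if (is.character(j)) j else "")
        p[[i]] <- r$p; ms[[j]] <- r$m; vs[[j]] <- r$v
      }
      return(list(p = p, m = ms, v = vs))
    }
    if (!(key %in% trainable_names)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v, "")
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

assign_leaf <- function(tree, path, value) {
  if (length(path) == 1L) {
    tree[[path[[1]]]] <- value
    return(tree)
  }
  tree[[path[[1]]]] <- assign_leaf(tree[[path[[1]]]], path[-1], value)
  tree
}

sgdm_init <- function(params) {
  list(v = apply_update(params, function(x, path) x * 0))
}

sgdm_step <- function(params, grads, state, lr, momentum = 0.9) {
  walk <- function(p, g, v, key) {
    if (is.list(p)) {
      nms <- names(p)
      vs <- v
      for (i in seq_along(p)) {
        j <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        r <- walk(p[[i]], g[[j]], v[[j]], if (is.character(j)) j else "")
        p[[i]] <- r$p; vs[[j]] <- r$v
      }
      return(list(p = p, v = vs))
    }
    if (!(key %in% trainable_names)) return(list(p = p, v = v))
    v <- momentum * v + g
    list(p = p - lr * v, v = v)
  }
  r <- walk(params, grads, state$v, "")
  state$v <- r$v
  list(params = r$p, state = state)
}

# accumulate gradient trees (same shape)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  tree_map2(`+`, a, b)
}

#' Cosine learning-rate schedule
#'
#' `lr(t) = lr_min + (lr_max - lr_min) (1 + cos(pi t / total)) / 2`, so
#' `lr(0) = lr_max` and `lr(total) = lr_min`.
#'
#' @param step current step (0-based).
#' @param total total number of steps.
#' @param lr_max,lr_min schedule endpoints.
#' @return learning rate at `step`.
#' @export
cosine_lr <- function(step, total, lr_max, lr_min = 0) {
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * step / total))
}

# running-stat merge: batchnorm updates its running means inside bn_fwd; the
# caller stitches the updated p back into the network after each forward pass
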