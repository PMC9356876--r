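#' Apply a homography to geometric points
#'
#' Maps sensed-image coordinates `(a, b)` to reference coordinates
#' `(a', b')`:
#' `a' = (h11 a + h12 b + h13) / (h31 a + h32 b + 1)` and similarly for `b'`.
#'
#' @param h a [homography()] (or plain 3 x 3 matrix with `[3,3] == 1`).
#' @param points n x 2 matrix (or length-2 vector) of `(x, y)` points.
#' @return n x 2 matrix of transformed points.
#' @export
transform_point <- function(h, points) {
  h <- unclass(h)
  p <- rbind(points)
  den <- h[3, 1] * p[, 1] + h[3, 2] * p[, 2] + h[3, 3]
  if (any(abs(den) < 1e-12))
    stop("point maps to projective infinity (zero denominator)")
  cbind(x = (h[1, 1] * p[, 1] + h[1, 2] * p[, 2] + h[1, 3]) / den,
        y = (h[2, 1] * p[, 1] + h[2, 2] * p[, 2] + h[2, 3]) / den)
}

#' Warp an image through a homography
#'
#' Inverse-mapped bilinear resampling onto the reference canvas: output pixel
#' `p` takes the sensed image's value at `h^{-1}(p)`. Pixels mapping outside
#' the sensed frame are zero.
#'
#' @param h a [homography()] mapping sensed to reference coordinates.
#' @param img the sensed [fundus_image()].
#' @param canvas length-2 `(rows, cols)` of the output; defaults to the input
#'   size.
#' @return a [fundus_image()].
#' @export
warp_image <- function(h, img, canvas = dim(img$pixels)[1:2]) {
  stopifnot(inherits(img, "fundus_image"))
  Hinv <- solve(unclass(h))
  d <- dim(img$pixels)
  out <- array(0, c(canvas[1], canvas[2], d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- cpp_warp(img$pixels[, , k], Hinv, canvas[1], canvas[2],
                           TRUE, 0)
  fundus_image(out, image_id = paste0(img$image_id, "_warped"))
}

image_gradients <- function(gray, blur_sigma = 1) {
  g <- cpp_gauss_blur(gray, blur_sigma)
  H <- nrow(g); W <- ncol(g)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# all histogram peaks within peak_frac of the maximum (multiple orientations
# stabilize matching at junctions, whose 3-4 vessel arms give near-equal peaks)
dominant_orientations <- function(grad, x, y, sigma = 6, nbins = 36L,
                                  peak_frac = 0.6) {
  rad <- ceiling(2 * sigma)
  H <- nrow(grad$gx); W <- ncol(grad$gx)
  rr <- max(1, round(y) - rad):min(H, round(y) + rad)
  cc <- max(1, round(x) - rad):min(W, round(x) + rad)
  gx <- grad$gx[rr, cc]; gy <- grad$gy[rr, cc]
  mag <- sqrt(gx^2 + gy^2)
  if (sum(mag) < 1e-9) return(numeric(0))
  wy <- outer((rr - y)^2, (cc - x)^2, "+")
  wgt <- exp(-wy / (2 * sigma^2)) * mag
  ori <- atan2(gy, gx) %% (2 * pi)
  b <- floor(ori / (2 * pi) * nbins) %% nbins
  hist <- vapply(0:(nbins - 1), function(k) sum(wgt[b == k]), numeric(1))
  # smooth the circular histogram, then parabolic peak interpolation
  hs <- (c(hist[nbins], hist[-nbins]) + hist + c(hist[-1], hist[1])) / 3
  left <- c(hs[nbins], hs[-nbins]); right <- c(hs[-1], hs[1])
  peaks <- which(hs > left & hs >= right & hs >= peak_frac * max(hs))
  vapply(peaks, function(k) {
    denom <- left[k] - 2 * hs[k] + right[k]
    off <- if (abs(denom) < 1e-12) 0 else 0.5 * (left[k] - right[k]) / denom
    (((k - 1 + off) / nbins) * 2 * pi) %% (2 * pi)
  }, numeric(1))
}

#' Extract keypoints around junction points
#'
#' Each junction yields a keypoint at its own location plus up to `n_aux`
#' keypoints at local gradient-magnitude maxima within `radius` pixels of the
#' junction. Every keypoint is assigned a dominant orientation from a
#' Gaussian-weighted gradient-orientation histogram (36 bins, parabolic peak
#' interpolation) and a fixed scale. Junctions too close to the border for a
#' descriptor window are skipped with a warning.
#'
#' @param junctions a [junction_points()] table (typically calibrated).
#' @param img the [fundus_image()] the descriptors will be computed on.
#' @param radius search radius for auxiliary keypoints, pixels.
#' @param n_aux maximum auxiliary keypoints per junction.
#' @param scale fixed keypoint scale, pixels.
#' @param orientation_sigma Gaussian window sigma of the orientation
#'   histogram, pixels.
#' @param peak_frac histogram peaks within this fraction of the maximum all
#'   yield a keypoint (junctions have several near-equal vessel-arm peaks;
#'   emitting one keypoint per peak makes matching robust to which arm wins).
#' @return data.frame of class `keypoints` with columns `x`, `y`, `scale`,
#'   `orientation`, `junction`.
#' @export
extract_keypoints <- function(junctions, img, radius = 5L, n_aux = 4L,
                              scale = 2, orientation_sigma = 6,
                              peak_frac = 0.6) {
  gray <- as_gray(img)
  grad <- image_gradients(gray)
  H <- nrow(gray); W <- ncol(gray)
  border <- 14L
  mag <- sqrt(grad$gx^2 + grad$gy^2)
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(junctions))) {
    r0 <- junctions$row[i]; c0 <- junctions$col[i]
    if (r0 <= border || c0 <= border || r0 > H - border || c0 > W - border) {
      n_skipped <- n_skipped + 1L
      next
    }
    cand <- cbind(x = c0, y = r0)
    if (radius > 0 && n_aux > 0) {
      rr <- (r0 - radius):(r0 + radius)
      cc <- (c0 - radius):(c0 + radius)
      sub <- mag[rr, cc]
      disc <- outer((rr - r0)^2, (cc - c0)^2, "+") <= radius^2
      sub[!disc] <- -Inf
      # local maxima in the 8-neighborhood, excluding the junction pixel
      ord <- order(sub, decreasing = TRUE)
      picked <- 0L
      for (j in ord) {
        if (picked >= n_aux || sub[j] <= 0) break
        rc <- arrayInd(j, dim(sub))
        pr <- rr[rc[1]]; pc <- cc[rc[2]]
        if (pr == r0 && pc == c0) next
        if (pr <= 1 || pc <= 1 || pr >= H || pc >= W) next
        if (mag[pr, pc] < max(mag[(pr - 1):(pr + 1), (pc - 1):(pc + 1)])) next
        if (any((cand[, 1] - pc)^2 + (cand[, 2] - pr)^2 < 4)) next
        cand <- rbind(cand, c(pc, pr))
        picked <- picked + 1L
      }
    }
    for (j in seq_len(nrow(cand))) {
      oris <- dominant_orientations(grad, cand[j, 1], cand[j, 2],
                                    sigma = orientation_sigma,
                                    peak_frac = peak_frac)
      for (ori in oris)
        rows[[length(rows) + 1L]] <- c(cand[j, 1], cand[j, 2], scale, ori, i)
    }
  }
  if (n_skipped > 0)
    warning(sprintf("%d junction(s) too close to the border were skipped",
                    n_skipped))
  kp <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    as.data.frame(matrix(numeric(), 0, 5))
  names(kp) <- c("x", "y", "scale", "orientation", "junction")
  class(kp) <- c("keypoints", "data.frame")
  kp
}

#' Compute SIFT-style orientation descriptors
#'
#' The standard 128-value descriptor: a 4 x 4 spatial grid of 8-bin gradient
#' orientation histograms, sampled on a patch rotated to the keypoint's
#' dominant orientation, trilinearly soft-binned, Gaussian weighted,
#' normalized to unit length, clipped at 0.2 and renormalized. Flat patches
#' (no gradient energy) are invalid and their keypoints dropped.
#'
#' @param img a [fundus_image()].
#' @param keypoints a `keypoints` table from [extract_keypoints()].
#' @param spacing sample spacing in pixels (at the reference scale 2); the
#'   descriptor support is `16 * spacing` pixels across.
#' @param grad_sigma Gaussian blur applied before gradients, pixels.
#' @return list with `descriptors` (n x 128 matrix, unit rows) and
#'   `keypoints` (the rows that produced valid descriptors).
#' @export
compute_descriptors <- function(img, keypoints, spacing = 2.5,
                                grad_sigma = 2) {
  gray <- as_gray(img)
  grad <- image_gradients(gray, grad_sigma)
  n <- nrow(keypoints)
  d <- 4L; nb <- 8L
  width <- 16L # patch samples per side
  desc <- matrix(0, n, d * d * nb)
  valid <- rep(TRUE, n)
  # sample grid in keypoint frame: width x width samples, cell = 4 samples
  gs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  gxs <- matrix(gs, width, width, byrow = TRUE)
  gys <- matrix(gs, width, width)
  sigma_w <- width / 2
  wgt0 <- exp(-(gxs^2 + gys^2) / (2 * sigma_w^2))
  for (i in seq_len(n)) {
    th <- keypoints$orientation[i]
    sp <- spacing * keypoints$scale[i] / 2
    co <- cos(th); si <- sin(th)
    xs <- keypoints$x[i] + sp * (co * gxs - si * gys)
    ys <- keypoints$y[i] + sp * (si * gxs + co * gys)
    gxv <- cpp_bilinear_sample(grad$gx, as.numeric(xs), as.numeric(ys))
    gyv <- cpp_bilinear_sample(grad$gy, as.numeric(xs), as.numeric(ys))
    # rotate gradients into the keypoint frame
    rgx <- co * gxv + si * gyv
    rgy <- -si * gxv + co * gyv
    mag <- sqrt(rgx^2 + rgy^2) * as.numeric(wgt0)
    if (sum(mag) < 1e-9) { valid[i] <- FALSE; next }
    ori <- atan2(rgy, rgx) %% (2 * pi)
    # trilinear soft binning into (cell_x, cell_y, orientation)
    cx <- (as.numeric(gxs) + (width - 1) / 2) / (width / d) - 0.5
    cy <- (as.numeric(gys) + (width - 1) / 2) / (width / d) - 0.5
    ob <- ori / (2 * pi) * nb
    v <- numeric(d * d * nb)
    x0 <- floor(cx); y0 <- floor(cy); o0 <- floor(ob)
    fx <- cx - x0; fy <- cy - y0; fo <- ob - o0
    for (dx in 0:1) for (dy in 0:1) for (do in 0:1) {
      xb <- x0 + dx; yb <- y0 + dy; obn <- (o0 + do) %% nb
      w <- mag * (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (do) fo else 1 - fo)
      ok <- xb >= 0 & xb < d & yb >= 0 & yb < d
      if (!any(ok)) next
      idx <- 1 + obn[ok] + nb * (xb[ok] + d * yb[ok])
      acc <- rowsum(w[ok], idx)
      v[as.integer(rownames(acc))] <- v[as.integer(rownames(acc))] + acc[, 1]
    }
    desc[i, ] <- v
  }
  # normalize, clip, renormalize
  for (i in which(valid)) {
    nv <- sqrt(sum(desc[i, ]^2))
    if (nv < 1e-9) { valid[i] <- FALSE; next }
    v <- pmin(desc[i, ] / nv, 0.2)
    desc[i, ] <- v / sqrt(sum(v^2))
  }
  list(descriptors = desc[valid, , drop = FALSE],
       keypoints = keypoints[valid, , drop = FALSE])
}

#' Match descriptors with the nearest-neighbor ratio test
#'
#' For each reference descriptor the nearest and second-nearest sensed
#' descriptors are found by Euclidean distance; the pair is kept iff
#' `d1/d2 <= ratio` (default 0.84). One-to-one matching is enforced by
#' keeping only the lowest-distance claim per sensed keypoint.
#'
#' @param ref_desc,sensed_desc descriptor matrices (rows are descriptors).
#' @param ratio ratio-test threshold in `(0, 1]`.
#' @param mutual also require the pair to be nearest in the reverse
#'   (sensed-to-reference) direction.
#' @return data.frame of class `match_pairs` with columns `ref_idx`,
#'   `sensed_idx`, `d1`, `d2`, `ratio`.
#' @export
match_descriptors <- function(ref_desc, sensed_desc, ratio = 0.84,
                              mutual = FALSE) {
  if (nrow(sensed_desc) < 2)
    stop("ratio-test matching needs at least 2 sensed descriptors")
  if (nrow(ref_desc) == 0) {
    out <- data.frame(ref_idx = integer(), sensed_idx = integer(),
                      d1 = numeric(), d2 = numeric(), ratio = numeric())
    class(out) <- c("match_pairs", "data.frame")
    return(out)
  }
  # squared distances via the Gram expansion
  d2 <- outer(rowSums(ref_desc^2), rowSums(sensed_desc^2), "+") -
    2 * ref_desc %*% t(sensed_desc)
  d2[d2 < 0] <- 0
  rows <- lapply(seq_len(nrow(ref_desc)), function(i) {
    o <- order(d2[i, ])[1:2]
    d1 <- sqrt(d2[i, o[1]]); dd2 <- sqrt(d2[i, o[2]])
    r <- if (dd2 < 1e-12) 1 else d1 / dd2
    c(i, o[1], d1, dd2, r)
  })
  m <- do.call(rbind, rows)
  m <- m[m[, 5] <= ratio, , drop = FALSE]
  if (mutual && nrow(m)) {
    back <- apply(d2[, m[, 2], drop = FALSE], 2, which.min)
    m <- m[m[, 1] == back, , drop = FALSE]
  }
  # one-to-one: lowest distance wins per sensed index
  if (nrow(m) > 1) {
    m <- m[order(m[, 3]), , drop = FALSE]
    m <- m[!duplicated(m[, 2]), , drop = FALSE]
  }
  out <- data.frame(ref_idx = as.integer(m[, 1]), sensed_idx = as.integer(m[, 2]),
                    d1 = m[, 3], d2 = m[, 4], ratio = m[, 5])
  class(out) <- c("match_pairs", "data.frame")
  out
}

normalize_points <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums((p - matrix(ctr, nrow(p), 2, byrow = TRUE))^2))
  s <- sqrt(2) / max(mean(d), 1e-12)
  Tm <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
  list(T = Tm, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
}

dlt_homography <- function(sensed, ref) {
  ns <- normalize_points(sensed); nr <- normalize_points(ref)
  s <- ns$p; r <- nr$p
  n <- nrow(s)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- r[i, 1]; v <- r[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  h <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  Hn <- solve(nr$T) %*% h %*% ns$T
  if (abs(Hn[3, 3]) < 1e-12) return(NULL)
  Hn / Hn[3, 3]
}

# TRUE when the point set has < 4 distinct points or all points lie on a line
degenerate_set <- function(p, tol = 1e-6) {
  p <- unique(round(p, 6))
  if (nrow(p) < 4) return(TRUE)
  ctr <- colMeans(p)
  cv <- crossprod(sweep(p, 2, ctr)) / nrow(p)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[2] < tol * max(ev[1], 1)
}

any_collinear <- function(p, tol = 1e-6) {
  n <- nrow(p)
  if (n < 3) return(TRUE)
  cmb <- utils::combn(n, 3)
  for (k in seq_len(ncol(cmb))) {
    a <- p[cmb[1, k], ]; b <- p[cmb[2, k], ]; cc <- p[cmb[3, k], ]
    area <- abs((b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    scale <- max(abs(rbind(a, b, cc))) + 1
    if (area < tol * scale) return(TRUE)
  }
  FALSE
}

#' Estimate a projective homography with RANSAC
#'
#' Repeated minimal 4-point direct-linear-transform solves with inlier
#' counting at the reprojection threshold, followed by a normalized DLT
#' re-fit on the best inlier set. The returned matrix maps sensed to
#' reference coordinates and is scaled so its last element is 1.
#'
#' @param sensed,ref n x 2 matrices of matched `(x, y)` points.
#' @param reproj_thresh RANSAC inlier reprojection threshold, pixels.
#' @param max_iter maximum RANSAC iterations.
#' @param confidence early-stop confidence for adaptive iteration count.
#' @param seed optional integer seed for the sampler.
#' @return list with `h` (a [homography()] or `NULL`), logical `inliers`,
#'   and `status` (`"ok"`, `"degenerate"`, or `"insufficient_matches"`).
#' @export
estimate_homography <- function(sensed, ref, reproj_thresh = 3,
                                max_iter = 2000L, confidence = 0.995,
                                seed = NULL) {
  sensed <- rbind(sensed); ref <- rbind(ref)
  n <- nrow(sensed)
  if (n < 4)
    return(list(h = NULL, inliers = logical(n), status = "insufficient_matches"))
  run <- function() {
    best_in <- logical(n); best_cnt <- 0L
    iter_needed <- max_iter
    i <- 0L
    while (i < min(iter_needed, max_iter)) {
      i <- i + 1L
      s <- sample.int(n, 4)
      if (any_collinear(sensed[s, , drop = FALSE]) ||
          any_collinear(ref[s, , drop = FALSE])) next
      Hm <- dlt_homography(sensed[s, , drop = FALSE], ref[s, , drop = FALSE])
      if (is.null(Hm) || !all(is.finite(Hm))) next
      den <- Hm[3, 1] * sensed[, 1] + Hm[3, 2] * sensed[, 2] + 1
      if (any(abs(den) < 1e-9)) next
      px <- (Hm[1, 1] * sensed[, 1] + Hm[1, 2] * sensed[, 2] + Hm[1, 3]) / den
      py <- (Hm[2, 1] * sensed[, 1] + Hm[2, 2] * sensed[, 2] + Hm[2, 3]) / den
      err <- sqrt((px - ref[, 1])^2 + (py - ref[, 2])^2)
      inl <- err <= reproj_thresh
      cnt <- sum(inl)
      if (cnt > best_cnt) {
        best_cnt <- cnt; best_in <- inl
        w <- cnt / n
        iter_needed <- if (w >= 1) i else
          ceiling(log(1 - confidence) / log(max(1 - w^4, 1e-12)))
      }
    }
    list(inliers = best_in, count = best_cnt)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (res$count < 4 || degenerate_set(sensed[res$inliers, , drop = FALSE]))
    return(list(h = NULL, inliers = res$inliers, status = "degenerate"))
  # iterated refit: re-estimate on the inlier set and recount until stable
  inl <- res$inliers
  Hm <- NULL
  for (round in 1:3) {
    Hc <- dlt_homography(sensed[inl, , drop = FALSE], ref[inl, , drop = FALSE])
    if (is.null(Hc) || !all(is.finite(Hc)) || abs(det(Hc)) < 1e-12) break
    Hm <- Hc
    den <- Hm[3, 1] * sensed[, 1] + Hm[3, 2] * sensed[, 2] + 1
    if (any(abs(den) < 1e-9)) break
    px <- (Hm[1, 1] * sensed[, 1] + Hm[1, 2] * sensed[, 2] + Hm[1, 3]) / den
    py <- (Hm[2, 1] * sensed[, 1] + Hm[2, 2] * sensed[, 2] + Hm[2, 3]) / den
    new_inl <- sqrt((px - ref[, 1])^2 + (py - ref[, 2])^2) <= reproj_thresh
    if (identical(new_inl, inl) || sum(new_inl) < 4 ||
        degenerate_set(sensed[new_inl, , drop = FALSE])) break
    inl <- new_inl
  }
  if (is.null(Hm) || !all(is.finite(Hm)) || abs(det(Hm)) < 1e-12)
    return(list(h = NULL, inliers = res$inliers, status = "degenerate"))
  list(h = homography(Hm), inliers = inl, status = "ok")
}

# one-to-one count of junction pairs aligned within thresh by H
count_aligned <- function(Hm, sensed_j, ref_j, thresh) {
  den <- Hm[3, 1] * sensed_j[, 1] + Hm[3, 2] * sensed_j[, 2] + 1
  if (any(abs(den) < 1e-9)) return(0L)
  px <- (Hm[1, 1] * sensed_j[, 1] + Hm[1, 2] * sensed_j[, 2] + Hm[1, 3]) / den
  py <- (Hm[2, 1] * sensed_j[, 1] + Hm[2, 2] * sensed_j[, 2] + Hm[2, 3]) / den
  dmat <- sqrt(outer(ref_j[, 1], px, "-")^2 + outer(ref_j[, 2], py, "-")^2)
  hit <- dmat <= thresh
  # greedy one-to-one
  n <- 0L
  while (any(hit)) {
    k <- arrayInd(which.max(hit / (dmat + 1e-9)), dim(hit))
    n <- n + 1L
    hit[k[1], ] <- FALSE
    hit[, k[2]] <- FALSE
  }
  n
}

# similarity transform (rotation + isotropic scale + translation) from two
# point correspondences, as a 3x3 matrix
similarity_from_two <- function(s1, s2, r1, r2) {
  zs <- complex(real = c(s1[1], s2[1]), imaginary = c(s1[2], s2[2]))
  zr <- complex(real = c(r1[1], r2[1]), imaginary = c(r1[2], r2[2]))
  dz <- zs[2] - zs[1]
  if (Mod(dz) < 1e-9) return(NULL)
  a <- (zr[2] - zr[1]) / dz
  b <- zr[1] - a * zs[1]
  matrix(c(Re(a), Im(a), 0, -Im(a), Re(a), 0, Re(b), Im(b), 1), 3, 3)
}

# least-squares similarity fit (complex regression zr ~ a zs + b)
similarity_ls <- function(sp, rp) {
  zs <- complex(real = sp[, 1], imaginary = sp[, 2])
  zr <- complex(real = rp[, 1], imaginary = rp[, 2])
  zsc <- zs - mean(zs); zrc <- zr - mean(zr)
  den <- sum(Conj(zsc) * zsc)
  if (Mod(den) < 1e-9) return(NULL)
  a <- sum(Conj(zsc) * zrc) / den
  b <- mean(zr) - a * mean(zs)
  matrix(c(Re(a), Im(a), 0, -Im(a), Re(a), 0, Re(b), Im(b), 1), 3, 3)
}

# hypotheses from descriptor matches, scored by the number of junctions
# brought into one-to-one alignment (the expected view change is close to a
# similarity). Two-match hypotheses are enumerated exhaustively (up to
# max_iter); one-match hypotheses -- anchor position plus keypoint-orientation
# rotation over a scale grid -- cover the case where all true matches sit on a
# single junction.
ransac_junction_aligned <- function(sensed_pts, ref_pts, sensed_j, ref_j,
                                    align_thresh = 5, max_iter = 2000L,
                                    seed = 1L, sensed_ori = NULL,
                                    ref_ori = NULL) {
  n <- nrow(sensed_pts)
  if (n < 4)
    return(list(h = NULL, inliers = logical(n), score = 0L,
                status = "insufficient_matches"))
  jcap <- min(nrow(sensed_j), nrow(ref_j))
  run <- function() {
    best <- NULL; best_score <- -1L
    pairs <- utils::combn(n, 2)
    if (ncol(pairs) > max_iter)
      pairs <- pairs[, sample.int(ncol(pairs), max_iter), drop = FALSE]
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]; b <- pairs[2, i]
      # well-separated samples in both frames, else the similarity is wild
      if (sum((sensed_pts[a, ] - sensed_pts[b, ])^2) < 225 ||
          sum((ref_pts[a, ] - ref_pts[b, ])^2) < 225) next
      Hm <- similarity_from_two(sensed_pts[a, ], sensed_pts[b, ],
                                ref_pts[a, ], ref_pts[b, ])
      if (is.null(Hm)) next
      sc_ <- sqrt(Hm[1, 1]^2 + Hm[2, 1]^2) # scale of the hypothesis
      if (sc_ < 0.5 || sc_ > 2) next
      sc <- count_aligned(Hm, sensed_j, ref_j, align_thresh)
      if (sc > best_score) { best_score <- sc; best <- Hm }
      if (best_score >= jcap) break
    }
    if (best_score < max(6, jcap %/% 2) && !is.null(sensed_ori)) {
      for (i in seq_len(n)) {
        th <- ref_ori[i] - sensed_ori[i]
        for (scl in seq(0.8, 1.25, by = 0.05)) {
          a <- complex(modulus = scl, argument = th)
          zs <- complex(real = sensed_pts[i, 1], imaginary = sensed_pts[i, 2])
          zr <- complex(real = ref_pts[i, 1], imaginary = ref_pts[i, 2])
          b <- zr - a * zs
          Hm <- matrix(c(Re(a), Im(a), 0, -Im(a), Re(a), 0,
                         Re(b), Im(b), 1), 3, 3)
          sc <- count_aligned(Hm, sensed_j, ref_j, align_thresh)
          if (sc > best_score) { best_score <- sc; best <- Hm }
        }
      }
    }
    list(h = best, score = best_score)
  }
  res <- withr::with_seed(seed, run())
  if (is.null(res$h) || res$score < 4)
    return(list(h = NULL, inliers = logical(n), score = max(res$score, 0L),
                status = "insufficient_matches"))
  den <- res$h[3, 1] * sensed_pts[, 1] + res$h[3, 2] * sensed_pts[, 2] + 1
  inl <- rep(FALSE, n)
  okd <- abs(den) > 1e-9
  px <- (res$h[1, 1] * sensed_pts[okd, 1] + res$h[1, 2] * sensed_pts[okd, 2] +
         res$h[1, 3]) / den[okd]
  py <- (res$h[2, 1] * sensed_pts[okd, 1] + res$h[2, 2] * sensed_pts[okd, 2] +
         res$h[2, 3]) / den[okd]
  inl[okd] <- sqrt((px - ref_pts[okd, 1])^2 +
                   (py - ref_pts[okd, 2])^2) <= align_thresh
  list(h = homography(res$h), inliers = inl, score = res$score, status = "ok")
}

#' Registration pipeline configuration
#'
#' @param clahe a [clahe_params()].
#' @param calibration a [calibration_params()].
#' @param keypoint_radius keypoint search radius around junctions, pixels.
#' @param n_aux auxiliary keypoints per junction.
#' @param ratio descriptor ratio-test threshold.
#' @param reproj_thresh,max_iter,confidence RANSAC settings.
#' @param mutual require descriptor matches to be mutual nearest neighbors.
#' @param try_inverted retry matching against the intensity-inverted sensed
#'   image when the first attempt aligns few junctions (handles multimodal
#'   pairs such as fluorescein angiography, where vessel contrast reverses).
#' @param guided_radius junction re-match radius (pixels) for the guided
#'   refinement rounds after the descriptor-based model; 0 disables.
#' @param segment_threshold fallback segmentation probability threshold.
#' @param seed integer seed controlling RANSAC sampling.
#' @return list of class `register_config`.
#' @export
register_config <- function(clahe = clahe_params(),
                            calibration = calibration_params(),
                            keypoint_radius = 5L, n_aux = 4L, ratio = 0.84,
                            reproj_thresh = 3, max_iter = 2000L,
                            confidence = 0.995, mutual = FALSE,
                            try_inverted = TRUE, guided_radius = 5,
                            segment_threshold = 0.5, seed = 1L) {
  structure(list(clahe = clahe, calibration = calibration,
                 keypoint_radius = keypoint_radius, n_aux = n_aux,
                 ratio = ratio, reproj_thresh = reproj_thresh,
                 max_iter = max_iter, confidence = confidence,
                 mutual = mutual, try_inverted = try_inverted,
                 guided_radius = guided_radius,
                 segment_threshold = segment_threshold, seed = seed),
            class = "register_config")
}

#' Register a sensed fundus image onto a reference image
#'
#' Runs the full feature-based pipeline: CLAHE preprocessing, vessel
#' segmentation (supplied masks, a trained segmentation network, or the
#' classical ridge-filter fallback), skeleton-based junction detection,
#' crossing-number calibration, keypoint extraction, SIFT-style descriptors,
#' ratio-test matching, RANSAC homography estimation, and warping of the
#' sensed image onto the reference canvas.
#'
#' @param ref,sensed [fundus_image()] objects.
#' @param ref_mask,sensed_mask optional [vessel_mask()] objects; when absent,
#'   vessels are segmented with `model` or the classical fallback.
#' @param model optional trained segmentation network from [train_vsn()].
#' @param config a [register_config()].
#' @return list of class `registration_result` with `homography`, `matches`,
#'   `inliers`, `warped`, `status` and `counts` (per-stage tallies).
#' @export
register_pair <- function(ref, sensed, ref_mask = NULL, sensed_mask = NULL,
                          model = NULL, config = register_config()) {
  counts <- list()
  ref_eq <- apply_clahe(ref, config$clahe)
  sensed_eq <- apply_clahe(sensed, config$clahe)
  get_mask <- function(img, mask) {
    if (!is.null(mask)) return(mask)
    segment_vessels(model, img, threshold = config$segment_threshold)$mask
  }
  ref_mask <- get_mask(ref_eq, ref_mask)
  sensed_mask <- get_mask(sensed_eq, sensed_mask)
  counts$vessel_pixels <- c(ref = sum(ref_mask), sensed = sum(sensed_mask))
  fail <- function(status) {
    structure(list(homography = NULL, matches = NULL, inliers = logical(),
                   warped = NULL, status = status, counts = counts),
              class = "registration_result")
  }
  jr <- detect_junctions_skeleton(ref_mask)
  js <- detect_junctions_skeleton(sensed_mask)
  jr <- calibrate_junctions(jr, ref_mask, config$calibration)
  js <- calibrate_junctions(js, sensed_mask, config$calibration)
  counts$junctions <- c(ref = nrow(jr), sensed = nrow(js))
  if (nrow(jr) < 4 || nrow(js) < 4) return(fail("insufficient_matches"))
  kr <- suppressWarnings(extract_keypoints(jr, ref_eq, config$keypoint_radius,
                                           config$n_aux))
  dr <- compute_descriptors(ref_eq, kr)
  if (nrow(dr$descriptors) < 4) return(fail("insufficient_matches"))
  attempt <- function(sen_img) {
    ks <- suppressWarnings(extract_keypoints(js, sen_img,
                                             config$keypoint_radius,
                                             config$n_aux))
    ds <- compute_descriptors(sen_img, ks)
    if (nrow(ds$descriptors) < 2)
      return(list(est = list(status = "insufficient_matches", score = 0L,
                             inliers = logical()),
                  matches = NULL, ds = ds))
    matches <- match_descriptors(dr$descriptors, ds$descriptors, config$ratio,
                                 mutual = config$mutual)
    # orientation variants share positions; best match per position pair
    if (nrow(matches)) {
      matches <- matches[order(matches$d1), , drop = FALSE]
      key <- paste(dr$keypoints$x[matches$ref_idx],
                   dr$keypoints$y[matches$ref_idx],
                   ds$keypoints$x[matches$sensed_idx],
                   ds$keypoints$y[matches$sensed_idx])
      matches <- matches[!duplicated(key), , drop = FALSE]
    }
    if (nrow(matches) < 4)
      return(list(est = list(status = "insufficient_matches", score = 0L,
                             inliers = logical()),
                  matches = matches, ds = ds))
    sensed_pts <- as.matrix(ds$keypoints[matches$sensed_idx, c("x", "y")])
    ref_pts <- as.matrix(dr$keypoints[matches$ref_idx, c("x", "y")])
    # RANSAC: hypotheses from minimal descriptor-match samples, scored by how
    # many calibrated junctions they bring into alignment (the landmarks
    # carry the reliable geometry; descriptors only propose)
    est <- ransac_junction_aligned(sensed_pts, ref_pts,
                                   rc_to_xy(js$row, js$col),
                                   rc_to_xy(jr$row, jr$col),
                                   align_thresh = config$guided_radius,
                                   max_iter = config$max_iter,
                                   seed = config$seed,
                                   sensed_ori = ds$keypoints$orientation[matches$sensed_idx],
                                   ref_ori = dr$keypoints$orientation[matches$ref_idx])
    list(est = est, matches = matches, ds = ds)
  }
  att <- attempt(sensed_eq)
  jcap <- min(nrow(jr), nrow(js))
  # multimodal case (e.g. angiography): gradients reverse sign under contrast
  # inversion, so retry against the intensity-inverted sensed image and keep
  # the attempt that aligns more junctions
  if (config$try_inverted &&
      (att$est$status != "ok" || att$est$score < max(6, jcap %/% 2))) {
    inv <- sensed_eq
    inv$pixels <- 255 - inv$pixels
    att2 <- attempt(inv)
    if (att2$est$status == "ok" &&
        (att$est$status != "ok" || att2$est$score > att$est$score)) {
      att <- att2
      counts$inverted_retry <- TRUE
    }
  }
  est <- att$est
  matches <- att$matches
  counts$keypoints <- c(ref = nrow(dr$keypoints), sensed = nrow(att$ds$keypoints))
  counts$matches <- if (is.null(matches)) 0L else nrow(matches)
  counts$inliers <- sum(est$inliers)
  counts$aligned_junctions <- est$score
  if (est$status != "ok") return(fail(est$status))
  # guided refinement: the descriptor-based model is only a bootstrap; the
  # calibrated junction positions themselves carry the precise geometry, so
  # re-match junctions under the current model and refit on those pairs
  h <- est$h
  for (round in 1:5) {
    mapped <- transform_point(h, rc_to_xy(js$row, js$col))
    dmat <- sqrt(outer(jr$col, mapped[, 1], "-")^2 +
                 outer(jr$row, mapped[, 2], "-")^2)
    cand <- which(dmat <= config$guided_radius, arr.ind = TRUE)
    if (nrow(cand) < 3) break
    cand <- cand[order(dmat[cand]), , drop = FALSE]
    used_r <- rep(FALSE, nrow(jr)); used_s <- rep(FALSE, nrow(js))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (used_r[cand[k, 1]] || used_s[cand[k, 2]]) next
      used_r[cand[k, 1]] <- TRUE; used_s[cand[k, 2]] <- TRUE
      keep[k] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    sp <- rc_to_xy(js$row[cand[, 2]], js$col[cand[, 2]])
    rp <- rc_to_xy(jr$row[cand[, 1]], jr$col[cand[, 1]])
    # full projective refit only once enough well-spread pairs align;
    # a least-squares similarity is stable down to 3 pairs
    Hg <- if (nrow(sp) >= 8 && !degenerate_set(sp)) dlt_homography(sp, rp)
          else similarity_ls(sp, rp)
    if (is.null(Hg) || !all(is.finite(Hg)) || abs(det(Hg)) < 1e-12) break
    h <- homography(Hg)
    if (!is.null(counts$guided_pairs) && counts$guided_pairs == nrow(sp) &&
        round > 2) break
    counts$guided_pairs <- nrow(sp)
  }
  warped <- warp_image(h, sensed, canvas = dim(ref$pixels)[1:2])
  structure(list(homography = h, matches = matches,
                 inliers = est$inliers, warped = warped, status = "ok",
                 counts = counts),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result status=%s matches=%s inliers=%s>\n",
              x$status,
              if (is.null(x$matches)) 0 else nrow(x$matches),
              sum(x$inliers)))
  invisible(x)
}
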