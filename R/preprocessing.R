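#' CLAHE parameters
#'
#' @param tile_rows,tile_cols contextual tile grid (default 8 x 8).
#' @param clip_limit contrast clip limit (> 0); the common default 2.0 is
#'   used since only the tile grid is fixed by the method.
#' @return list of class `clahe_params`.
#' @export
clahe_params <- function(tile_rows = 8L, tile_cols = 8L, clip_limit = 2) {
  if (tile_rows < 1 || tile_cols < 1) stop("tile grid must be >= 1 x 1")
  if (clip_limit <= 0) stop("clip_limit must be > 0")
  structure(list(tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols),
                 clip_limit = clip_limit), class = "clahe_params")
}

clahe_matrix <- function(m, params) {
  if (diff(range(m)) < .Machine$double.eps * 255) return(m) # constant image
  # EBImage stores images x-major; transpose in and out. EBImage's clahe
  # requires dimensions divisible by twice the tile grid; pad by reflection.
  H <- nrow(m); W <- ncol(m)
  bh <- 2L * params$tile_rows; bw <- 2L * params$tile_cols
  Hp <- ceiling(H / bh) * bh; Wp <- ceiling(W / bw) * bw
  mp <- matrix(0, Hp, Wp)
  mp[1:H, 1:W] <- m
  if (Hp > H) mp[(H + 1):Hp, 1:W] <- m[H:(2 * H - Hp + 1), , drop = FALSE]
  if (Wp > W) mp[, (W + 1):Wp] <- mp[, W:(2 * W - Wp + 1), drop = FALSE]
  img <- EBImage::Image(t(mp) / 255)
  eq <- EBImage::clahe(img, nx = params$tile_cols, ny = params$tile_rows,
                       limit = params$clip_limit)
  out <- t(EBImage::imageData(eq))[1:H, 1:W, drop = FALSE] * 255
  pmin(pmax(out, 0), 255)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Equalizes intensity tile-by-tile with a clip limit, the standard
#' normalization for fundus images whose illumination varies across the field
#' of view. Grayscale images are equalized directly; RGB images are equalized
#' on the green channel (which carries the strongest vessel contrast) with the
#' result applied as a luminance gain to all channels.
#'
#' @param img a [fundus_image()] with 8-bit intensities.
#' @param params a [clahe_params()].
#' @return a [fundus_image()] of the same shape, values in `[0, 255]`.
#' @export
apply_clahe <- function(img, params = clahe_params()) {
  stopifnot(inherits(img, "fundus_image"), inherits(params, "clahe_params"))
  d <- dim(img$pixels)
  if (d[1] < params$tile_rows || d[2] < params$tile_cols)
    stop("image smaller than one CLAHE tile")
  if (d[3] == 1L) {
    out <- clahe_matrix(img$pixels[, , 1], params)
    return(fundus_image(out, image_id = img$image_id))
  }
  g <- img$pixels[, , 2]
  eq <- clahe_matrix(g, params)
  gain <- eq / pmax(g, 1)
  px <- img$pixels
  for (k in 1:3) px[, , k] <- pmin(pmax(px[, , k] * gain, 0), 255)
  fundus_image(px, image_id = img$image_id)
}

# exact rotation by multiples of 90 degrees, counterclockwise in (x, y)
rot90_exact <- function(m, quarter) {
  q <- quarter %% 4
  if (q == 0) return(m)
  if (q == 2) return(m[nrow(m):1, ncol(m):1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("same-canvas 90-degree rotation needs a square image")
  n <- nrow(m)
  out <- matrix(0, n, n)
  if (q == 1) {
    # out[y, x] = in[N+1-x, y]
    for (x in seq_len(n)) out[, x] <- m[n + 1 - x, ]
  } else {
    # out[y, x] = in[x, N+1-y]
    for (x in seq_len(n)) out[, x] <- rev(m[x, ])
  }
  out
}

#' Geometric training augmentation: flip and rotation
#'
#' Applies the identical transform to the image and (optionally) its vessel
#' mask. Flips and multiples of 90 degrees are exact index permutations;
#' other angles rotate about the image center on the same canvas, bilinear
#' for the image and nearest-neighbor for the mask (which therefore stays
#' binary).
#'
#' @param img a [fundus_image()].
#' @param mask optional [vessel_mask()] of matching size.
#' @param flip one of `"none"`, `"h"`, `"v"`, `"hv"`.
#' @param rotation degrees in `[0, 360)`, counterclockwise in `(x, y)`.
#' @return list with elements `image` and `mask` (`NULL` if no mask given).
#' @export
augment <- function(img, mask = NULL, flip = c("none", "h", "v", "hv"),
                    rotation = 0) {
  flip <- match.arg(flip)
  if (rotation < 0 || rotation >= 360) stop("rotation must lie in [0, 360)")
  stopifnot(inherits(img, "fundus_image"))
  tx_mat <- function(m, bilinear) {
    if (flip %in% c("h", "hv")) m <- m[, ncol(m):1, drop = FALSE]
    if (flip %in% c("v", "hv")) m <- m[nrow(m):1, , drop = FALSE]
    if (rotation == 0) return(m)
    if (rotation %% 90 == 0) return(rot90_exact(m, rotation %/% 90))
    n <- nrow(m)
    M <- compose_homography(max(dim(m)), rotation = -rotation)
    cpp_warp(m, unclass(M), nrow(m), ncol(m), bilinear, 0)
  }
  d <- dim(img$pixels)
  px <- img$pixels
  for (k in seq_len(d[3])) px[, , k] <- tx_mat(img$pixels[, , k], TRUE)
  out_img <- fundus_image(px, image_id = img$image_id)
  out_mask <- NULL
  if (!is.null(mask)) {
    mm <- tx_mat(unclass(mask) * 1.0, FALSE)
    out_mask <- vessel_mask((mm > 0.5) * 1L)
  }
  list(image = out_img, mask = out_mask)
}
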