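#' @useDynLib fundusreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd quantile
#' @importFrom utils read.csv write.csv head
NULL

JUNCTION_KINDS <- c("bifurcation", "crossover", "unknown")
PROVENANCES <- c("ground_truth", "detected", "calibrated")

#' Fundus image container
#'
#' A raster fundus photograph: a 2-D (grayscale) or 3-D (RGB) intensity array
#' with values on the 8-bit scale `[0, 255]` (stored as doubles). Pixel
#' origin is the top-left corner; raster indices are 1-based `(row, col)` and
#' geometric points use `(x, y) = (col, row)`.
#'
#' @param pixels numeric matrix (H x W) or array (H x W x 3), finite values.
#' @param image_id character identifier.
#' @return An object of class `fundus_image` with elements `pixels` and
#'   `image_id`.
#' @export
fundus_image <- function(pixels, image_id = "image") {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  d <- dim(pixels)
  if (length(d) != 3L || !(d[3] %in% c(1L, 3L)))
    stop("pixels must be H x W or H x W x {1,3}")
  if (d[1] < 32L || d[2] < 32L)
    stop("image must be at least 32 x 32 pixels")
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, image_id = as.character(image_id)),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image '%s' %d x %d x %d, range [%.1f, %.1f]>\n",
              x$image_id, d[1], d[2], d[3], min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) dim(x$pixels)

n_channels <- function(img) dim(img$pixels)[3]

#' Grayscale view of a fundus image
#'
#' RGB images are reduced to the green channel, which carries the highest
#' vessel-to-background contrast in fundus photography; grayscale images pass
#' through.
#'
#' @param img a [fundus_image()].
#' @return numeric matrix, same height/width.
#' @export
as_gray <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  p <- img$pixels
  if (dim(p)[3] == 3L) p[, , 2] else p[, , 1]
}

#' Binary vessel mask
#'
#' @param mask matrix of 0/1 values; 1 marks a vessel pixel.
#' @return Integer matrix of class `vessel_mask`.
#' @export
vessel_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("vessel mask values must be 0 or 1")
  storage.mode(mask) <- "integer"
  class(mask) <- c("vessel_mask", class(mask))
  mask
}

#' Binary skeleton (centerline) mask
#'
#' @param mask matrix of 0/1 values marking 1-pixel-wide vessel centerlines.
#' @return Integer matrix of class `skeleton_mask`.
#' @export
skeleton_mask <- function(mask) {
  mask <- as.matrix(unclass(mask))
  if (!all(mask %in% c(0, 1))) stop("skeleton mask values must be 0 or 1")
  storage.mode(mask) <- "integer"
  class(mask) <- c("skeleton_mask", class(mask))
  mask
}

#' Junction point table
#'
#' Vascular landmarks (bifurcations and crossovers) as a data frame with one
#' row per point. Coordinates are 1-based raster indices.
#'
#' @param row,col integer pixel coordinates (1-based).
#' @param kind one of `"bifurcation"`, `"crossover"`, `"unknown"` (recycled).
#' @param score detection confidence in `[0, 1]`; 1 for ground truth.
#' @param provenance one of `"ground_truth"`, `"detected"`, `"calibrated"`.
#' @return data.frame of class `junction_points` with columns
#'   `row`, `col`, `kind`, `score`, `provenance`.
#' @export
junction_points <- function(row = integer(), col = integer(),
                            kind = "unknown", score = 1,
                            provenance = "ground_truth") {
  n <- length(row)
  if (length(col) != n) stop("row and col lengths differ")
  df <- data.frame(row = as.integer(round(row)), col = as.integer(round(col)),
                   kind = rep_len(as.character(kind), n),
                   score = rep_len(as.numeric(score), n),
                   provenance = rep_len(as.character(provenance), n),
                   stringsAsFactors = FALSE)
  bad <- !df$kind %in% JUNCTION_KINDS
  if (any(bad)) {
    warning(sprintf("%d unknown junction kind value(s) mapped to 'unknown'",
                    sum(bad)))
    df$kind[bad] <- "unknown"
  }
  if (!all(df$provenance %in% PROVENANCES)) stop("invalid provenance")
  if (n > 0 && (any(df$row < 1) || any(df$col < 1)))
    stop("junction coordinates must be >= 1")
  if (n > 0 && (any(df$score < 0) || any(df$score > 1)))
    stop("scores must lie in [0, 1]")
  class(df) <- c("junction_points", "data.frame")
  df
}

#' Ground-truth correspondence set
#'
#' Paired control points between a reference and a sensed image, in geometric
#' `(x, y)` pixel coordinates.
#'
#' @param ref n x 2 matrix of reference-image points.
#' @param sensed n x 2 matrix of the matching sensed-image points.
#' @return list of class `correspondence_set` with matrices `ref`, `sensed`.
#' @export
correspondence_set <- function(ref, sensed) {
  ref <- as.matrix(ref); sensed <- as.matrix(sensed)
  if (nrow(ref) < 1L) stop("need at least one correspondence")
  if (!identical(dim(ref), dim(sensed)) || ncol(ref) != 2L)
    stop("ref and sensed must be n x 2 with equal n")
  if (!all(is.finite(ref)) || !all(is.finite(sensed)))
    stop("correspondence points must be finite")
  structure(list(ref = ref, sensed = sensed), class = "correspondence_set")
}

#' Confusion counts
#'
#' @param tp,fp,fn non-negative integer counts.
#' @param tn non-negative integer, or `NA` for detection tasks where true
#'   negatives are not enumerable.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn = NA_integer_) {
  v <- c(tp, fp, fn)
  if (any(v < 0) || (!is.na(tn) && tn < 0)) stop("counts must be >= 0")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_counts")
}

#' Projective homography
#'
#' A 3 x 3 projective transform mapping sensed-image pixel coordinates
#' `(a, b)` to reference-image coordinates `(a', b')`:
#' \deqn{a' = (h_{11} a + h_{12} b + h_{13}) / (h_{31} a + h_{32} b + 1)}
#' \deqn{b' = (h_{21} a + h_{22} b + h_{23}) / (h_{31} a + h_{32} b + 1)}
#' The matrix is normalized so its last element is 1.
#'
#' @param m numeric 3 x 3 matrix with nonzero `m[3,3]` and nonzero
#'   determinant.
#' @return matrix of class `homography`, normalized so `m[3,3] == 1`.
#' @export
homography <- function(m) {
  m <- as.matrix(m)
  if (!identical(dim(m), c(3L, 3L))) stop("homography must be 3 x 3")
  if (!all(is.finite(m))) stop("homography entries must be finite")
  if (abs(m[3, 3]) < 1e-12) stop("h[3,3] must be nonzero for normalization")
  m <- m / m[3, 3]
  if (abs(det(m)) < 1e-12) stop("homography must be invertible")
  class(m) <- c("homography", class(m))
  m
}

#' Convert raster indices to geometric points
#'
#' @param row,col 1-based raster indices.
#' @return n x 2 matrix of `(x, y)` coordinates.
#' @export
rc_to_xy <- function(row, col) cbind(x = as.numeric(col), y = as.numeric(row))

#' Convert geometric points to raster indices
#'
#' @param xy n x 2 matrix of `(x, y)` coordinates.
#' @return data.frame with integer `row`, `col` (nearest pixel).
#' @export
xy_to_rc <- function(xy) {
  xy <- rbind(xy)
  data.frame(row = as.integer(round(xy[, 2])), col = as.integer(round(xy[, 1])))
}
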