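#' Calibration parameters
#'
#' Window and snap radii for skeleton-based refinement of detected junction
#' points. The window must cover the detector's localization error without
#' merging adjacent junctions.
#'
#' @param window_half integer half-size of the crop window, pixels.
#' @param snap_radius integer maximum snap distance, pixels; `0` filters
#'   points without moving them.
#' @param spur_length skeleton spurs up to this length (pixels) are pruned
#'   before branches are counted, suppressing thinning artifacts on wide
#'   vessels.
#' @return list of class `calibration_params`.
#' @export
calibration_params <- function(window_half = 12L, snap_radius = 8L,
                               spur_length = 4L) {
  if (window_half < max(snap_radius, 1)) stop("window_half must be >= snap_radius >= 1")
  if (snap_radius < 0) stop("snap_radius must be >= 0")
  structure(list(window_half = as.integer(window_half),
                 snap_radius = as.integer(snap_radius),
                 spur_length = as.integer(spur_length)),
            class = "calibration_params")
}

#' Prune short skeleton spurs
#'
#' Iteratively removes endpoint pixels (crossing number 1) `iterations`
#' times. Thinning a wide vessel produces short side spurs whose roots look
#' like 3-branch junctions; pruning them removes those false candidates while
#' only shortening genuine terminal branches.
#'
#' @param skel a [skeleton_mask()].
#' @param iterations number of endpoint-removal passes.
#' @return a pruned [skeleton_mask()].
#' @export
prune_spurs <- function(skel, iterations = 4L) {
  m <- unclass(skel)
  for (k in seq_len(iterations)) {
    cn <- crossing_number_map(skeleton_mask(m))
    ends <- cn == 1L | cn == 0L
    if (!any(ends & m == 1L)) break
    m[ends] <- 0L
  }
  skeleton_mask(m)
}

#' Skeletonize a binary vessel region
#'
#' Morphological thinning (Zhang-Suen) to a 1-pixel-wide centerline. The
#' skeleton is a subset of the mask and preserves its connectivity.
#'
#' @param mask a [vessel_mask()] or binary matrix.
#' @return a [skeleton_mask()].
#' @export
skeletonize_region <- function(mask) {
  m <- unclass(as.matrix(mask))
  storage.mode(m) <- "integer"
  # pad so border vessel pixels are thinnable, then crop back
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  thin <- cpp_thin(p)
  skeleton_mask(thin[2:(nrow(m) + 1L), 2:(ncol(m) + 1L), drop = FALSE])
}

ring_offsets <- matrix(c(-1L, 0L,  -1L, 1L,  0L, 1L,  1L, 1L,
                         1L, 0L,   1L, -1L, 0L, -1L, -1L, -1L),
                       ncol = 2L, byrow = TRUE)

#' Count skeleton branches meeting at a pixel
#'
#' The crossing number: the count of 0-to-1 transitions around the pixel's
#' 8-neighborhood ring. Interior line pixels score 2, endpoints 1, and
#' junction pixels 3 or more.
#'
#' @param skeleton a [skeleton_mask()].
#' @param pixel length-2 integer `(row, col)`, must lie on the skeleton.
#' @return integer branch count.
#' @export
count_branch_neighbors <- function(skeleton, pixel) {
  m <- unclass(skeleton)
  r <- pixel[1]; c <- pixel[2]
  if (r < 1 || c < 1 || r > nrow(m) || c > ncol(m) || m[r, c] != 1)
    stop("pixel is not on the skeleton")
  ring <- vapply(seq_len(8), function(i) {
    rr <- r + ring_offsets[i, 1]; cc <- c + ring_offsets[i, 2]
    if (rr < 1 || cc < 1 || rr > nrow(m) || cc > ncol(m)) 0L else m[rr, cc]
  }, integer(1))
  sum(ring == 1L & c(ring[-1], ring[1]) == 0L)
}

crossing_number_map <- function(skel) {
  m <- unclass(skel)
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- m
  shift <- function(dr, dc) p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  rings <- lapply(seq_len(8), function(i)
    shift(ring_offsets[i, 1], ring_offsets[i, 2]))
  cn <- matrix(0L, H, W)
  for (i in seq_len(8)) {
    nxt <- rings[[if (i == 8) 1 else i + 1]]
    cn <- cn + (rings[[i]] == 1L & nxt == 0L)
  }
  cn[m == 0L] <- -1L
  cn
}

#' Detect junction candidates from a skeletonized mask
#'
#' Skeletonizes the mask and returns one point per cluster of skeleton pixels
#' whose crossing number is at least 3. Nearby branch pixels (within
#' `merge_radius`) are merged to their rounded centroid, since a thinned
#' vessel crossing often yields two adjacent 3-valent pixels rather than one
#' 4-valent pixel.
#'
#' @param mask a [vessel_mask()].
#' @param merge_radius cluster radius in pixels.
#' @param spur_length spur-pruning passes before branch counting (see
#'   [prune_spurs()]).
#' @return a [junction_points()] table with provenance `"detected"`.
#' @export
detect_junctions_skeleton <- function(mask, merge_radius = 5,
                                      spur_length = 8L) {
  skel <- prune_spurs(skeletonize_region(mask), spur_length)
  cn <- crossing_number_map(skel)
  idx <- which(cn >= 3L, arr.ind = TRUE)
  if (!nrow(idx)) return(junction_points(provenance = "detected"))
  # greedy clustering by proximity
  used <- rep(FALSE, nrow(idx))
  pts <- list()
  o <- order(-cn[idx])
  idx <- idx[o, , drop = FALSE]
  for (i in seq_len(nrow(idx))) {
    if (used[i]) next
    d2 <- (idx[, 1] - idx[i, 1])^2 + (idx[, 2] - idx[i, 2])^2
    cl <- !used & d2 <= merge_radius^2
    used[cl] <- TRUE
    pts[[length(pts) + 1L]] <- c(round(mean(idx[cl, 1])),
                                 round(mean(idx[cl, 2])))
  }
  pm <- do.call(rbind, pts)
  junction_points(row = pm[, 1], col = pm[, 2], kind = "unknown", score = 1,
                  provenance = "detected")
}

#' Calibrate junction points against the vessel skeleton
#'
#' For each point, a window is cropped from the vessel mask, skeletonized,
#' and searched for skeleton pixels where three or more branches meet
#' (crossing number >= 3). The point snaps to the nearest such pixel within
#' the snap radius, or is dropped if none exists. Calibrated points landing
#' on the same pixel are deduplicated, keeping the highest score.
#'
#' @param points a [junction_points()] table.
#' @param mask the [vessel_mask()] the points were detected on.
#' @param params a [calibration_params()].
#' @return a [junction_points()] table with provenance `"calibrated"`.
#' @export
calibrate_junctions <- function(points, mask, params = calibration_params()) {
  m <- unclass(as.matrix(mask))
  H <- nrow(m); W <- ncol(m)
  wh <- params$window_half
  out <- list()
  for (i in seq_len(nrow(points))) {
    r0 <- points$row[i]; c0 <- points$col[i]
    if (r0 < 1 || c0 < 1 || r0 > H || c0 > W)
      stop("junction point outside image bounds")
    rr <- max(1, r0 - wh):min(H, r0 + wh)
    cc <- max(1, c0 - wh):min(W, c0 + wh)
    sub <- m[rr, cc, drop = FALSE]
    if (sum(sub) == 0) next
    skel <- prune_spurs(skeletonize_region(sub), params$spur_length)
    cn <- crossing_number_map(skel)
    cand <- which(cn >= 3L, arr.ind = TRUE)
    if (!nrow(cand)) next
    cr <- cand[, 1] + rr[1] - 1L
    cl <- cand[, 2] + cc[1] - 1L
    # cluster adjacent branch pixels (a thinned crossing yields two 3-valent
    # pixels straddling the true junction); snap to the branch pixel nearest
    # the centroid of the closest cluster
    cl_id <- integer(length(cr))
    nid <- 0L
    for (k in order((cr - r0)^2 + (cl - c0)^2)) {
      near <- which(cl_id > 0L & (cr - cr[k])^2 + (cl - cl[k])^2 <= 25)
      cl_id[k] <- if (length(near)) cl_id[near[1]] else (nid <- nid + 1L)
    }
    cents <- vapply(seq_len(nid), function(id)
      c(mean(cr[cl_id == id]), mean(cl[cl_id == id])), numeric(2))
    d2 <- (cents[1, ] - r0)^2 + (cents[2, ] - c0)^2
    j <- which.min(d2)
    if (d2[j] > params$snap_radius^2) next
    sel <- which(cl_id == j)
    b <- sel[which.min((cr[sel] - cents[1, j])^2 + (cl[sel] - cents[2, j])^2)]
    out[[length(out) + 1L]] <- c(cr[b], cl[b], points$score[i])
  }
  if (!length(out)) return(junction_points(provenance = "calibrated"))
  om <- do.call(rbind, out)
  # deduplicate identical pixels, keeping the highest score
  o <- order(-om[, 3])
  om <- om[o, , drop = FALSE]
  dup <- duplicated(om[, 1:2, drop = FALSE])
  om <- om[!dup, , drop = FALSE]
  junction_points(row = om[, 1], col = om[, 2], kind = "unknown",
                  score = om[, 3], provenance = "calibrated")
}
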