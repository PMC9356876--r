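#' Parameters of the synthetic vascular tree generator
#'
#' The generator grows recursive binary trees from root stubs on the circular
#' field-of-view boundary, the way major vessel arcades enter a fundus
#' photograph. Every branching event is recorded as a ground-truth
#' bifurcation; intersections of segments from different roots are recorded
#' as crossovers.
#'
#' @param image_size square image side in pixels (>= 64).
#' @param n_roots number of root vessels entering the field of view.
#' @param branch_prob probability that a vessel bifurcates at the end of each
#'   segment (otherwise the branch terminates).
#' @param min_branch_angle,max_branch_angle half-opening angle range between
#'   the two daughter branches, degrees.
#' @param initial_width vessel diameter at the roots, pixels.
#' @param width_decay multiplicative width taper per generation, in (0, 1].
#' @param max_depth maximum tree depth in generations (>= 1); a depth-1 tree
#'   is a single unbranched vessel per root.
#' @param seed integer RNG seed.
#' @return list of class `vascular_tree_params`.
#' @export
vascular_tree_params <- function(image_size = 256L, n_roots = 3L,
                                 branch_prob = 0.85,
                                 min_branch_angle = 20, max_branch_angle = 45,
                                 initial_width = 5, width_decay = 0.82,
                                 max_depth = 6L, seed = 1L) {
  if (image_size < 64) stop("image_size must be >= 64")
  if (max_depth < 1) stop("max_depth must be >= 1")
  if (initial_width < 1) stop("initial_width must be >= 1 px")
  if (branch_prob < 0 || branch_prob > 1) stop("branch_prob must be in [0,1]")
  if (width_decay <= 0 || width_decay > 1) stop("width_decay must be in (0,1]")
  structure(list(image_size = as.integer(image_size),
                 n_roots = as.integer(n_roots), branch_prob = branch_prob,
                 min_branch_angle = min_branch_angle,
                 max_branch_angle = max_branch_angle,
                 initial_width = initial_width, width_decay = width_decay,
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "vascular_tree_params")
}

fov_geometry <- function(image_size) {
  list(cx = (image_size + 1) / 2, cy = (image_size + 1) / 2,
       radius = 0.47 * image_size)
}

fov_mask <- function(image_size) {
  g <- fov_geometry(image_size)
  xs <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE)
  ys <- matrix(seq_len(image_size), image_size, image_size)
  ((xs - g$cx)^2 + (ys - g$cy)^2 <= g$radius^2) * 1L
}

# interior intersection point of two segments, or NULL
segment_intersection <- function(ax, ay, bx, by, cx, cy, dx, dy,
                                 lo = 0.02, hi = 0.98) {
  r <- c(bx - ax, by - ay); s <- c(dx - cx, dy - cy)
  den <- r[1] * s[2] - r[2] * s[1]
  if (abs(den) < 1e-9) return(NULL)
  t <- ((cx - ax) * s[2] - (cy - ay) * s[1]) / den
  u <- ((cx - ax) * r[2] - (cy - ay) * r[1]) / den
  if (t < lo || t > hi || u < lo || u > hi) return(NULL)
  c(ax + t * r[1], ay + t * r[2])
}

point_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- if (l2 > 0) ((px - ax) * dx + (py - ay) * dy) / l2 else 0
  t <- min(max(t, 0), 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

segment_min_dist <- function(a, b) {
  if (!is.null(segment_intersection(a[1], a[2], a[3], a[4],
                                    b[1], b[2], b[3], b[4], lo = 0, hi = 1)))
    return(0)
  min(point_seg_dist(a[1], a[2], b[1], b[2], b[3], b[4]),
      point_seg_dist(a[3], a[4], b[1], b[2], b[3], b[4]),
      point_seg_dist(b[1], b[2], a[1], a[2], a[3], a[4]),
      point_seg_dist(b[3], b[4], a[1], a[2], a[3], a[4]))
}

#' Generate a synthetic vascular tree with ground-truth junctions
#'
#' Grows `n_roots` recursive binary trees inward from the field-of-view
#' boundary. Segment widths taper by `width_decay` per generation. Every
#' branching event inside the field of view is recorded as a bifurcation;
#' crossings between segments of different roots are recorded as crossovers.
#' Deterministic given `params$seed`.
#'
#' @param params a [vascular_tree_params()].
#' @return list with elements `mask` (a [vessel_mask()]) and `junctions`
#'   (a [junction_points()] table with provenance `"ground_truth"`).
#' @export
generate_vascular_tree <- function(params) {
  stopifnot(inherits(params, "vascular_tree_params"))
  s <- params$image_size
  g <- fov_geometry(s)
  min_junction_sep <- 12 # px between any two recorded junctions
  min_cross_angle <- 35 * pi / 180
  withr::with_seed(params$seed, {
    segs <- list() # x0, y0, x1, y1, halfwidth
    junc <- list() # row, col, kind (1 bif, 2 cross)
    junction_clear <- function(px, py, extra = NULL) {
      pts <- c(junc, extra)
      !length(pts) ||
        min(vapply(pts, function(j) (j[1] - py)^2 + (j[2] - px)^2,
                   numeric(1))) >= min_junction_sep^2
    }
    # a candidate segment is admissible iff every interaction with an
    # existing non-adjacent segment is a clean steep crossing far from both
    # segments' endpoints and from other junctions; returns the crossovers it
    # creates, or NULL when the segment must be rejected
    check_segment <- function(cand, hw) {
      crossings <- list()
      for (sg in segs) {
        # adjacent segments (sharing an endpoint with the candidate) merge at
        # a recorded bifurcation; skip them
        shared <- min((sg[1] - cand[1])^2 + (sg[2] - cand[2])^2,
                      (sg[3] - cand[1])^2 + (sg[4] - cand[2])^2,
                      (sg[1] - cand[3])^2 + (sg[2] - cand[4])^2,
                      (sg[3] - cand[3])^2 + (sg[4] - cand[4])^2) < 1e-6
        if (shared) next
        p <- segment_intersection(cand[1], cand[2], cand[3], cand[4],
                                  sg[1], sg[2], sg[3], sg[4])
        if (!is.null(p)) {
          v1 <- c(cand[3] - cand[1], cand[4] - cand[2])
          v2 <- c(sg[3] - sg[1], sg[4] - sg[2])
          ang <- acos(min(1, abs(sum(v1 * v2)) /
                            sqrt(sum(v1^2) * sum(v2^2))))
          endd <- min(sqrt((p[1] - c(cand[1], cand[3], sg[1], sg[3]))^2 +
                           (p[2] - c(cand[2], cand[4], sg[2], sg[4]))^2))
          if (ang < min_cross_angle || endd < 9 ||
              !junction_clear(p[1], p[2], crossings))
            return(NULL)
          crossings[[length(crossings) + 1L]] <- c(p[2], p[1], 2)
        } else if (segment_min_dist(cand, sg) < hw + sg[5] + 2) {
          return(NULL) # tangent touch: would merge without a clean crossing
        }
      }
      crossings
    }
    add_segment <- function(cand, hw) {
      cr <- check_segment(cand, hw)
      if (is.null(cr)) return(FALSE)
      segs[[length(segs) + 1L]] <<- c(cand, hw)
      junc <<- c(junc, cr)
      TRUE
    }
    # grows one branch; returns TRUE iff its first sub-segment was drawn
    grow <- function(x, y, theta, width, depth) {
      len <- 0.2 * s * 0.85^depth * runif(1, 0.85, 1.15)
      mid_theta <- theta + runif(1, -8, 8) * pi / 180
      mx <- x + cos(mid_theta) * len / 2
      my <- y + sin(mid_theta) * len / 2
      end_theta <- mid_theta + runif(1, -8, 8) * pi / 180
      ex <- mx + cos(end_theta) * len / 2
      ey <- my + sin(end_theta) * len / 2
      if (!add_segment(c(x, y, mx, my), width / 2)) return(FALSE)
      if (!add_segment(c(mx, my, ex, ey), width / 2)) return(TRUE)
      inside <- (ex - g$cx)^2 + (ey - g$cy)^2 <= (0.98 * g$radius)^2
      if (!inside || depth >= params$max_depth) return(TRUE)
      w2 <- max(1, width * params$width_decay)
      if (runif(1) < params$branch_prob && junction_clear(ex, ey)) {
        half <- runif(1, params$min_branch_angle, params$max_branch_angle) *
          pi / 180
        # the visible junction of two width-w2 daughter strokes sits where
        # their lumens separate: the medial-axis point, offset from the
        # branching corner along the bisector by (w2/2)/sin(half)
        off <- min((w2 / 2) / sin(half), 8)
        jx <- ex + off * cos(end_theta)
        jy <- ey + off * sin(end_theta)
        # tentatively record the bifurcation so children and later branches
        # keep their distance; withdrawn unless both daughters actually grow
        junc[[length(junc) + 1L]] <<- c(jy, jx, 1)
        jidx <- length(junc)
        ok1 <- grow(ex, ey, end_theta - half, w2, depth + 1L)
        ok2 <- grow(ex, ey, end_theta + half, w2, depth + 1L)
        if (!(ok1 && ok2)) junc[[jidx]] <<- NULL
      } else if (depth < params$max_depth - 1L && runif(1) < 0.5) {
        grow(ex, ey, end_theta, w2, depth + 1L)
      }
      TRUE
    }
    root_angles <- runif(1, 0, 2 * pi) +
      seq(0, 2 * pi, length.out = params$n_roots + 1L)[-(params$n_roots + 1L)]
    for (i in seq_len(params$n_roots)) {
      a <- root_angles[i] + runif(1, -0.2, 0.2)
      rx <- g$cx + g$radius * cos(a)
      ry <- g$cy + g$radius * sin(a)
      inward <- a + pi + runif(1, -0.5, 0.5)
      grow(rx, ry, inward, params$initial_width, 1L)
    }
    if (!length(segs)) stop("tree generation produced zero vessel pixels")
    sm <- do.call(rbind, segs)
    mask <- cpp_draw_segments(s, s, sm[, 1], sm[, 2], sm[, 3], sm[, 4], sm[, 5])
    mask <- mask * fov_mask(s)
    if (sum(mask) == 0) stop("tree generation produced zero vessel pixels")
    if (length(junc)) {
      jm <- do.call(rbind, junc)
      # keep junctions inside the field of view with margin
      d2 <- (jm[, 2] - g$cx)^2 + (jm[, 1] - g$cy)^2
      jm <- jm[d2 <= (0.95 * g$radius)^2, , drop = FALSE]
      # anchor each junction coordinate to the rendered geometry: the medial
      # axis (skeleton) point where the strokes actually meet, found as the
      # centroid of the nearby cluster of branch pixels (crossing number >= 3)
      if (nrow(jm)) {
        skel <- prune_spurs(skeletonize_region(vessel_mask(mask)), 4L)
        cnm <- crossing_number_map(skel)
        bp <- which(cnm >= 3L, arr.ind = TRUE)
        if (nrow(bp)) for (i in seq_len(nrow(jm))) {
          dd <- (bp[, 1] - jm[i, 1])^2 + (bp[, 2] - jm[i, 2])^2
          sel <- dd <= 36
          if (any(sel)) {
            jm[i, 1] <- mean(bp[sel, 1])
            jm[i, 2] <- mean(bp[sel, 2])
          }
        }
      }
      junctions <- junction_points(row = jm[, 1], col = jm[, 2],
                                   kind = c("bifurcation", "crossover")[jm[, 3]],
                                   score = 1, provenance = "ground_truth")
    } else {
      junctions <- junction_points()
    }
    list(mask = vessel_mask(mask), junctions = junctions)
  })
}

#' Render a fundus-style image from a vessel mask
#'
#' Fundus style draws dark vessels on a bright textured background with a
#' radial illumination gradient and additive Gaussian noise, zero outside the
#' circular field of view. Angiography style inverts the contrast (bright
#' vessels on a dark background), emulating fluorescein angiograms. Vessel
#' pixels differ from the local background by about 60 gray levels before
#' noise.
#'
#' @param mask a [vessel_mask()].
#' @param style `"fundus"` or `"angiography"`.
#' @param seed integer RNG seed for texture and noise.
#' @param noise_sd additive Gaussian noise standard deviation, gray levels.
#' @return a [fundus_image()] (grayscale).
#' @export
render_fundus <- function(mask, style = c("fundus", "angiography"), seed = 1L,
                          noise_sd = 3) {
  style <- match.arg(style)
  m <- unclass(mask)
  s <- nrow(m)
  g <- fov_geometry(s)
  fov <- fov_mask(s)
  withr::with_seed(seed, {
    xs <- matrix(seq_len(ncol(m)), s, ncol(m), byrow = TRUE)
    ys <- matrix(seq_len(s), s, ncol(m))
    rr <- sqrt((xs - g$cx)^2 + (ys - g$cy)^2) / g$radius
    texture <- cpp_gauss_blur(matrix(rnorm(length(m)), s), 8)
    texture <- 10 * texture / max(sd(texture), 1e-9)
    vess <- cpp_gauss_blur(m * 1.0, 0.7)
    vess <- pmin(vess / max(max(vess), 1e-9) * 1.4, 1)
    if (style == "fundus") {
      img <- 200 - 50 * rr^2 + texture - 60 * vess
    } else {
      img <- 45 + 20 * (1 - rr^2) + texture + 60 * vess
    }
    img <- img + rnorm(length(img), sd = noise_sd)
    img <- pmin(pmax(img, 0), 255) * fov
    fundus_image(img, image_id = paste0("synthetic_", style))
  })
}

#' Compose a projective homography from named transform components
#'
#' Rotation and scaling act about the image center; the perspective terms fill
#' the third row. The composition is
#' `H = T(center) . (s R) . T(-center) . T(t) . P` with
#' `P = [[1,0,0],[0,1,0],[p1,p2,1]]`, normalized so `H[3,3] = 1`.
#'
#' @param image_size square image side, pixels (fixes the center of rotation).
#' @param rotation degrees, counterclockwise in `(x, y)` coordinates.
#' @param translation length-2 `(tx, ty)` pixels.
#' @param scale isotropic scale factor.
#' @param perspective length-2 third-row terms `(h31, h32)`.
#' @return a [homography()].
#' @export
compose_homography <- function(image_size, rotation = 0,
                               translation = c(0, 0), scale = 1,
                               perspective = c(0, 0)) {
  c0 <- (image_size + 1) / 2
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  S <- diag(c(scale, scale, 1))
  Tc <- diag(3); Tc[1:2, 3] <- c(c0, c0)
  Tmc <- diag(3); Tmc[1:2, 3] <- -c(c0, c0)
  Tt <- diag(3); Tt[1:2, 3] <- translation
  P <- diag(3); P[3, 1:2] <- perspective
  homography(Tc %*% S %*% R %*% Tmc %*% Tt %*% P)
}

#' Generate a registered synthetic fundus image pair
#'
#' Builds a reference phantom, derives the sensed image by resampling it
#' through the inverse of a known projective homography (`true_H` maps sensed
#' to reference coordinates), and renders both with independent noise.
#' Quality `"blurred"` applies a defocus (Gaussian) kernel to the sensed image
#' only; `"inverted"` renders the sensed image in angiography style.
#'
#' @param params a [vascular_tree_params()].
#' @param rotation degrees, `|rotation| <= 45`.
#' @param translation length-2 pixels.
#' @param scale in `[0.8, 1.25]`.
#' @param perspective length-2, each `|.| <= 2e-4`.
#' @param quality `"good"`, `"blurred"` or `"inverted"`.
#' @param seed integer RNG seed for rendering noise.
#' @param blur_sigma defocus kernel sigma for `"blurred"`, pixels.
#' @return list of class `synthetic_pair` with `ref_image`, `sensed_image`,
#'   `true_mask_ref`, `true_mask_sensed`, `true_junctions_ref`,
#'   `true_junctions_sensed`, `true_H` and `quality`.
#' @export
generate_pair <- function(params, rotation = 0, translation = c(0, 0),
                          scale = 1, perspective = c(0, 0),
                          quality = c("good", "blurred", "inverted"),
                          seed = 1L, blur_sigma = 2) {
  quality <- match.arg(quality)
  if (abs(rotation) > 45) stop("|rotation| must be <= 45 degrees")
  if (scale < 0.8 || scale > 1.25) stop("scale must lie in [0.8, 1.25]")
  if (any(abs(perspective) > 2e-4)) stop("|perspective| terms must be <= 2e-4")
  s <- params$image_size
  tree <- generate_vascular_tree(params)
  true_H <- compose_homography(s, rotation, translation, scale, perspective)
  # sensed(p) = ref(true_H p): resample reference content through true_H
  sensed_mask <- cpp_warp(unclass(tree$mask) * 1.0, unclass(true_H), s, s,
                          FALSE, 0)
  fov_ref <- fov_mask(s)
  fov_sensed <- cpp_warp(fov_ref * 1.0, unclass(true_H), s, s, FALSE, 0)
  if (sum(fov_sensed) < 0.2 * sum(fov_ref))
    stop("transform pushes more than 80% of the field of view out of frame")
  sensed_mask <- vessel_mask((sensed_mask > 0.5) * 1L)
  # sensed junctions: reference junctions through the inverse map
  Hinv <- solve(unclass(true_H))
  jr <- tree$junctions
  sensed_j <- junction_points()
  keep_ref <- rep(FALSE, nrow(jr))
  if (nrow(jr)) {
    xy <- transform_point(homography(Hinv), rc_to_xy(jr$row, jr$col))
    ok <- xy[, 1] >= 2 & xy[, 1] <= s - 1 & xy[, 2] >= 2 & xy[, 2] <= s - 1
    ok[ok] <- fov_sensed[cbind(round(xy[ok, 2]), round(xy[ok, 1]))] > 0.5
    keep_ref <- ok
    sensed_j <- junction_points(row = xy[ok, 2], col = xy[ok, 1],
                                kind = jr$kind[ok], score = 1,
                                provenance = "ground_truth")
  }
  ref_img <- render_fundus(tree$mask, "fundus", seed = seed)
  sensed_style <- if (quality == "inverted") "angiography" else "fundus"
  sensed_img <- render_fundus(sensed_mask, sensed_style, seed = seed + 1L)
  if (quality == "blurred") {
    px <- cpp_gauss_blur(sensed_img$pixels[, , 1], blur_sigma) *
      (fov_mask(s) * 1.0)
    sensed_img <- fundus_image(px, image_id = sensed_img$image_id)
  }
  structure(list(ref_image = ref_img, sensed_image = sensed_img,
                 true_mask_ref = tree$mask, true_mask_sensed = sensed_mask,
                 true_junctions_ref = tree$junctions,
                 true_junctions_sensed = sensed_j,
                 true_H = true_H, quality = quality),
            class = "synthetic_pair")
}

#' Sample training patches from synthetic fundus phantoms
#'
#' Renders vascular phantoms and cuts square patches (with their true vessel
#' masks) at random positions inside the field of view, for desk-scale
#' segmentation training.
#'
#' @param n number of patches.
#' @param size patch side, pixels.
#' @param seed integer RNG seed.
#' @param image_size phantom size the patches are cut from.
#' @param min_vessel_frac patches with a smaller vessel fraction are rejected
#'   (keeps pure-background patches out of small training sets).
#' @return list of `list(image=, mask=)` pairs.
#' @export
synthetic_patches <- function(n, size = 64L, seed = 1L, image_size = 256L,
                              min_vessel_frac = 0.02) {
  out <- vector("list", n)
  withr::with_seed(seed, {
    tree_seed <- sample.int(1e6, 1)
    tr <- generate_vascular_tree(vascular_tree_params(image_size = image_size,
                                                      seed = tree_seed))
    img <- render_fundus(tr$mask, "fundus", seed = tree_seed + 1L)
    gray <- as_gray(apply_clahe(img))
    got <- 0L
    guard <- 0L
    while (got < n) {
      guard <- guard + 1L
      if (guard %% 40L == 0L) { # fresh phantom every 40 draws
        tree_seed <- sample.int(1e6, 1)
        tr <- generate_vascular_tree(vascular_tree_params(
          image_size = image_size, seed = tree_seed))
        img <- render_fundus(tr$mask, "fundus", seed = tree_seed + 1L)
        gray <- as_gray(apply_clahe(img))
      }
      r0 <- sample.int(image_size - size, 1)
      c0 <- sample.int(image_size - size, 1)
      msk <- unclass(tr$mask)[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]
      if (mean(msk) < min_vessel_frac) next
      got <- got + 1L
      out[[got]] <- list(image = gray[r0:(r0 + size - 1L),
                                      c0:(c0 + size - 1L)],
                         mask = vessel_mask(msk))
    }
  })
  out
}

#' Write a synthetic pair to a directory
#'
#' Writes `ref.png`, `sensed.png`, `mask_ref.png`, `mask_sensed.png`,
#' `junctions_ref.csv`, `junctions_sensed.csv`, `H.txt` (3 x 3 row-major) and
#' `manifest.yaml`.
#'
#' @param pair a `synthetic_pair` from [generate_pair()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(pair$ref_image, file.path(dir, "ref.png"))
  write_image(pair$sensed_image, file.path(dir, "sensed.png"))
  write_mask(pair$true_mask_ref, file.path(dir, "mask_ref.png"))
  write_mask(pair$true_mask_sensed, file.path(dir, "mask_sensed.png"))
  write_points(pair$true_junctions_ref, file.path(dir, "junctions_ref.csv"))
  write_points(pair$true_junctions_sensed, file.path(dir, "junctions_sensed.csv"))
  write_homography(pair$true_H, file.path(dir, "H.txt"))
  yaml::write_yaml(list(quality = pair$quality,
                        image_size = nrow(pair$true_mask_ref),
                        files = c("ref.png", "sensed.png", "mask_ref.png",
                                  "mask_sensed.png", "junctions_ref.csv",
                                  "junctions_sensed.csv", "H.txt")),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
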