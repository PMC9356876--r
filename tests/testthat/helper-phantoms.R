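# shared fixtures, built in code

# plus-shaped mask: two crossing bars of the given half-thickness
plus_mask <- function(n = 21L, half = 2L) {
  m <- matrix(0L, n, n)
  c0 <- (n + 1L) %/% 2L
  m[(c0 - half):(c0 + half), 4:(n - 3)] <- 1L
  m[4:(n - 3), (c0 - half):(c0 + half)] <- 1L
  vessel_mask(m)
}

# 1-px Y skeleton: three rays from the center at the given angles (degrees)
y_skeleton <- function(n = 9L, angles = c(90, 210, 330)) {
  m <- matrix(0L, n, n)
  c0 <- (n + 1L) %/% 2L
  m[c0, c0] <- 1L
  for (a in angles * pi / 180) {
    for (t in seq(1, (n - 1) / 2, by = 0.5)) {
      r <- round(c0 + t * sin(a))
      cc <- round(c0 + t * cos(a))
      if (r >= 1 && r <= n && cc >= 1 && cc <= n) m[r, cc] <- 1L
    }
  }
  skeleton_mask(m)
}

# cached default phantom (a moderately branched tree and its rendering)
test_tree <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_vascular_tree(vascular_tree_params(seed = 3))
    cache
  }
})

# sparse control-point grid inside the circular field of view
fov_grid <- function(image_size = 256L, n = 100L) {
  g <- (image_size + 1) / 2
  r <- 0.47 * image_size
  xs <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE)
  ys <- matrix(seq_len(image_size), image_size, image_size)
  idx <- which((xs - g)^2 + (ys - g)^2 <= r^2, arr.ind = TRUE)
  sel <- idx[round(seq(1, nrow(idx), length.out = n)), ]
  cbind(x = sel[, 2], y = sel[, 1])
}

# mean control-point error between an estimated and the true homography
control_point_error <- function(h_est, h_true, image_size = 256L) {
  grid <- fov_grid(image_size)
  mean(sqrt(rowSums((transform_point(h_est, grid) -
                     transform_point(h_true, grid))^2)))
}

# the seeded registration experiment used across tests: a synthetic pair with
# a randomized realistic transform, registered from ground-truth masks
registration_error_for_seed <- function(s, quality = "good") {
  set.seed(s)
  pair <- generate_pair(vascular_tree_params(seed = s),
                        rotation = runif(1, -20, 20),
                        translation = runif(2, -30, 30),
                        scale = runif(1, 0.9, 1.1),
                        perspective = runif(2, -1e-4, 1e-4),
                        quality = quality, seed = s + 100L)
  res <- register_pair(pair$ref_image, pair$sensed_image,
                       ref_mask = pair$true_mask_ref,
                       sensed_mask = pair$true_mask_sensed)
  if (res$status != "ok") return(Inf)
  control_point_error(res$homography, pair$true_H)
}

# toy detector training set: small trees on 128 px masks
jdn_toy_dataset <- function(n = 10L, image_size = 128L) {
  lapply(seq_len(n), function(s) {
    tr <- generate_vascular_tree(vascular_tree_params(
      image_size = image_size, n_roots = 2L, initial_width = 4,
      max_depth = 5L, seed = s))
    list(image = tr$mask, junctions = tr$junctions)
  })
}
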