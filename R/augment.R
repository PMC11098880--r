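#' Augmentation parameters
#'
#' Training-time point-cloud augmentation: random uniform scale about the
#' centroid, rigid translation, rotation about z, additive brightness and
#' hue rotation in HSV space, plus an optional crop to the vicinity of a
#' hand. Magnitudes emulate real-world variation (clothing shades, lighting,
#' object size); all are configurable.
#'
#' @param scale_range Uniform scale factor range.
#' @param translate_sd_m Gaussian translation SD per axis (m).
#' @param rotation_z_range_deg z-rotation range (degrees).
#' @param brightness_range Additive RGB offset range.
#' @param hue_range_deg Hue rotation range (degrees).
#' @param crop_to_hand_prob Probability that [crop_to_hands()] crops.
#' @param crop_radius_m Crop sphere radius (m).
#' @return List of class `augment_params`.
#' @export
augment_params <- function(scale_range = c(0.9, 1.1), translate_sd_m = 0.1,
                           rotation_z_range_deg = c(-180, 180),
                           brightness_range = c(-0.1, 0.1),
                           hue_range_deg = c(-10, 10),
                           crop_to_hand_prob = 0.5, crop_radius_m = 0.6) {
  stopifnot(scale_range[1] <= scale_range[2],
            rotation_z_range_deg[1] <= rotation_z_range_deg[2],
            brightness_range[1] <= brightness_range[2],
            hue_range_deg[1] <= hue_range_deg[2],
            crop_to_hand_prob >= 0, crop_to_hand_prob <= 1,
            translate_sd_m >= 0, crop_radius_m > 0)
  structure(list(scale_range = scale_range, translate_sd_m = translate_sd_m,
                 rotation_z_range_deg = rotation_z_range_deg,
                 brightness_range = brightness_range,
                 hue_range_deg = hue_range_deg,
                 crop_to_hand_prob = crop_to_hand_prob,
                 crop_radius_m = crop_radius_m), class = "augment_params")
}

identity_augment_params <- function()
  augment_params(scale_range = c(1, 1), translate_sd_m = 0,
                 rotation_z_range_deg = c(0, 0), brightness_range = c(0, 0),
                 hue_range_deg = c(0, 0), crop_to_hand_prob = 0)

shift_hue <- function(colors, deg) {
  if (deg == 0) return(colors)
  r <- colors[, 1]; g <- colors[, 2]; b <- colors[, 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  i1 <- nz & mx == r
  i2 <- nz & !i1 & mx == g
  i3 <- nz & !i1 & !i2
  h[i1] <- ((g[i1] - b[i1]) / d[i1]) %% 6
  h[i2] <- (b[i2] - r[i2]) / d[i2] + 2
  h[i3] <- (r[i3] - g[i3]) / d[i3] + 4
  h <- (h * 60 + deg) %% 360
  x <- d * (1 - abs((h / 60) %% 2 - 1))
  m <- mx - d
  hh <- as.integer(h / 60)
  rp <- gp <- bp <- numeric(length(r))
  s <- hh == 0L | hh == 5L; rp[s] <- d[s]
  s <- hh == 1L | hh == 4L; rp[s] <- x[s]
  s <- hh == 1L | hh == 2L; gp[s] <- d[s]
  s <- hh == 0L | hh == 3L; gp[s] <- x[s]
  s <- hh == 3L | hh == 4L; bp[s] <- d[s]
  s <- hh == 2L | hh == 5L; bp[s] <- x[s]
  cbind(rp + m, gp + m, bp + m)
}

#' Augment a point cloud
#'
#' One random draw per transform per call: uniform scale about the cloud
#' centroid, z-rotation about the centroid, rigid translation; additive
#' brightness then hue rotation, clipped to \[0, 1\]. Point order and any
#' instance labels are untouched.
#'
#' @param points N x 3 matrix.
#' @param colors N x 3 matrix.
#' @param params An [augment_params()].
#' @param seed Optional seed for reproducibility.
#' @return List with transformed `points` and `colors`.
#' @export
augment_cloud <- function(points, colors, params = augment_params(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(points) > 0)
  s <- stats::runif(1, params$scale_range[1], params$scale_range[2])
  th <- stats::runif(1, params$rotation_z_range_deg[1],
                     params$rotation_z_range_deg[2]) * pi / 180
  tr <- stats::rnorm(3, 0, params$translate_sd_m)
  br <- stats::runif(1, params$brightness_range[1], params$brightness_range[2])
  hu <- stats::runif(1, params$hue_range_deg[1], params$hue_range_deg[2])
  ctr <- colMeans(points)
  # compose scale-about-centroid, rotation and translation into one affine
  A <- s * t(rot_z(th))
  off <- ctr + tr - as.numeric(ctr %*% A)
  p <- points %*% A
  p[, 1] <- p[, 1] + off[1]; p[, 2] <- p[, 2] + off[2]
  p[, 3] <- p[, 3] + off[3]
  cl <- pmin(pmax(colors + br, 0), 1)
  cl <- shift_hue(cl, hu)
  list(points = p, colors = pmin(pmax(cl, 0), 1))
}

#' Augment a relation pair cloud
#'
#' The two indicator groups receive two independent transform draws,
#' simulating the pair's entities at varying relative sizes and positions.
#' The indicator channel is untouched.
#'
#' @param pair Matrix as returned by [sample_entity_clouds()] for a pair
#'   (columns x, y, z, r, g, b, ind).
#' @param params An [augment_params()].
#' @param seed Optional seed.
#' @return Augmented pair matrix.
#' @export
augment_relation_pair <- function(pair, params = augment_params(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ncol(pair) == 7L)
  for (g in c(0, 1)) {
    sel <- pair[, 7] == g
    if (!any(sel)) next
    a <- augment_cloud(pair[sel, 1:3, drop = FALSE],
                       pair[sel, 4:6, drop = FALSE], params)
    pair[sel, 1:3] <- a$points
    pair[sel, 4:6] <- a$colors
  }
  pair
}

# geometry-only augmentation draw (scale, z-rotation, translation) applied
# as one composed affine; used on the per-entity / per-pair hot path where
# the color draw has already been applied frame-wide
augment_geom <- function(points, params) {
  s <- stats::runif(1, params$scale_range[1], params$scale_range[2])
  th <- stats::runif(1, params$rotation_z_range_deg[1],
                     params$rotation_z_range_deg[2]) * pi / 180
  tr <- stats::rnorm(3, 0, params$translate_sd_m)
  ctr <- colMeans(points)
  A <- s * t(rot_z(th))
  off <- ctr + tr - as.numeric(ctr %*% A)
  p <- points %*% A
  p[, 1] <- p[, 1] + off[1]; p[, 2] <- p[, 2] + off[2]
  p[, 3] <- p[, 3] + off[3]
  p
}

#' Crop a cloud to the vicinity of a hand
#'
#' With probability `crop_to_hand_prob`, keeps only points within
#' `crop_radius_m` of one uniformly chosen wrist joint; implicitly trains
#' relation heads to concentrate on hand-held instruments. Never empties a
#' cloud: a crop that would remove everything passes through.
#'
#' @param points,colors Point cloud matrices.
#' @param poses List of [human_pose()] supplying wrist joints.
#' @param params An [augment_params()].
#' @param seed Optional seed.
#' @return List with `points`, `colors` and logical `kept` (indices kept).
#' @export
crop_to_hands <- function(points, colors, poses, params = augment_params(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep_all <- list(points = points, colors = colors,
                   kept = seq_len(nrow(points)))
  if (!length(poses)) {
    warning("crop_to_hands: no poses; passing through")
    return(keep_all)
  }
  if (stats::runif(1) >= params$crop_to_hand_prob) return(keep_all)
  wrists <- do.call(rbind, lapply(poses, function(p)
    p$joints[c("wrist_l", "wrist_r"), , drop = FALSE]))
  w <- wrists[sample.int(nrow(wrists), 1), ]
  d <- sqrt(rowSums(sweep(points, 2, w)^2))
  kept <- which(d <= params$crop_radius_m)
  if (!length(kept)) return(keep_all)
  list(points = points[kept, , drop = FALSE],
       colors = colors[kept, , drop = FALSE], kept = kept)
}
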