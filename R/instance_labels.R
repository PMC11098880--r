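# distance from every point to segment [a, b]
point_segment_dist <- function(points, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) return(sqrt(rowSums(sweep(points, 2, a)^2)))
  t <- pmin(pmax((sweep(points, 2, a) %*% ab) / len2, 0), 1)
  proj <- outer(as.numeric(t), ab) + matrix(a, nrow(points), 3, byrow = TRUE)
  sqrt(rowSums((points - proj)^2))
}

points_in_box <- function(points, box, margin = 0) {
  local <- sweep(points, 2, box$center)
  if (box$yaw != 0) local <- local %*% rot_z(box$yaw) # inverse rotation
  abs(local[, 1]) <= box$size[1] / 2 + margin &
    abs(local[, 2]) <= box$size[2] / 2 + margin &
    abs(local[, 3]) <= box$size[3] / 2 + margin
}

#' Assign instance labels from detected poses and boxes
#'
#' Every point gets at most one label by precedence: (1) points inside
#' exactly one object box take that object (overlaps resolved to the box
#' with the nearest center); (2) remaining points within `r_body` of any
#' skeleton bone segment take the nearest such person; (3) remaining points
#' within `r_hand` of a wrist joint form that person's virtual instrument,
#' provided at least `min_instrument_points` qualify; (4) everything else is
#' background (`-1`).
#'
#' @param cloud A [point_cloud_frame()] (existing labels are overwritten).
#' @param poses List of [human_pose()].
#' @param boxes List of [object_box()]; names used as entity ids (fallback:
#'   class names).
#' @param params List with `r_body` (default 0.15 m, about limb thickness),
#'   `r_hand` (0.25 m, covers held tools), `min_instrument_points` (20),
#'   `box_margin` (0.02 m inflation absorbing sensor jitter at box faces).
#' @return The cloud with `labels` and an `entities` registry filled in.
#' @export
compute_instance_labels <- function(cloud, poses, boxes,
                                    params = list(r_body = 0.15,
                                                  r_hand = 0.25,
                                                  min_instrument_points = 20L,
                                                  box_margin = 0.02)) {
  pts <- cloud$points
  n <- nrow(pts)
  reg_id <- character(0); reg_class <- character(0)
  add_entity <- function(id, class) {
    reg_id <<- c(reg_id, id); reg_class <<- c(reg_class, class)
    length(reg_id)
  }
  labels <- rep(-1L, n)
  # 1. boxes (overlaps -> nearest box center)
  if (length(boxes)) {
    ids <- names(boxes)
    if (is.null(ids)) ids <- vapply(boxes, `[[`, "", "class_name")
    box_lab <- integer(length(boxes))
    d2c <- matrix(Inf, n, length(boxes))
    inb <- matrix(FALSE, n, length(boxes))
    for (k in seq_along(boxes)) {
      box_lab[k] <- add_entity(ids[k], boxes[[k]]$class_name)
      inb[, k] <- points_in_box(pts, boxes[[k]], params$box_margin %||% 0)
      d2c[, k] <- rowSums(sweep(pts, 2, boxes[[k]]$center)^2)
    }
    d2c[!inb] <- Inf
    hit <- rowSums(inb) > 0
    if (any(hit)) labels[hit] <- box_lab[max.col(-d2c[hit, , drop = FALSE])]
  }
  # 2. human bodies (nearest bone segment within r_body)
  if (length(poses)) {
    free <- labels == -1L
    dbody <- matrix(Inf, n, length(poses))
    hum_lab <- integer(length(poses))
    bp <- bone_pairs()
    for (k in seq_along(poses)) {
      hum_lab[k] <- add_entity(poses[[k]]$person_id, "human")
      j <- poses[[k]]$joints
      dbody[, k] <- min_segment_dist(pts, j[bp[, 1], , drop = FALSE],
                                     j[bp[, 2], , drop = FALSE])
    }
    near <- free & apply(dbody, 1, min) <= params$r_body
    if (any(near))
      labels[near] <- hum_lab[max.col(-dbody[near, , drop = FALSE])]
    # 3. virtual instruments at the hands
    free <- labels == -1L
    for (k in seq_along(poses)) {
      j <- poses[[k]]$joints
      dw <- pmin(sqrt(rowSums(sweep(pts, 2, j["wrist_l", ])^2)),
                 sqrt(rowSums(sweep(pts, 2, j["wrist_r", ])^2)))
      cand <- free & dw <= params$r_hand
      if (sum(cand) >= params$min_instrument_points) {
        lab <- add_entity(paste0("instrument_", poses[[k]]$person_id),
                          "instrument")
        labels[cand] <- lab
        free <- labels == -1L
      }
    }
  }
  point_cloud_frame(pts, cloud$colors, labels,
                    entities = data.frame(label = seq_along(reg_id),
                                          entity_id = reg_id,
                                          class_name = reg_class,
                                          stringsAsFactors = FALSE))
}

#' Fixed-size point samples for entities and pairs
#'
#' Uniform random sampling of an entity's points, with replacement iff fewer
#' points than requested. For a pair, the union of both entities' points is
#' sampled and every point carries a which-entity indicator channel (0 =
#' first entity, 1 = second).
#'
#' @param cloud A labeled [point_cloud_frame()].
#' @param ids One entity id (character) or a length-2 vector for a pair.
#' @param n_points Sample size (conventionally 4000 for entities, 8000 for
#'   pairs).
#' @return Matrix with columns x, y, z, r, g, b, ind; or a list with
#'   `empty = TRUE` when no entity point exists (the caller substitutes a
#'   missing-geometry embedding).
#' @export
sample_entity_clouds <- function(cloud, ids, n_points = if (length(ids) == 2L)
  8000L else 4000L) {
  stopifnot(!is.null(cloud$labels), !is.null(cloud$entities))
  labs <- cloud$entities$label[match(ids, cloud$entities$entity_id)]
  if (anyNA(labs)) stop("unknown entity id: ",
                        paste(ids[is.na(labs)], collapse = ", "))
  idx <- which(cloud$labels %in% labs)
  if (!length(idx)) return(list(empty = TRUE, ids = ids))
  take <- if (length(idx) >= n_points) sample(idx, n_points)
          else sample(idx, n_points, replace = TRUE)
  ind <- if (length(ids) == 2L) as.numeric(cloud$labels[take] == labs[2]) else
    rep(0, n_points)
  cbind(cloud$points[take, , drop = FALSE],
        cloud$colors[take, , drop = FALSE], ind = ind)
}
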