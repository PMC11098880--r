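#' Simulator configuration
#'
#' The stated world of the simulator: a 1 Hz, ~11 minute total knee
#' replacement take with four staff (head surgeon, assistant surgeon,
#' circulating nurse, anaesthetist) plus the patient, captured from six
#' ceiling viewpoints. Instruments share one shape and differ only in color,
#' which deliberately makes tool-use relations unresolvable from the
#' human-patient pair geometry alone and resolvable from images.
#'
#' @param seed RNG seed for the take.
#' @param take_length_s Take duration in seconds (default 660, the average
#'   recording length of the real dataset).
#' @param fps Frames per second (default 1, the capture protocol).
#' @param phase_duration_weights Positive fractions over the 8 canonical
#'   phases (normalized internally).
#' @param n_staff Staff besides the patient, 2..4; staff are dropped from the
#'   back of (head surgeon, assistant, nurse, anaesthetist).
#' @param noise List: `relation_dropout_rate`, `relation_swap_rate`
#'   (graph corruption; see [inject_noise()]) and `pose_jitter_sd_m`
#'   (Gaussian joint jitter).
#' @param points_per_entity Surface points sampled per entity (instruments
#'   get 30\% of this, small objects being sparsely captured).
#' @param n_views Number of orthographic camera views.
#' @param image_res Image resolution in pixels per side.
#' @param theta_close Centroid distance threshold (m) for `CloseTo`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, take_length_s = 660, fps = 1,
                       phase_duration_weights = c(0.08, 0.05, 0.15, 0.17,
                                                  0.18, 0.12, 0.05, 0.20),
                       n_staff = 4L,
                       noise = list(relation_dropout_rate = 0,
                                    relation_swap_rate = 0,
                                    pose_jitter_sd_m = 0.01),
                       points_per_entity = 300L, n_views = 6L,
                       image_res = 48L, theta_close = 1.5) {
  stopifnot(take_length_s > 0, fps > 0,
            length(phase_duration_weights) == 8L,
            all(phase_duration_weights >= 0),
            sum(phase_duration_weights) > 0,
            n_staff >= 2L, n_staff <= 4L,
            noise$relation_dropout_rate >= 0, noise$relation_dropout_rate <= 1,
            noise$relation_swap_rate >= 0, noise$relation_swap_rate <= 1,
            points_per_entity > 0, n_views >= 1)
  structure(list(seed = as.integer(seed), take_length_s = take_length_s,
                 fps = fps,
                 phase_duration_weights = phase_duration_weights /
                   sum(phase_duration_weights),
                 n_staff = as.integer(n_staff), noise = noise,
                 points_per_entity = as.integer(points_per_entity),
                 n_views = as.integer(n_views),
                 image_res = as.integer(image_res),
                 theta_close = theta_close),
            class = "sim_config")
}

#' Static OR layout
#'
#' Equipment poses, sizes and a color map. All static objects are muted
#' grey-blue; the per-action instrument colors are fully saturated and are
#' the only saturated colors in the room (color-only instrument coding).
#'
#' @return An object of class `or_layout` with `boxes` (named list of
#'   [object_box()]) and `colors` (named list of RGB triples).
#' @export
or_layout <- function() {
  boxes <- list(
    op_table = object_box("operating table", c(0, 0, 0.45), c(2.0, 0.8, 0.9)),
    anesthesia = object_box("anesthesia equipment", c(-2.2, 1.5, 0.75),
                            c(0.6, 0.6, 1.5)),
    instr_table = object_box("instrument table", c(2.0, 1.5, 0.45),
                             c(1.2, 0.6, 0.9)),
    sec_table = object_box("secondary table", c(2.0, -1.5, 0.45),
                           c(1.0, 0.6, 0.9)))
  colors <- list(
    op_table = c(0.55, 0.55, 0.58), anesthesia = c(0.45, 0.48, 0.55),
    instr_table = c(0.62, 0.62, 0.62), sec_table = c(0.50, 0.50, 0.50),
    floor = c(0.35, 0.35, 0.35),
    hs = c(0.30, 0.42, 0.45), as = c(0.35, 0.45, 0.38),
    cn = c(0.45, 0.40, 0.45), an = c(0.38, 0.38, 0.48),
    patient = c(0.72, 0.70, 0.66))
  structure(list(boxes = boxes, colors = colors), class = "or_layout")
}

#' Per-action instrument colors
#'
#' Instruments are geometrically identical small blocks; only their color
#' identifies the tool (and hence the action).
#' @return Named list mapping action relation to RGB.
#' @export
instrument_colors <- function() {
  list(Cutting = c(0.95, 0.05, 0.05), Drilling = c(0.05, 0.85, 0.05),
       Sawing = c(0.05, 0.25, 0.95), Hammering = c(0.95, 0.85, 0.05),
       Suturing = c(0.85, 0.05, 0.85), Cementing = c(0.05, 0.85, 0.85),
       Preparing = c(0.95, 0.50, 0.05), Cleaning = c(0.50, 0.05, 0.95))
}

#' 3D object bounding box
#'
#' @param class_name Entity class.
#' @param center xyz center (m).
#' @param size xyz extents (m), positive.
#' @param yaw Rotation about z (radians).
#' @return An object of class `object_box`.
#' @export
object_box <- function(class_name, center, size, yaw = 0) {
  stopifnot(length(center) == 3L, length(size) == 3L, all(size > 0))
  structure(list(class_name = class_name, center = as.numeric(center),
                 size = as.numeric(size), yaw = as.numeric(yaw)),
            class = "object_box")
}

staff_ids <- function(n_staff) c("hs", "as", "cn", "an")[seq_len(n_staff)]

staff_roles <- function() c(hs = "head surgeon", as = "assistant surgeon",
                            cn = "circulating nurse", an = "anaesthetist")

# stations: where each person stands, per broad phase block
staff_station <- function(who, in_surgery) {
  switch(who,
    hs = if (in_surgery) c(0.45, -0.65) else c(0.35, -1.95),
    as = if (in_surgery) c(1.05, -0.60) else c(1.30, -1.45),
    cn = c(1.45, 0.90),
    an = c(-1.55, 1.00))
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
}

standing_pose_joints <- function(center_xy, heading = 0) {
  perp <- c(-sin(heading), cos(heading))
  fwd <- c(cos(heading), sin(heading))
  at <- function(lat, fw, z) c(center_xy + lat * perp + fw * fwd, z)
  j <- rbind(
    head = at(0, 0, 1.68), neck = at(0, 0, 1.52),
    shoulder_l = at(0.20, 0, 1.45), shoulder_r = at(-0.20, 0, 1.45),
    elbow_l = at(0.26, 0.03, 1.15), elbow_r = at(-0.26, 0.03, 1.15),
    wrist_l = at(0.24, 0.08, 0.90), wrist_r = at(-0.24, 0.08, 0.90),
    hip_l = at(0.12, 0, 0.95), hip_r = at(-0.12, 0, 0.95),
    knee_l = at(0.13, 0.02, 0.50), knee_r = at(-0.13, 0.02, 0.50),
    ankle_l = at(0.13, 0.04, 0.08), ankle_r = at(-0.13, 0.04, 0.08))
  j[joint_names(), , drop = FALSE]
}

lying_pose_joints <- function(center_xy = c(0.05, 0), z = 1.02) {
  cx <- center_xy[1]; cy <- center_xy[2]
  j <- rbind(
    head = c(cx - 0.70, cy, z + 0.04), neck = c(cx - 0.55, cy, z + 0.02),
    shoulder_l = c(cx - 0.48, cy + 0.18, z),
    shoulder_r = c(cx - 0.48, cy - 0.18, z),
    elbow_l = c(cx - 0.18, cy + 0.22, z), elbow_r = c(cx - 0.18, cy - 0.22, z),
    wrist_l = c(cx + 0.10, cy + 0.20, z), wrist_r = c(cx + 0.10, cy - 0.20, z),
    hip_l = c(cx + 0.10, cy + 0.12, z), hip_r = c(cx + 0.10, cy - 0.12, z),
    knee_l = c(cx + 0.45, cy + 0.10, z + 0.03),
    knee_r = c(cx + 0.45, cy - 0.10, z + 0.03),
    ankle_l = c(cx + 0.75, cy + 0.08, z), ankle_r = c(cx + 0.75, cy - 0.08, z))
  j[joint_names(), , drop = FALSE]
}

# reach the right arm so the wrist lands at `target` (exactly), elbow halfway
reach_arm <- function(joints, target) {
  sh <- joints["shoulder_r", ]
  joints["wrist_r", ] <- target
  joints["elbow_r", ] <- (sh + target) / 2 + c(0, 0, 0.06)
  joints
}

bone_pairs <- function() {
  rbind(c("head", "neck"), c("neck", "shoulder_l"), c("neck", "shoulder_r"),
        c("shoulder_l", "elbow_l"), c("shoulder_r", "elbow_r"),
        c("elbow_l", "wrist_l"), c("elbow_r", "wrist_r"),
        c("shoulder_l", "hip_l"), c("shoulder_r", "hip_r"),
        c("hip_l", "hip_r"),
        c("hip_l", "knee_l"), c("hip_r", "knee_r"),
        c("knee_l", "ankle_l"), c("knee_r", "ankle_r"))
}

torso_centroid <- function(joints)
  colMeans(joints[c("shoulder_l", "shoulder_r", "hip_l", "hip_r"), ])

# ---- phase schedule -------------------------------------------------------

phase_frame_counts <- function(n_frames, weights) {
  raw <- weights * n_frames
  counts <- floor(raw)
  rem <- n_frames - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# scripted foreground activity for one frame; t1 is 1-based index within phase
phase_script <- function(phase_idx, t1, n_staff) {
  acts <- list() # each: list(actor, relation, target, blob)
  add <- function(actor, relation, target, blob = NA_character_)
    acts[[length(acts) + 1L]] <<- list(actor = actor, relation = relation,
                                       target = target, blob = blob)
  has <- function(who) who %in% staff_ids(n_staff)
  cyc <- ((t1 - 1L) %% 10L) + 1L
  if (phase_idx == 1L) {
    if (has("cn")) add("cn", "Cleaning", "instr_table", "Cleaning")
    if (has("as") && cyc <= 5L) add("as", "Touching", "sec_table")
    if (has("an") && cyc <= 6L) add("an", "Touching", "anesthesia")
  } else if (phase_idx == 2L) {
    if (has("an") && cyc <= 6L) add("an", "Touching", "anesthesia")
    if (has("cn") && cyc <= 4L) add("cn", "Touching", "instr_table")
  } else if (phase_idx == 3L) {
    add("hs", "Preparing", "patient", "Preparing")
    if (has("as")) add("as", "Preparing", "patient", "Preparing")
    if (has("an") && cyc <= 6L) add("an", "Touching", "anesthesia")
  } else if (phase_idx == 4L) {
    rel <- if (cyc <= 4L) "Cutting" else if (cyc <= 7L) "Drilling" else "Sawing"
    add("hs", rel, "patient", rel)
    if (has("as")) add("as", "Assisting", "hs")
    if (has("cn") && cyc <= 3L) add("cn", "Touching", "instr_table")
  } else if (phase_idx == 5L) {
    rel <- if (cyc <= 4L || cyc >= 9L) "Hammering"
           else if (cyc <= 6L) "Operating" else "Suturing"
    add("hs", rel, "patient", if (rel == "Operating") NA_character_ else rel)
    if (has("as")) add("as", "Assisting", "hs")
  } else if (phase_idx == 6L) {
    add("hs", "Cementing", "patient", "Cementing")
    if (has("as")) add("as", "Assisting", "hs")
  } else if (phase_idx == 7L) {
    if (has("an") && cyc <= 6L) add("an", "Touching", "anesthesia")
  } else {
    if (has("cn")) add("cn", "Cleaning", "instr_table", "Cleaning")
    if (has("as") && cyc <= 5L) add("as", "Touching", "sec_table")
  }
  acts
}

box_face_point <- function(box, towards_xy) {
  # point on the box face nearest to an outside xy position, at hand height
  d <- towards_xy - box$center[1:2]
  half <- box$size[1:2] / 2
  p <- box$center[1:2] + pmin(pmax(d, -half), half)
  # push slightly outside the face along the dominant axis
  ax <- which.max(abs(d) / half)
  p[ax] <- box$center[ax] + sign(d[ax]) * (half[ax] + 0.10)
  # hand hovers above the working surface rather than brushing the face
  c(p, min(box$center[3] + box$size[3] / 2 + 0.12, 1.08))
}

#' Geometric and scripted relations for one frame
#'
#' Merges the scripted action edges with the two geometric predicates:
#' `LyingOn` when a human torso centroid is horizontally within a table
#' footprint and 0-0.5 m above its top, and `CloseTo` when a human subject's
#' centroid is within `theta_close` of another entity (human-human proximity
#' thus appears once per direction). Precedence per ordered pair:
#' scripted action > LyingOn > CloseTo.
#'
#' @param centroids Named list of entity centroids (humans: torso centroid).
#' @param human_ids Character vector of human node ids.
#' @param torso Named list of torso centroids for humans.
#' @param boxes Named list of [object_box()].
#' @param scripted Data frame of scripted edges (subject, relation, object).
#' @param theta_close CloseTo threshold (m).
#' @return Edge data frame (subject, relation, object).
#' @export
relations_from_geometry <- function(centroids, human_ids, torso, boxes,
                                    scripted, theta_close = 1.5) {
  edges <- scripted
  key <- function(s, o) paste(s, o, sep = "\r")
  taken <- if (nrow(edges)) key(edges$subject, edges$object) else character(0)
  add <- function(s, r, o) {
    if (!(key(s, o) %in% taken)) {
      edges <<- rbind(edges, data.frame(subject = s, relation = r, object = o,
                                        stringsAsFactors = FALSE))
      taken <<- c(taken, key(s, o))
    }
  }
  # LyingOn
  for (h in human_ids) {
    tc <- torso[[h]]
    for (bn in names(boxes)) {
      b <- boxes[[bn]]
      top <- b$center[3] + b$size[3] / 2
      within <- all(abs(tc[1:2] - b$center[1:2]) <= b$size[1:2] / 2)
      if (within && tc[3] > top && tc[3] - top < 0.5) add(h, "LyingOn", bn)
    }
  }
  # CloseTo (human subject only; instruments excluded)
  others <- setdiff(names(centroids), grep("^instrument", names(centroids),
                                           value = TRUE))
  for (h in human_ids) {
    for (o in setdiff(others, h)) {
      if (sqrt(sum((centroids[[h]] - centroids[[o]])^2)) < theta_close)
        add(h, "CloseTo", o)
    }
  }
  edges
}

# ---- point sampling -------------------------------------------------------

sample_box_points <- function(box, n, color, jitter_sd = 0.008) {
  half <- box$size / 2
  areas <- c(half[2] * half[3], half[2] * half[3], half[1] * half[3],
             half[1] * half[3], half[1] * half[2], half[1] * half[2]) * 4
  face <- sample.int(6, n, replace = TRUE, prob = areas)
  u <- stats::runif(n, -1, 1); v <- stats::runif(n, -1, 1)
  pts <- matrix(0, n, 3)
  sgn <- ifelse(face %% 2 == 1, 1, -1)
  ax <- ceiling(face / 2) # 1=x faces, 2=y faces, 3=z faces
  for (a in 1:3) {
    sel <- ax == a
    if (!any(sel)) next
    rest <- setdiff(1:3, a)
    pts[sel, a] <- sgn[sel] * half[a]
    pts[sel, rest[1]] <- u[sel] * half[rest[1]]
    pts[sel, rest[2]] <- v[sel] * half[rest[2]]
  }
  if (box$yaw != 0) pts <- pts %*% t(rot_z(box$yaw))
  pts <- sweep(pts, 2, box$center, "+") +
    matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3)
  list(points = pts, colors = matrix(rep(color, each = n), n, 3) +
         matrix(stats::rnorm(3 * n, 0, 0.015), n, 3))
}

sample_human_points <- function(joints, n, color, jitter_sd = 0.008) {
  bp <- bone_pairs()
  a <- joints[bp[, 1], , drop = FALSE]
  b <- joints[bp[, 2], , drop = FALSE]
  len <- sqrt(rowSums((b - a)^2))
  radius <- ifelse(bp[, 1] %in% c("shoulder_l", "shoulder_r", "hip_l") &
                     bp[, 2] %in% c("hip_l", "hip_r"), 0.09, 0.05)
  bone <- sample.int(nrow(bp), n, replace = TRUE, prob = pmax(len, 1e-6))
  t <- stats::runif(n)
  base <- a[bone, ] + t * (b[bone, ] - a[bone, ])
  # radial offset in a random direction perpendicular-ish to the bone
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-9)
  pts <- base + dir * radius[bone] * sqrt(stats::runif(n)) +
    matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3)
  list(points = pts, colors = matrix(rep(color, each = n), n, 3) +
         matrix(stats::rnorm(3 * n, 0, 0.015), n, 3))
}

sample_cube_points <- function(center, half, n, color, jitter_sd = 0.004) {
  pts <- matrix(stats::runif(3 * n, -half, half), n, 3)
  pts <- sweep(pts, 2, center, "+") +
    matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3)
  list(points = pts, colors = matrix(rep(color, each = n), n, 3) +
         matrix(stats::rnorm(3 * n, 0, 0.01), n, 3))
}

#' Render a frame to a point cloud and orthographic views
#'
#' Every entity contributes Gaussian-perturbed surface points of its
#' primitive (boxes for equipment, limb capsules for humans, a small block
#' for instruments) carrying its color; a floor plane contributes background
#' points. Views are orthographic projections with z-buffering from
#' `n_views` azimuths at 45 degrees elevation.
#'
#' @param ents Named list of per-entity geometry descriptors (internal).
#' @param layout An [or_layout()].
#' @param config A [sim_config()].
#' @return List: `cloud` (a [point_cloud_frame()] with ground-truth instance
#'   labels and entity registry) and `images` (list of res x res x 3 arrays).
#' @export
render_frame <- function(ents, layout, config) {
  ppe <- config$points_per_entity
  parts <- list(); labels <- integer(0)
  reg_id <- character(0); reg_class <- character(0)
  li <- 0L
  for (id in names(ents)) {
    e <- ents[[id]]
    n <- if (e$kind == "instrument") max(10L, as.integer(0.3 * ppe)) else ppe
    s <- switch(e$kind,
      box = sample_box_points(e$box, n, e$color),
      human = sample_human_points(e$joints, n, e$color),
      instrument = sample_cube_points(e$center, 0.02, n, e$color))
    li <- li + 1L
    reg_id <- c(reg_id, id); reg_class <- c(reg_class, e$class)
    parts[[length(parts) + 1L]] <- s
    labels <- c(labels, rep(li, n))
  }
  # background floor
  nf <- max(50L, as.integer(1.3 * ppe))
  fl <- list(points = cbind(stats::runif(nf, -3, 3), stats::runif(nf, -2.5, 2.5),
                            stats::rnorm(nf, 0, 0.005)),
             colors = matrix(rep(layout$colors$floor, each = nf), nf, 3) +
               matrix(stats::rnorm(3 * nf, 0, 0.01), nf, 3))
  parts[[length(parts) + 1L]] <- fl
  labels <- c(labels, rep(-1L, nf))
  pts <- do.call(rbind, lapply(parts, `[[`, "points"))
  cols <- pmin(pmax(do.call(rbind, lapply(parts, `[[`, "colors")), 0), 1)
  dimnames(pts) <- dimnames(cols) <- NULL
  cloud <- point_cloud_frame(pts, cols, labels,
                             entities = data.frame(label = seq_along(reg_id),
                                                   entity_id = reg_id,
                                                   class_name = reg_class,
                                                   stringsAsFactors = FALSE))
  images <- render_views(pts, cols, config$n_views, config$image_res)
  list(cloud = cloud, images = images)
}

render_views <- function(points, colors, n_views, res) {
  lapply(seq_len(n_views), function(v) {
    az <- 2 * pi * (v - 1) / n_views
    el <- pi / 4
    d <- c(cos(az) * cos(el), sin(az) * cos(el), -sin(el)) # viewing direction
    up <- c(0, 0, 1)
    r <- c(-sin(az), cos(az), 0)                           # right vector
    u <- c(up - sum(up * d) * d); u <- u / sqrt(sum(u^2))
    x <- points %*% r; y <- points %*% u; depth <- points %*% d
    span <- 7
    px <- pmin(pmax(floor((x / span + 0.5) * res) + 1, 1), res)
    py <- pmin(pmax(floor((y / span + 0.5) * res) + 1, 1), res)
    cell <- (py - 1) * res + px
    ord <- order(depth, decreasing = TRUE) # nearest (smallest depth) last
    img <- array(0, c(res, res, 3))
    idx <- cell[ord]
    img[cbind(py[ord], px[ord], 1)] <- colors[ord, 1]
    img[cbind(py[ord], px[ord], 2)] <- colors[ord, 2]
    img[cbind(py[ord], px[ord], 3)] <- colors[ord, 3]
    img
  })
}

# ---- the timeline ---------------------------------------------------------

#' Simulate one take
#'
#' Walks the eight canonical phases (durations proportional to the configured
#' weights), emitting for each 1 Hz frame the phase-appropriate scripted
#' actions with geometrically consistent poses (the acting hand within 0.4 m
#' of the patient knee, the scripted instrument block placed at the hand),
#' the geometric relations, and optionally the rendered geometry.
#' Reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param geometry If FALSE, skip point-cloud/image rendering (fast path for
#'   graph-level experiments); poses, boxes and graphs are still produced.
#' @return List of frame bundles, each with `frame_id`, `phase_idx`,
#'   `gt_phase`, `gt_graph`, `gt_roles`, `poses`, `boxes`, and (with
#'   geometry) `cloud` and `images`. The attribute `"take"` carries take-level
#'   metadata.
#' @export
simulate_timeline <- function(config = sim_config(), geometry = TRUE) {
  set.seed(config$seed)
  layout <- or_layout()
  phases <- surgical_phases()
  n_frames <- as.integer(round(config$take_length_s * config$fps))
  counts <- phase_frame_counts(n_frames, config$phase_duration_weights)
  if (all(counts == 0)) stop("zero-length phase schedule")
  phase_of <- rep(seq_len(8L), counts)
  t_in <- unlist(lapply(counts, seq_len), use.names = FALSE)
  staff <- staff_ids(config$n_staff)
  roles <- c(staff_roles()[staff], patient = "patient")
  jsd <- config$noise$pose_jitter_sd_m
  colors <- layout$colors
  icolors <- instrument_colors()
  bundles <- vector("list", n_frames)
  sway_phase <- stats::runif(4, 0, 2 * pi)
  for (f in seq_len(n_frames)) {
    pi_ <- phase_of[f]
    patient_here <- pi_ >= 2L && pi_ <= 7L
    acts <- phase_script(pi_, t_in[f], config$n_staff)
    in_surgery <- pi_ >= 3L && pi_ <= 6L
    # poses
    joints <- list()
    if (patient_here) joints$patient <- lying_pose_joints()
    for (si in seq_along(staff)) {
      who <- staff[si]
      st <- staff_station(who, in_surgery)
      st <- st + 0.06 * c(sin(2 * pi * f / 37 + sway_phase[si]),
                          cos(2 * pi * f / 29 + sway_phase[si]))
      heading <- atan2(-st[2], -st[1]) # face room center
      joints[[who]] <- standing_pose_joints(st, heading)
    }
    # reach arms + instruments for scripted actions
    instruments <- list()
    scripted <- data.frame(subject = character(), relation = character(),
                           object = character(), stringsAsFactors = FALSE)
    for (a in acts) {
      if (a$target == "patient" && !patient_here) next
      if (a$target == "patient") {
        # the head surgeon works at the knee; a second actor (joint patient
        # preparation) works on the shin so hands and tools never collide
        knee <- if (a$actor == "hs") joints$patient["knee_r", ] else
          (joints$patient["knee_r", ] + joints$patient["ankle_r", ]) / 2
        sh <- joints[[a$actor]]["shoulder_r", ]
        dir <- sh - knee; dir <- dir / sqrt(sum(dir^2))
        wrist <- knee + 0.33 * dir
        joints[[a$actor]] <- reach_arm(joints[[a$actor]], wrist)
      } else if (a$target %in% names(layout$boxes)) {
        tc <- torso_centroid(joints[[a$actor]])
        wrist <- box_face_point(layout$boxes[[a$target]], tc[1:2])
        joints[[a$actor]] <- reach_arm(joints[[a$actor]], wrist)
      }
      scripted <- rbind(scripted,
                        data.frame(subject = a$actor, relation = a$relation,
                                   object = a$target, stringsAsFactors = FALSE))
      if (!is.na(a$blob)) {
        w <- joints[[a$actor]]["wrist_r", ]
        ref <- if (a$target == "patient") joints$patient["knee_r", ] else
          c(layout$boxes[[a$target]]$center[1:2], w[3])
        v <- ref - w
        u <- c(-v[2], v[1], 0)
        nu <- sqrt(sum(u^2))
        u <- if (nu < 1e-6) c(1, 0, 0) else u / nu
        iid <- paste0("instrument_", a$actor)
        instruments[[iid]] <- list(center = w + 0.2 * u,
                                   color = icolors[[a$blob]])
        scripted <- rbind(scripted,
                          data.frame(subject = a$actor, relation = "Holding",
                                     object = iid, stringsAsFactors = FALSE))
      }
    }
    # pose jitter (after geometry so contracts hold within jitter magnitude)
    if (jsd > 0)
      joints <- lapply(joints, function(j)
        j + matrix(stats::rnorm(length(j), 0, jsd), nrow(j), 3))
    # entities and centroids
    torso <- lapply(joints, torso_centroid)
    centroids <- c(torso, lapply(layout$boxes, `[[`, "center"),
                   lapply(instruments, `[[`, "center"))
    human_ids <- names(joints)
    edges <- relations_from_geometry(centroids, human_ids, torso,
                                     layout$boxes, scripted,
                                     config$theta_close)
    nodes <- c(
      lapply(human_ids, function(h)
        entity(h, if (h == "patient") "patient" else "human",
               centroid = torso[[h]])),
      lapply(names(layout$boxes), function(b)
        entity(b, layout$boxes[[b]]$class_name,
               centroid = layout$boxes[[b]]$center)),
      lapply(names(instruments), function(i)
        entity(i, "instrument", centroid = instruments[[i]]$center)))
    gt_graph <- scene_graph(f, nodes, edges)
    poses <- lapply(human_ids, function(h) human_pose(h, joints[[h]]))
    bundle <- list(frame_id = f, phase_idx = pi_, gt_phase = phases[pi_],
                   gt_graph = gt_graph,
                   gt_roles = roles[intersect(names(roles), human_ids)],
                   poses = poses,
                   boxes = layout$boxes)
    if (geometry) {
      ents <- c(
        stats::setNames(lapply(names(layout$boxes), function(b)
          list(kind = "box", box = layout$boxes[[b]],
               class = layout$boxes[[b]]$class_name,
               color = colors[[b]])), names(layout$boxes)),
        stats::setNames(lapply(human_ids, function(h)
          list(kind = "human", joints = joints[[h]],
               class = if (h == "patient") "patient" else "human",
               color = colors[[if (h == "patient") "patient" else h]])),
          human_ids),
        stats::setNames(lapply(names(instruments), function(i)
          list(kind = "instrument", center = instruments[[i]]$center,
               class = "instrument", color = instruments[[i]]$color)),
          names(instruments)))
      rf <- render_frame(ents, layout, config)
      bundle$cloud <- rf$cloud
      bundle$images <- rf$images
    }
    bundles[[f]] <- bundle
  }
  attr(bundles, "take") <- list(seed = config$seed, roles = roles,
                                phases = phases[phase_of], config = config)
  bundles
}

#' Ground-truth scene sequence of a simulated take
#'
#' @param bundles Output of [simulate_timeline()].
#' @param take_id Take identifier.
#' @param with_roles If TRUE, ground-truth clinical roles are applied to the
#'   human nodes.
#' @return A [scene_sequence()].
#' @export
take_sequence <- function(bundles, take_id = "sim", with_roles = FALSE) {
  tk <- attr(bundles, "take")
  seq <- scene_sequence(take_id, lapply(bundles, `[[`, "gt_graph"),
                        fps = if (is.null(tk)) 1 else tk$config$fps)
  if (with_roles) {
    roles <- if (is.null(tk)) {
      # reconstruct from the per-frame ground truth when the take attribute
      # was lost (e.g. a sliced bundle list)
      do.call(c, lapply(bundles, `[[`, "gt_roles"))[]
    } else tk$roles
    seq <- apply_roles(seq, roles[!duplicated(names(roles))])
  }
  seq
}

#' Corrupt ground-truth graphs with edge noise
#'
#' Each edge is independently dropped with probability `dropout`; each
#' surviving edge is relabeled to a uniformly random *other* relation with
#' probability `swap`. Node sets are untouched. Produces "predicted-like"
#' graphs for downstream robustness experiments.
#'
#' @param sequence A [scene_sequence()] (or list of graphs).
#' @param dropout,swap Rates in \[0, 1\].
#' @param seed RNG seed.
#' @param relations A [relation_vocabulary()].
#' @return Object of the same shape with corrupted edges.
#' @export
inject_noise <- function(sequence, dropout = 0.2, swap = 0.05, seed = 1L,
                         relations = relation_vocabulary()) {
  stopifnot(dropout >= 0, dropout <= 1, swap >= 0, swap <= 1)
  set.seed(seed)
  corrupt <- function(g) {
    e <- g$edges
    if (nrow(e)) {
      keep <- stats::runif(nrow(e)) >= dropout
      e <- e[keep, , drop = FALSE]
      if (nrow(e)) {
        do_swap <- stats::runif(nrow(e)) < swap
        for (k in which(do_swap))
          e$relation[k] <- sample(setdiff(relations$names, e$relation[k]), 1)
      }
      g$edges <- e
    }
    g
  }
  if (inherits(sequence, "ssg_sequence")) {
    sequence$graphs <- lapply(sequence$graphs, corrupt)
    sequence
  } else lapply(sequence, corrupt)
}
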