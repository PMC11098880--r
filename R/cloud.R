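#' Colored point-cloud frame
#'
#' @param points N x 3 numeric matrix of positions (m).
#' @param colors N x 3 numeric matrix of RGB in \[0, 1\].
#' @param labels Optional integer vector of per-point instance labels
#'   (`-1` = background, positive values index rows of `entities`).
#' @param entities Optional registry data frame (`label`, `entity_id`,
#'   `class_name`) mapping label values to entities.
#' @return An object of class `point_cloud_frame`.
#' @export
point_cloud_frame <- function(points, colors, labels = NULL, entities = NULL) {
  points <- as.matrix(points); colors <- as.matrix(colors)
  stopifnot(ncol(points) == 3L, ncol(colors) == 3L,
            nrow(points) == nrow(colors))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    stopifnot(length(labels) == nrow(points))
    if (!is.null(entities))
      stopifnot(all(labels %in% c(-1L, entities$label)))
  }
  structure(list(points = points, colors = colors, labels = labels,
                 entities = entities), class = "point_cloud_frame")
}

#' @export
print.point_cloud_frame <- function(x, ...) {
  cat(sprintf("<point cloud> %d points%s\n", nrow(x$points),
              if (is.null(x$labels)) "" else sprintf(
                ", %d instances", length(setdiff(unique(x$labels), -1L)))))
  invisible(x)
}

#' Read and write ASCII PLY point clouds
#'
#' Minimal ASCII PLY (xyz as float properties, rgb as uchar 0-255), the
#' interchange format for fused OR captures. Instance labels travel in a
#' sidecar text file (one integer per line, aligned with point order), see
#' [write_labels()].
#'
#' @param cloud A [point_cloud_frame()].
#' @param path Output/input file path.
#' @return `read_ply` returns a `point_cloud_frame`; `write_ply` returns
#'   `path` invisibly.
#' @export
write_ply <- function(cloud, path) {
  n <- nrow(cloud$points)
  header <- c("ply", "format ascii 1.0", sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green",
              "property uchar blue", "end_header")
  rgb <- round(pmin(pmax(cloud$colors, 0), 1) * 255)
  body <- paste(formatC(cloud$points[, 1], format = "g", digits = 8),
                formatC(cloud$points[, 2], format = "g", digits = 8),
                formatC(cloud$points[, 3], format = "g", digits = 8),
                rgb[, 1], rgb[, 2], rgb[, 3])
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("malformed PLY: no end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines[1:end], value = TRUE)[1]))
  m <- do.call(rbind, lapply(strsplit(trimws(lines[end + seq_len(nv)]), " +"),
                             as.numeric))
  point_cloud_frame(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE] / 255)
}

#' Instance-label sidecar files
#'
#' @param cloud A labeled [point_cloud_frame()].
#' @param path File path (plain text, one integer label per line).
#' @return `read_labels` returns an integer vector.
#' @export
write_labels <- function(cloud, path) {
  stopifnot(!is.null(cloud$labels))
  writeLines(as.character(cloud$labels), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) as.integer(readLines(path))

#' Read and write PPM images
#'
#' Plain-text PPM (P3), used for the simulator's rendered views.
#' @param img res x res x 3 array in \[0, 1\].
#' @param path File path.
#' @return `read_ppm` returns such an array.
#' @export
write_ppm <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  v <- round(pmin(pmax(aperm(img, c(3, 2, 1)), 0), 1) * 255)
  writeLines(c("P3", sprintf("%d %d", w, h), "255",
               paste(as.integer(v), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  stopifnot(tok[1] == "P3")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.numeric(tok[4])
  v <- as.numeric(tok[-(1:4)]) / mx
  aperm(array(v, c(3, w, h)), c(3, 2, 1))
}

#' Write a simulated take to disk
#'
#' One PLY + label sidecar per frame, PPM images per view, poses and boxes as
#' JSON, ground-truth graphs as a scene-sequence JSON.
#'
#' @param bundles Output of [simulate_timeline()] (with geometry).
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_take <- function(bundles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in bundles) {
    stem <- file.path(dir, sprintf("frame_%04d", b$frame_id))
    if (!is.null(b$cloud)) {
      write_ply(b$cloud, paste0(stem, ".ply"))
      write_labels(b$cloud, paste0(stem, ".labels.txt"))
      for (v in seq_along(b$images))
        write_ppm(b$images[[v]], sprintf("%s_view%d.ppm", stem, v))
    }
    meta <- list(
      poses = lapply(b$poses, function(p)
        list(person_id = p$person_id, joints = p$joints)),
      boxes = lapply(names(b$boxes), function(nm)
        list(id = nm, class = b$boxes[[nm]]$class_name,
             center = b$boxes[[nm]]$center, size = b$boxes[[nm]]$size,
             yaw = b$boxes[[nm]]$yaw)))
    if (!is.null(b$cloud) && !is.null(b$cloud$entities))
      meta$entities <- b$cloud$entities
    jsonlite::write_json(meta, paste0(stem, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  # ground-truth export carries the ground-truth roles
  write_scene_sequence(take_sequence(bundles, with_roles = TRUE),
                       file.path(dir, "graphs.json"))
  invisible(dir)
}

#' Read a take written by [write_take()]
#'
#' @param dir Take directory.
#' @param use_images Load the PPM views.
#' @return List of frames consumable by [train_sgg()] / [predict_graph()]
#'   (each with `cloud`, `images`, `gt_graph`, `poses`, `frame_id`).
#' @export
read_take <- function(dir, use_images = TRUE) {
  gfile <- file.path(dir, "graphs.json")
  sq <- if (file.exists(gfile)) read_scene_sequence(gfile)
  plys <- sort(list.files(dir, pattern = "^frame_[0-9]+\\.ply$"))
  lapply(plys, function(p) {
    stem <- sub("\\.ply$", "", p)
    fid <- as.integer(sub("frame_", "", stem))
    cloud <- read_ply(file.path(dir, p))
    lf <- file.path(dir, paste0(stem, ".labels.txt"))
    meta <- jsonlite::read_json(file.path(dir, paste0(stem, ".meta.json")),
                                simplifyVector = TRUE)
    if (file.exists(lf))
      cloud <- point_cloud_frame(cloud$points, cloud$colors, read_labels(lf),
                                 entities = meta$entities)
    imgs <- NULL
    if (use_images) {
      vf <- sort(list.files(dir, pattern = paste0("^", stem, "_view[0-9]+\\.ppm$")))
      if (length(vf)) imgs <- lapply(file.path(dir, vf), read_ppm)
    }
    poses <- lapply(seq_len(nrow(meta$poses)), function(k)
      human_pose(meta$poses$person_id[k],
                 matrix(meta$poses$joints[[k]], ncol = 3,
                        dimnames = list(joint_names(), NULL))))
    gt <- if (!is.null(sq)) {
      hit <- which(vapply(sq$graphs, `[[`, 1L, "frame_id") == fid)
      if (length(hit)) sq$graphs[[hit]]
    }
    list(cloud = cloud, images = imgs, gt_graph = gt, poses = poses,
         frame_id = fid)
  })
}
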