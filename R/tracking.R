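#' Solve the linear assignment problem
#'
#' Minimum-cost bipartite matching (Kuhn-Munkres with potentials, O(n^3)).
#' Rectangular matrices are handled by implicit padding; with more columns
#' than rows every row is matched, otherwise some rows stay unmatched.
#'
#' @param cost Numeric matrix of nonnegative finite costs (rows = workers,
#'   columns = jobs).
#' @return Integer vector `a` of length `nrow(cost)`: `a[i]` is the column
#'   assigned to row `i`, or `NA` if unmatched.
#' @export
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  stopifnot(all(is.finite(cost)))
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  flip <- nr > nc
  if (flip) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1) # p[j+1] = row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    way <- integer(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  if (flip) {
    back <- rep(NA_integer_, nc) # original rows
    for (i in seq_len(n)) if (!is.na(ans[i])) back[ans[i]] <- i
    ans <- back
  }
  ans
}

#' 14-joint skeleton
#'
#' @param person_id Detection or person identifier.
#' @param joints 14 x 3 numeric matrix of joint positions (m), rows named
#'   head, neck, l/r shoulder, elbow, wrist, hip, knee, ankle.
#' @param confidence Optional per-joint confidences in \[0, 1\].
#' @return An object of class `human_pose`.
#' @export
human_pose <- function(person_id, joints, confidence = rep(1, 14)) {
  joints <- as.matrix(joints)
  stopifnot(nrow(joints) == 14L, ncol(joints) == 3L, all(is.finite(joints)))
  if (is.null(rownames(joints))) rownames(joints) <- joint_names()
  structure(list(person_id = as.character(person_id), joints = joints,
                 confidence = confidence), class = "human_pose")
}

#' @rdname human_pose
#' @export
joint_names <- function() {
  c("head", "neck",
    "shoulder_l", "shoulder_r", "elbow_l", "elbow_r", "wrist_l", "wrist_r",
    "hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r")
}

pose_distance <- function(a, b) mean(sqrt(rowSums((a$joints - b$joints)^2)))

#' Build per-person tracks by Hungarian matching of skeletons
#'
#' For every adjacent frame pair the optimal assignment minimizing mean
#' 14-joint Euclidean distance links detections to live tracks; links costlier
#' than `gate` are rejected, terminating the old track and starting a new one.
#' The returned tracks partition all detections.
#'
#' @param pose_frames List (one element per frame, in temporal order) of lists
#'   of [human_pose()]. Empty frames allowed.
#' @param frame_ids Optional integer frame ids (default `seq_along`).
#' @param gate Maximum mean joint distance (m) for a link; default 0.8.
#' @return List of tracks: each a list with `track_id` and `frames`, a named
#'   character vector mapping frame id to the detection's person id.
#' @export
build_tracks <- function(pose_frames, frame_ids = seq_along(pose_frames),
                         gate = 0.8) {
  tracks <- list()
  live <- integer(0)       # indices into tracks
  live_pose <- list()      # last pose of each live track
  next_id <- 1L
  for (f in seq_along(pose_frames)) {
    dets <- pose_frames[[f]]
    nd <- length(dets)
    assigned_track <- rep(NA_integer_, nd)
    if (length(live) && nd) {
      cost <- matrix(0, length(live), nd)
      for (i in seq_along(live)) for (j in seq_len(nd))
        cost[i, j] <- pose_distance(live_pose[[i]], dets[[j]])
      a <- hungarian_assign(cost)
      for (i in seq_along(live))
        if (!is.na(a[i]) && cost[i, a[i]] <= gate) assigned_track[a[i]] <- live[i]
    }
    new_live <- integer(0); new_pose <- list()
    for (j in seq_len(nd)) {
      ti <- assigned_track[j]
      if (is.na(ti)) { # birth
        ti <- next_id; next_id <- next_id + 1L
        tracks[[ti]] <- list(track_id = sprintf("T%03d", ti),
                             frames = character(0))
      }
      fr <- tracks[[ti]]$frames
      fr[[as.character(frame_ids[f])]] <- dets[[j]]$person_id
      tracks[[ti]]$frames <- fr
      new_live <- c(new_live, ti)
      new_pose[[length(new_pose) + 1L]] <- dets[[j]]
    }
    live <- new_live; live_pose <- new_pose
  }
  tracks
}

#' Attach selected scene graphs to a track
#'
#' A track of duration K' keeps `K = min(K', max_graphs)` graphs sampled
#' uniformly along its extent, each with the track's human node marked as the
#' target node.
#'
#' @param track A track from [build_tracks()].
#' @param sequence The take's [scene_sequence()] (frame ids must cover the
#'   track).
#' @param max_graphs Upper bound on K (default 32).
#' @return The track with `selected_graphs` (list of graphs), `target_nodes`
#'   (character vector of node ids) and `K` filled in.
#' @export
select_track_graphs <- function(track, sequence, max_graphs = 32L) {
  fids <- vapply(sequence$graphs, function(g) g$frame_id, integer(1))
  tf <- as.integer(names(track$frames))
  K <- min(length(tf), max_graphs)
  pick <- tf[unique(round(seq(1, length(tf), length.out = K)))]
  idx <- match(pick, fids)
  if (anyNA(idx)) stop("track references frames absent from the sequence")
  track$selected_graphs <- sequence$graphs[idx]
  track$target_nodes <- unname(track$frames[as.character(pick)])
  track$K <- length(idx)
  track
}
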