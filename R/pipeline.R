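#' Score tracks and assign clinical roles for a take
#'
#' Convenience wrapper over the tracking / scoring / assignment chain:
#' builds tracks from the per-frame poses, attaches each track's selected
#' graphs, scores roles heuristically or with a learned model, and runs the
#' greedy bijective assignment.
#'
#' @param pose_frames List (per frame) of lists of [human_pose()].
#' @param sequence The take's [scene_sequence()] (typically predicted graphs).
#' @param method `"heuristic"` or `"learned"`.
#' @param model A [train_role_model()] model (required for `"learned"`).
#' @param frame_ids Frame ids matching `pose_frames`.
#' @param gate Tracking gate (m).
#' @return List: `tracks`, `scores` (a [role_score_matrix()]), `assignment`
#'   (role per track), `node_roles` (named role vector over human node ids,
#'   usable with [apply_roles()]).
#' @export
assign_take_roles <- function(pose_frames, sequence,
                              method = c("heuristic", "learned"),
                              model = NULL,
                              frame_ids = seq_along(pose_frames),
                              gate = 0.8) {
  method <- match.arg(method)
  tracks <- build_tracks(pose_frames, frame_ids, gate)
  tracks <- lapply(tracks, select_track_graphs, sequence = sequence)
  rows <- lapply(tracks, function(tr) {
    if (method == "heuristic") heuristic_role_scores(tr)
    else learned_role_scores(tr, model)
  })
  scores <- role_score_matrix(rows, vapply(tracks, `[[`, "", "track_id"))
  assignment <- assign_roles(scores)
  node_roles <- character(0)
  for (k in seq_along(tracks)) {
    if (is.na(assignment[k])) next
    for (nid in unique(unname(tracks[[k]]$frames)))
      node_roles[nid] <- assignment[k]
  }
  list(tracks = tracks, scores = scores, assignment = assignment,
       node_roles = node_roles)
}
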