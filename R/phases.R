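#' Latched surgery milestones
#'
#' `surgery_started` latches on the first patient-preparation or operative
#' action; `surgery_finished` latches on the first frame, after cementing has
#' been observed, on which no operative action fires (cementing marks the
#' conclusion, so the cessation of surgical actions afterwards means the
#' surgery is over). Both flags are monotone within a take and
#' `finished` implies `started`.
#'
#' @return An object of class `phase_state`.
#' @export
phase_state <- function() {
  structure(list(surgery_started = FALSE, surgery_finished = FALSE,
                 cement_seen = FALSE, previous_phase = "OR Preparation"),
            class = "phase_state")
}

graph_has_patient <- function(graph) {
  for (n in graph$nodes)
    if (node_label(n) == "patient" || n$class_name == "patient") return(TRUE)
  FALSE
}

graph_has_role <- function(graph) {
  for (n in graph$nodes) if (!is.null(n$role)) return(TRUE)
  FALSE
}

#' Surgical phase of a single frame
#'
#' Evaluates the eight transparent rules in priority order on a
#' role-augmented scene graph, threading the latched [phase_state()]:
#' specific operative triplets (cementing, hammering, cutting, joint
#' preparing) dominate; then patient presence combined with the
#' started/finished flags resolves roll-in/roll-out and preparation/cleanup;
#' any frame firing no rule inherits the previous frame's phase.
#'
#' @param graph A [scene_graph()] whose human nodes carry clinical roles
#'   (see [apply_roles()]).
#' @param state A [phase_state()].
#' @return List with `phase` (one of [surgical_phases()]) and the updated
#'   `state`.
#' @export
phase_of_frame <- function(graph, state = phase_state()) {
  if (length(graph$nodes) && !graph_has_role(graph))
    stop("no clinical roles on graph nodes; assign roles first (see assign_roles/apply_roles)")
  ph <- NA_character_
  if (has_triplet(graph, "head surgeon", "Cementing", "patient")) {
    ph <- "Surgery 3: Conclusion"; state$cement_seen <- TRUE
  } else if (has_triplet(graph, "head surgeon", "Hammering", "patient")) {
    ph <- "Surgery 2: Implant Placement"
  } else if (has_triplet(graph, "head surgeon", "Cutting", "patient")) {
    ph <- "Surgery 1: Implant Placement Preparation"
  } else if (has_triplet(graph, "head surgeon", "Preparing", "patient") &&
             has_triplet(graph, "assistant surgeon", "Preparing", "patient")) {
    ph <- "Patient Preparation"
  }
  if (!is.na(ph)) {
    state$surgery_started <- TRUE
  } else {
    # operative actions have ceased after cementing: surgery is finished
    if (state$cement_seen) state$surgery_finished <- TRUE
    pat <- graph_has_patient(graph)
    if (pat && !state$surgery_started) ph <- "Patient Roll-In"
    else if (pat && state$surgery_finished) ph <- "Patient Roll-Out"
    else if (!pat && !state$surgery_started) ph <- "OR Preparation"
    else if (!pat && state$surgery_finished) ph <- "OR Cleanup"
    else ph <- state$previous_phase
  }
  state$previous_phase <- ph
  list(phase = ph, state = state)
}

majority_smooth <- function(labels, w) {
  if (w <= 1 || length(labels) < 2) return(labels)
  stopifnot(w %% 2 == 1)
  h <- (w - 1) %/% 2
  n <- length(labels)
  out <- labels
  for (i in seq_len(n)) {
    win <- labels[max(1, i - h):min(n, i + h)]
    tab <- table(win)
    best <- names(tab)[tab == max(tab)]
    # majority; ties keep the original label if tied, else earliest in window
    out[i] <- if (labels[i] %in% best) labels[i] else win[win %in% best][1]
  }
  out
}

#' Recognize surgical phases over a take
#'
#' Left-to-right fold of [phase_of_frame()] threading the latched state,
#' optionally followed by sliding-window majority smoothing (odd `w`;
#' `w = 1`, the default, disables smoothing — useful against noisy predicted
#' graphs, disabled for faithfulness to the plain rule list).
#'
#' @param sequence A role-augmented [scene_sequence()].
#' @param w Odd smoothing window length.
#' @return Character vector of per-frame phases, same length as the take.
#' @export
recognize_phases <- function(sequence, w = 1) {
  graphs <- if (inherits(sequence, "ssg_sequence")) sequence$graphs else sequence
  state <- phase_state()
  out <- character(length(graphs))
  for (i in seq_along(graphs)) {
    res <- phase_of_frame(graphs[[i]], state)
    out[i] <- res$phase
    state <- res$state
  }
  majority_smooth(out, w)
}
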