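tool_use_relations <- function()
  c("Cutting", "Drilling", "Sawing", "Hammering", "Suturing", "Cementing")

#' Default heuristic role-evidence table
#'
#' Each row adds `weight` to `role` whenever the track's target node is the
#' `direction` end of an edge labeled `relation` (optionally restricted to a
#' partner of class `partner`). The head surgeon collects tool-use and
#' operating relations as subject, the patient collects lying-on as subject
#' and tool-use as object, the assistant collects assisting/holding/preparing,
#' the circulating nurse and the anaesthetist collect contact/proximity with
#' the instrument table and the anesthesia equipment respectively.
#'
#' @return Data frame with columns `role`, `relation`, `direction`
#'   (`"subject"`/`"object"`), `partner` (class label or NA), `weight`.
#' @export
role_evidence_table <- function() {
  rbind(
    data.frame(role = "head surgeon",
               relation = c(tool_use_relations(), "Operating"),
               direction = "subject", partner = NA_character_, weight = 1),
    data.frame(role = "patient", relation = "LyingOn", direction = "subject",
               partner = NA_character_, weight = 1),
    data.frame(role = "patient", relation = tool_use_relations(),
               direction = "object", partner = NA_character_, weight = 1),
    data.frame(role = "assistant surgeon",
               relation = c("Assisting", "Holding", "Preparing"),
               direction = "subject", partner = NA_character_, weight = 1),
    data.frame(role = "circulating nurse",
               relation = c("Cleaning", "Touching", "CloseTo"),
               direction = "subject", partner = "instrument table", weight = 1),
    data.frame(role = "anaesthetist", relation = c("CloseTo", "Touching"),
               direction = "subject", partner = "anesthesia equipment",
               weight = 1))
}

#' Heuristic role likelihoods for one track
#'
#' Counts, over the track's selected graphs, the relations incident to the
#' track's target node, weighted by [role_evidence_table()]; rows are
#' Laplace-smoothed and normalized to sum 1, so an edgeless track scores
#' uniform 1/5.
#'
#' @param track A track with `selected_graphs` and `target_nodes` (see
#'   [select_track_graphs()]).
#' @param table Evidence table; see [role_evidence_table()].
#' @param eps Laplace smoothing constant.
#' @return Named numeric vector over [clinical_roles()], summing to 1.
#' @export
heuristic_role_scores <- function(track, table = role_evidence_table(),
                                  eps = 0.1) {
  roles <- clinical_roles()
  score <- stats::setNames(numeric(length(roles)), roles)
  for (k in seq_along(track$selected_graphs)) {
    g <- track$selected_graphs[[k]]
    nid <- track$target_nodes[[k]]
    e <- g$edges
    if (!nrow(e)) next
    cls <- node_classes(g)
    for (r in seq_len(nrow(e))) {
      for (dir in c("subject", "object")) {
        if (e[[dir]][r] != nid) next
        partner_id <- if (dir == "subject") e$object[r] else e$subject[r]
        hits <- table$relation == e$relation[r] & table$direction == dir &
          (is.na(table$partner) | table$partner == unname(cls[partner_id]))
        if (any(hits))
          score[table$role[hits]] <- score[table$role[hits]] + table$weight[hits]
      }
    }
  }
  score <- score + eps
  score / sum(score)
}

#' Role score matrix
#'
#' @param rows List or matrix of per-track role score rows (each summing
#'   to 1).
#' @param track_ids Optional row names.
#' @return Numeric tracks x 5 matrix, rows normalized to sum 1.
#' @export
role_score_matrix <- function(rows, track_ids = NULL) {
  m <- if (is.matrix(rows)) rows else do.call(rbind, rows)
  colnames(m) <- clinical_roles()
  if (!is.null(track_ids)) rownames(m) <- track_ids
  if (any(m < 0)) stop("role scores must be nonnegative")
  if (any(abs(rowSums(m) - 1) > 1e-9)) stop("rows must sum to 1")
  m
}

#' Greedy bijective role assignment
#'
#' The printed sequential procedure: pick the globally highest (track, role)
#' probability among unassigned tracks and still-available roles, assign it,
#' remove that role from every other track's row, renormalize the remaining
#' rows to sum 1, and repeat until every track has a role or roles are
#' exhausted. Ties break deterministically by lower track index, then role
#' order. An all-zero row after deletions receives the first remaining role.
#'
#' With `method = "hungarian"` a globally optimal max-probability matching is
#' computed instead (comparison variant, not the default).
#'
#' @param scores A [role_score_matrix()].
#' @param method `"greedy"` (the printed algorithm) or `"hungarian"`.
#' @param trace If TRUE, attach attribute `"trace"`: the score matrix after
#'   every deletion/renormalization step (rows of still-open tracks over
#'   still-open roles).
#' @return Named character vector: role per track (NA for surplus tracks).
#' @export
#' @examples
#' m <- role_score_matrix(rbind(c(.6,.3,.1,0,0), c(.5,.4,.1,0,0),
#'                              c(.1,.2,.7,0,0)))
#' assign_roles(m)[1:3] # head surgeon, assistant surgeon, patient
assign_roles <- function(scores, method = c("greedy", "hungarian"),
                         trace = FALSE) {
  method <- match.arg(method)
  steps <- list()
  roles <- colnames(scores)
  nt <- nrow(scores)
  out <- stats::setNames(rep(NA_character_, nt), rownames(scores))
  if (method == "hungarian") {
    a <- hungarian_assign(-scores) # maximize total probability
    out[] <- ifelse(is.na(a), NA_character_, roles[a])
    return(out)
  }
  w <- scores
  track_open <- rep(TRUE, nt)
  role_open <- rep(TRUE, ncol(scores))
  while (any(track_open) && any(role_open)) {
    sub <- w
    sub[!track_open, ] <- -Inf
    sub[, !role_open] <- -Inf
    best <- max(sub)
    if (!is.finite(best)) break
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    ti <- hit[["row"]]; ri <- hit[["col"]]
    if (best == 0) { # degenerate all-zero rows: fall back to tie-break order
      ti <- which(track_open)[1]
      ri <- which(role_open)[1]
      warning("all-zero role row; assigned remaining role by tie-break")
    }
    out[ti] <- roles[ri]
    track_open[ti] <- FALSE
    role_open[ri] <- FALSE
    # remove the role from the remaining rows and renormalize them to sum 1
    for (t in which(track_open)) {
      w[t, ri] <- 0
      s <- sum(w[t, role_open])
      if (s > 0) w[t, role_open] <- w[t, role_open] / s
    }
    if (trace)
      steps[[length(steps) + 1L]] <- w[track_open, role_open, drop = FALSE]
  }
  if (trace) attr(out, "trace") <- steps
  out
}
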