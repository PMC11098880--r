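#' Harmonic F1
#'
#' `2pr/(p+r)`, defined as 0 when `p + r = 0`.
#' @param precision,recall Numeric vectors in \[0, 1\] (recycled).
#' @return Numeric vector of F1 scores.
#' @export
#' @examples
#' harmonic_f1(0.36, 0.72) # 0.48
harmonic_f1 <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE))
    stop("precision and recall must lie in [0, 1]")
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Macro average
#'
#' Unweighted arithmetic mean over per-class values; sample-size agnostic, so
#' rare classes (a handful of cutting or drilling events per take) weigh as
#' much as ubiquitous ones.
#' @param values Numeric vector of per-class values.
#' @return Scalar mean.
#' @export
macro_average <- function(values) {
  if (!length(values)) stop("macro_average of an empty vector")
  mean(as.numeric(values))
}

#' Per-class and macro precision/recall/F1 from parallel label vectors
#'
#' @param predicted,truth Character vectors of equal length.
#' @param classes Character vector fixing the class universe. Classes absent
#'   from both truth and prediction are listed with zero scores but excluded
#'   from the macro average (a class that never occurs and is never predicted
#'   carries no information); undefined precision/recall count as 0.
#' @return An object of class `class_scores`: list with `per_class` (data
#'   frame `class`, `precision`, `recall`, `f1`, `support`), `macro` (named
#'   numeric), and `confusion` (classes x classes matrix, rows = truth).
#' @export
prf_scores <- function(predicted, truth, classes) {
  stopifnot(length(predicted) == length(truth))
  bad <- setdiff(unique(c(predicted, truth)), classes)
  if (length(bad)) stop("labels outside class universe: ", paste(bad, collapse = ", "))
  pf <- factor(predicted, levels = classes)
  tf <- factor(truth, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) == 0, 0, tp / colSums(cm))
  rec <- ifelse(rowSums(cm) == 0, 0, tp / rowSums(cm))
  f1 <- harmonic_f1(prec, rec)
  per <- data.frame(class = classes, precision = as.numeric(prec),
                    recall = as.numeric(rec), f1 = as.numeric(f1),
                    support = as.numeric(rowSums(cm)),
                    stringsAsFactors = FALSE, row.names = NULL)
  active <- rowSums(cm) > 0 | colSums(cm) > 0
  if (!any(active)) active[] <- TRUE
  structure(list(per_class = per,
                 macro = c(precision = macro_average(per$precision[active]),
                           recall = macro_average(per$recall[active]),
                           f1 = macro_average(per$f1[active])),
                 confusion = unclass(cm)),
            class = "class_scores")
}

#' @export
print.class_scores <- function(x, ...) {
  p <- x$per_class
  p[, 2:4] <- round(p[, 2:4], 2)
  print(p, row.names = FALSE)
  cat(sprintf("macro: precision %.2f  recall %.2f  f1 %.2f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

pair_labels_of_graph <- function(graph, ids, none) {
  n <- length(ids)
  if (n < 2) return(character(0))
  lab <- matrix(none, n, n, dimnames = list(ids, ids))
  e <- graph$edges
  if (nrow(e)) {
    keep <- e$subject %in% ids & e$object %in% ids
    e <- e[keep, , drop = FALSE]
    if (nrow(e)) lab[cbind(e$subject, e$object)] <- e$relation
  }
  lab[row(lab) != col(lab)]
}

#' Relation scores over frame-aligned graph sequences
#'
#' Implements the benchmark protocol: a relation is scored over the ordered
#' pairs of entities present in the ground-truth scene. For every such pair
#' the predicted label (the reserved `"None"` if the prediction carries no
#' edge) is compared with the ground-truth label, a 15-class confusion is
#' accumulated over all frames, and per-class plus macro precision/recall/F1
#' are reported, `"None"` column included. Predicted edges touching
#' hallucinated entities (ids absent from the ground truth) are ignored.
#'
#' @param predicted,truth Lists of [scene_graph()] (or two [scene_sequence()])
#'   aligned frame by frame.
#' @param relations A [relation_vocabulary()].
#' @param include_none If FALSE, drop the `"None"` class before averaging.
#' @return A `class_scores` object.
#' @export
relation_prf <- function(predicted, truth, relations = relation_vocabulary(),
                         include_none = TRUE) {
  if (inherits(predicted, "ssg_sequence")) predicted <- predicted$graphs
  if (inherits(truth, "ssg_sequence")) truth <- truth$graphs
  if (length(predicted) != length(truth))
    stop("predicted and ground-truth sequences are not frame-aligned")
  pl <- character(); tl <- character()
  for (i in seq_along(truth)) {
    if (predicted[[i]]$frame_id != truth[[i]]$frame_id)
      stop(sprintf("frame misalignment at index %d: %d vs %d", i,
                   predicted[[i]]$frame_id, truth[[i]]$frame_id))
    ids <- node_ids(truth[[i]])
    tl <- c(tl, pair_labels_of_graph(truth[[i]], ids, relations$none))
    pl <- c(pl, pair_labels_of_graph(predicted[[i]], ids, relations$none))
  }
  out <- prf_scores(pl, tl, relations$all)
  if (!include_none) {
    keep <- out$per_class$class != relations$none
    act <- keep & (rowSums(out$confusion) > 0 | colSums(out$confusion) > 0)
    if (!any(act)) act <- keep
    out$macro <- c(precision = macro_average(out$per_class$precision[act]),
                   recall = macro_average(out$per_class$recall[act]),
                   f1 = macro_average(out$per_class$f1[act]))
    out$per_class <- out$per_class[keep, ]
  }
  out
}

#' Role and phase scores
#'
#' Same confusion machinery as [relation_prf()], over the 5 clinical roles or
#' the 8 surgical phases.
#' @param predicted,truth Character vectors of per-track roles or per-frame
#'   phases.
#' @return A `class_scores` object.
#' @export
role_prf <- function(predicted, truth)
  prf_scores(predicted, truth, clinical_roles())

#' @rdname role_prf
#' @export
phase_prf <- function(predicted, truth)
  prf_scores(predicted, truth, surgical_phases())
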