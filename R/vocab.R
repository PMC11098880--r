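#' Relation vocabulary
#'
#' The closed set of semantic relations an OR scene graph may carry on its
#' directed edges, plus the reserved background label `"None"`. `"None"` is a
#' classifier class only: relation heads score it, the evaluation protocol
#' averages over it, but it is never stored as a graph edge.
#'
#' @param names Ordered character vector of relation labels (without
#'   `"None"`). Defaults to the 14 relations of the 4D-OR knee-replacement
#'   vocabulary.
#' @return An object of class `relation_vocabulary` with elements `names`
#'   (the storable relations), `none` (the reserved label) and `all`
#'   (the 15 classifier classes, `"None"` last).
#' @export
#' @examples
#' rv <- relation_vocabulary()
#' length(rv$all) # 15
relation_vocabulary <- function(names = c(
  "Assisting", "Cementing", "Cleaning", "CloseTo", "Cutting", "Drilling",
  "Hammering", "Holding", "LyingOn", "Operating", "Preparing", "Sawing",
  "Suturing", "Touching")) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("relation labels must be unique")
  if ("None" %in% names) stop("'None' is reserved and cannot be a relation")
  structure(list(names = names, none = "None", all = c(names, "None")),
            class = "relation_vocabulary")
}

#' Entity vocabulary
#'
#' Entity classes that scene-graph nodes may take. The `"instrument"` class is
#' flagged virtual: it represents a hand-held tool whose geometry is too
#' unreliable to demand points, so that tool-use relations stay expressible.
#'
#' @param names Ordered character vector of entity class labels.
#' @param virtual Character vector of classes that need no geometry.
#' @return An object of class `entity_vocabulary`.
#' @export
entity_vocabulary <- function(names = c(
  "patient", "head surgeon", "assistant surgeon", "circulating nurse",
  "anaesthetist", "human", "operating table", "anesthesia equipment",
  "instrument table", "secondary table", "instrument",
  "drill", "saw", "hammer"), virtual = "instrument") {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("entity labels must be unique")
  if (!all(virtual %in% names)) stop("virtual classes must be in the vocabulary")
  structure(list(names = names, virtual = virtual), class = "entity_vocabulary")
}

#' Clinical roles
#'
#' The five clinical roles of a simulated total knee replacement team.
#' @return Character vector of length 5.
#' @export
clinical_roles <- function() {
  c("patient", "head surgeon", "assistant surgeon", "circulating nurse",
    "anaesthetist")
}

#' Surgical phases
#'
#' The eight workflow phases, in canonical temporal order. Phases with a
#' "Surgery" prefix are the main operative steps (patient under anesthesia).
#' @return Character vector of length 8.
#' @export
surgical_phases <- function() {
  c("OR Preparation", "Patient Roll-In", "Patient Preparation",
    "Surgery 1: Implant Placement Preparation", "Surgery 2: Implant Placement",
    "Surgery 3: Conclusion", "Patient Roll-Out", "OR Cleanup")
}

check_label <- function(label, vocab_names, what) {
  if (!is.character(label) || length(label) != 1L || !(label %in% vocab_names))
    stop(sprintf("unknown %s label: '%s'", what, paste(label, collapse = ",")))
  invisible(label)
}
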