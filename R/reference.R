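#' Published 4D-OR benchmark reference scores
#'
#' Per-class precision/recall/F1 reported on the 4D-OR knee-replacement
#' benchmark test split, shipped as plain CSV: relation scores of the
#' multimodal scene-graph generation model (15 classes including `"None"`),
#' clinical-role scores for the heuristic and the learned graph-encoder
#' scorers (5 roles), and surgical-phase scores of the rule engine on
#' predicted graphs (8 phases). Used by the worked examples that recompute
#' the benchmark's macro averages and harmonic F1 values with this package's
#' metric functions.
#'
#' @param table One of `"relations"`, `"roles"`, `"phases"`.
#' @return Data frame with the printed per-class values (2 decimal places).
#' @export
#' @examples
#' tab <- fourdor_reference_scores("relations")
#' macro_average(tab$f1) # 0.8127, printed as 0.81
fourdor_reference_scores <- function(table = c("relations", "roles", "phases")) {
  table <- match.arg(table)
  f <- system.file("extdata", paste0("fourdor_", sub("s$", "", table),
                                     "_scores.csv"), package = "orssg")
  utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}
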