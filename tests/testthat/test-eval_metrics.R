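test_that("harmonic_f1 matches the closed form and handles the zero case", {
  expect_equal(harmonic_f1(0.36, 0.72), 0.48)
  expect_equal(harmonic_f1(1.00, 0.58), 2 * 0.58 / 1.58, tolerance = 1e-12)
  expect_identical(harmonic_f1(0, 0), 0)
  expect_error(harmonic_f1(1.2, 0.5), "\\[0, 1\\]")
})

test_that("macro_average is an unweighted mean with sane bounds", {
  expect_equal(macro_average(rep(0.7, 9)), 0.7)
  x <- runif(20)
  expect_equal(macro_average(x), macro_average(rev(x)))
  expect_gte(macro_average(x), min(x))
  expect_lte(macro_average(x), max(x))
  expect_error(macro_average(numeric(0)), "empty")
})

test_that("published benchmark tables reproduce their printed macros", {
  rel <- fourdor_reference_scores("relations")
  expect_identical(nrow(rel), 15L)
  expect_equal(round(macro_average(rel$precision), 2), 0.80)
  expect_equal(round(macro_average(rel$recall), 2), 0.86)
  expect_equal(round(macro_average(rel$f1), 2), 0.81)
  expect_equal(macro_average(rel$f1), 0.812667, tolerance = 1e-6)
  # per-class f1 column is consistent with the printed P/R via harmonic mean
  expect_equal(round(harmonic_f1(rel$precision, rel$recall), 2), rel$f1,
               tolerance = 0.011) # printed columns are independently rounded
  rol <- fourdor_reference_scores("roles")
  h <- rol[rol$method == "heuristic", ]
  expect_equal(round(macro_average(h$precision), 2), 0.78)
  expect_equal(round(macro_average(h$f1), 2), 0.77)
  ph <- fourdor_reference_scores("phases")
  expect_equal(round(macro_average(ph$precision), 2), 0.96)
  expect_equal(round(macro_average(ph$f1), 2), 0.97)
})

test_that("relation_prf implements the gt-pair protocol", {
  nodes <- list(entity("a", "human"), entity("b", "patient"),
                entity("c", "operating table"))
  gt <- scene_graph(1, nodes,
                    data.frame(subject = c("a", "b"),
                               relation = c("Sawing", "LyingOn"),
                               object = c("b", "c")))
  # perfect prediction
  sc <- relation_prf(list(gt), list(gt))
  expect_equal(unname(sc$macro["f1"]), 1)
  # edgeless prediction: None recall 1, others 0
  pred0 <- scene_graph(1, nodes)
  sc0 <- relation_prf(list(pred0), list(gt))
  pc <- sc0$per_class
  expect_equal(pc$recall[pc$class == "None"], 1)
  expect_equal(pc$recall[pc$class == "Sawing"], 0)
  # hallucinated-entity edges are ignored
  pred_h <- scene_graph(1, c(nodes, list(entity("zz", "human"))),
                        data.frame(subject = c("a", "b", "zz"),
                                   relation = c("Sawing", "LyingOn", "Cutting"),
                                   object = c("b", "c", "a")))
  expect_equal(unname(relation_prf(list(pred_h), list(gt))$macro["f1"]), 1)
  expect_error(relation_prf(list(gt), list(gt, gt)), "frame")
})

test_that("a single swapped pair yields the hand-counted confusion", {
  # 4 Sawing + 4 Drilling gt pairs over two frames; one of each predicted as
  # the other -> P = R = 0.75 for both classes
  nodes <- lapply(letters[1:5], function(x) entity(x, "human"))
  mk <- function(rels, fid) {
    scene_graph(fid, nodes,
                data.frame(subject = c("a", "b", "c", "d"),
                           relation = rels, object = c("b", "c", "d", "e")))
  }
  gt <- list(mk(c("Sawing", "Sawing", "Drilling", "Drilling"), 1),
             mk(c("Sawing", "Sawing", "Drilling", "Drilling"), 2))
  pred <- list(mk(c("Sawing", "Sawing", "Drilling", "Drilling"), 1),
               mk(c("Drilling", "Sawing", "Sawing", "Drilling"), 2))
  sc <- relation_prf(pred, gt)
  pc <- sc$per_class
  expect_equal(pc$precision[pc$class == "Sawing"], 0.75)
  expect_equal(pc$recall[pc$class == "Sawing"], 0.75)
  expect_equal(pc$precision[pc$class == "Drilling"], 0.75)
})

test_that("prf machinery agrees with an independent oracle on random labelings", {
  classes <- c("x", "y", "z", "w")
  set.seed(11)
  for (rep in 1:20) {
    truth <- sample(classes, 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.6, truth, sample(classes, 60, replace = TRUE))
    sc <- prf_scores(pred, truth, classes)
    orc <- oracle_prf(pred, truth, classes)
    expect_equal(sc$per_class$precision, unname(orc[, "precision"]))
    expect_equal(sc$per_class$recall, unname(orc[, "recall"]))
    expect_equal(sc$per_class$f1, unname(orc[, "f1"]))
  }
})

test_that("role_prf and phase_prf reuse the confusion machinery", {
  r <- role_prf(c("patient", "head surgeon"), c("patient", "anaesthetist"))
  expect_identical(nrow(r$per_class), 5L)
  p <- phase_prf(rep("OR Cleanup", 3), rep("OR Cleanup", 3))
  expect_identical(nrow(p$per_class), 8L)
  expect_equal(unname(p$per_class$f1[p$per_class$class == "OR Cleanup"]), 1)
})
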