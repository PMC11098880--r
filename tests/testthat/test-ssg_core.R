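test_that("vocabularies carry the benchmark class structure", {
  rv <- relation_vocabulary()
  expect_length(rv$all, 15L)
  expect_identical(rv$all[15], "None")
  expect_error(relation_vocabulary(c("A", "A")), "unique")
  expect_error(relation_vocabulary(c("A", "None")), "reserved")
  ev <- entity_vocabulary()
  expect_true("instrument" %in% ev$virtual)
  expect_length(clinical_roles(), 5L)
  expect_length(surgical_phases(), 8L)
})

test_that("validate_graph reports each violation and passes valid graphs", {
  g <- fix_graph()
  expect_identical(validate_graph(g), character(0))
  g_bad <- g
  g_bad$edges <- rbind(g_bad$edges,
                       data.frame(subject = "hs1", relation = "Cutting",
                                  object = "x9"))
  v <- validate_graph(g_bad)
  expect_length(v, 1L)
  expect_match(v, "x9")
  g_none <- g
  g_none$edges$relation[1] <- "None"
  expect_match(validate_graph(g_none), "reserved", all = FALSE)
  g_loop <- g
  g_loop$edges$object[1] <- "hs1"
  expect_match(validate_graph(g_loop), "self-loop", all = FALSE)
  g_dup <- g
  g_dup$edges <- rbind(g_dup$edges,
                       data.frame(subject = "hs1", relation = "Cutting",
                                  object = "p1"))
  expect_match(validate_graph(g_dup), "multiple relations", all = FALSE)
})

test_that("has_triplet matches classes directionally and rejects unknown labels", {
  g <- fix_graph()
  expect_true(has_triplet(g, "head surgeon", "Sawing", "patient"))
  expect_false(has_triplet(g, "patient", "Sawing", "head surgeon"))
  empty <- scene_graph(1, list())
  expect_false(has_triplet(empty, "head surgeon", "Sawing", "patient"))
  expect_error(has_triplet(g, "wizard", "Sawing", "patient"), "unknown")
  # role-augmented query: class "human" carrying a role matches the role label
  g2 <- scene_graph(2, list(entity("h1", "human", role = "head surgeon"),
                            entity("p1", "patient")),
                    data.frame(subject = "h1", relation = "Drilling",
                               object = "p1"))
  expect_true(has_triplet(g2, "head surgeon", "Drilling", "patient"))
})

test_that("has_triplet is monotone under edge addition", {
  g <- fix_graph()
  queries <- list(c("head surgeon", "Sawing", "patient"),
                  c("patient", "LyingOn", "operating table"))
  before <- vapply(queries, function(q) has_triplet(g, q[1], q[2], q[3]),
                   logical(1))
  g$edges <- rbind(g$edges,
                   data.frame(subject = "hs1", relation = "CloseTo",
                              object = "t1"))
  after <- vapply(queries, function(q) has_triplet(g, q[1], q[2], q[3]),
                  logical(1))
  expect_true(all(after >= before))
})

test_that("graph_to_triplets round-trips and rejects invalid graphs", {
  g <- fix_graph()
  tr <- graph_to_triplets(g)
  expect_identical(nrow(tr), 2L)
  g2 <- triplets_to_graph(g$frame_id, tr, g$nodes)
  expect_setequal(do.call(paste, graph_to_triplets(g2)),
                  do.call(paste, tr))
  expect_identical(nrow(graph_to_triplets(scene_graph(1, g$nodes))), 0L)
  g_bad <- g
  g_bad$edges$object[1] <- "zz"
  expect_error(graph_to_triplets(g_bad), "invalid graph")
})

test_that("sequence JSON io round-trips field-for-field", {
  graphs <- lapply(1:5, function(i) {
    g <- fix_graph(i)
    g$nodes[["hs1"]]$role <- "head surgeon"
    g$nodes[["hs1"]]$centroid <- c(0.1, -0.5, 1.1)
    g
  })
  s <- scene_sequence("takeA", graphs, fps = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_scene_sequence(s, f)
  s2 <- read_scene_sequence(f)
  expect_equal(s2, s)
  # duplicate frame ids are a parse error
  txt <- jsonlite::read_json(f)
  txt$frames[[2]]$frame_id <- 1L
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(txt, f2, auto_unbox = TRUE)
  expect_error(read_scene_sequence(f2), "duplicate frame_id")
  # empty frame list
  s0 <- scene_sequence("empty", list())
  write_scene_sequence(s0, f)
  expect_length(read_scene_sequence(f)$graphs, 0L)
  # unknown labels rejected
  txt <- jsonlite::read_json(f)
  expect_error(scene_sequence("x", list(fix_graph(2), fix_graph(1))),
               "strictly increasing")
})
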