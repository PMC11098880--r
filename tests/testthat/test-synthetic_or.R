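test_that("timeline walks the canonical phases with weighted durations", {
  cfg <- sim_config(seed = 1, take_length_s = 660)
  b <- simulate_timeline(cfg, geometry = FALSE)
  expect_length(b, 660L)
  idx <- vapply(b, `[[`, 1L, "phase_idx")
  expect_true(all(diff(idx) >= 0))           # canonical order
  expect_setequal(unique(idx), 1:8)          # all phases present
  counts <- tabulate(idx, 8)
  expect_equal(counts / 660, cfg$phase_duration_weights, tolerance = 0.01)
  # roles constant within a take; graphs valid
  expect_identical(attr(b, "take")$roles[["hs"]], "head surgeon")
  expect_length(unlist(lapply(b[seq(1, 660, 60)], function(f)
    validate_graph(f$gt_graph))), 0L)
})

test_that("same seed reproduces the take exactly", {
  b1 <- simulate_timeline(sim_config(seed = 42, take_length_s = 30))
  b2 <- simulate_timeline(sim_config(seed = 42, take_length_s = 30))
  expect_equal(b1[[17]]$cloud$points, b2[[17]]$cloud$points)
  expect_equal(b1[[17]]$images, b2[[17]]$images)
  expect_identical(lapply(b1, `[[`, "gt_graph"), lapply(b2, `[[`, "gt_graph"))
})

test_that("weights concentrated on OR Preparation leave the room patientless", {
  w <- c(0.93, rep(0.01, 7))
  b <- simulate_timeline(sim_config(seed = 2, take_length_s = 200,
                                    phase_duration_weights = w),
                         geometry = FALSE)
  no_pat <- vapply(b, function(f) !("patient" %in% node_ids(f$gt_graph)),
                   logical(1))
  expect_gte(mean(no_pat), 0.9)
  expect_error(sim_config(phase_duration_weights = rep(0, 8)),
               "phase_duration_weights")
})

test_that("geometric relations respect their predicates", {
  b <- simulate_timeline(sim_config(seed = 6, take_length_s = 120),
                         geometry = FALSE)
  mid <- b[[60]] # inside the operative block
  g <- mid$gt_graph
  expect_true(has_triplet(g, "patient", "LyingOn", "operating table"))
  # CloseTo pairs are within the threshold; distant pairs absent
  cents <- lapply(g$nodes, `[[`, "centroid")
  e <- g$edges
  for (k in which(e$relation == "CloseTo")) {
    d <- sqrt(sum((cents[[e$subject[k]]] - cents[[e$object[k]]])^2))
    expect_lt(d, 1.5)
  }
  # scripted action frames: the acting hand is near the patient knee and the
  # instrument points carry the instrument's label
  act <- Filter(function(f) any(f$gt_graph$edges$relation == "Sawing"), b)
  expect_gt(length(act), 0)
  f <- act[[1]]
  hs_pose <- f$poses[[which(vapply(f$poses, `[[`, "", "person_id") == "hs")]]
  knee <- f$poses[[which(vapply(f$poses, `[[`, "", "person_id") ==
                           "patient")]]$joints["knee_r", ]
  expect_lt(sqrt(sum((hs_pose$joints["wrist_r", ] - knee)^2)), 0.4 + 0.05)
})

test_that("instance labels partition the cloud and instruments carry color", {
  b <- simulate_timeline(sim_config(seed = 3, take_length_s = 40))
  f <- b[[30]]
  cl <- f$cloud
  expect_identical(length(cl$labels), nrow(cl$points))
  expect_true(all(cl$labels %in% c(-1L, cl$entities$label)))
  iid <- cl$entities$label[cl$entities$class_name == "instrument"]
  if (length(iid)) {
    icol <- cl$colors[cl$labels == iid[1], , drop = FALSE]
    expect_gt(max(colMeans(icol)) - min(colMeans(icol)), 0.4) # saturated
  }
  # doubling points_per_entity roughly doubles the cloud
  b2 <- simulate_timeline(sim_config(seed = 3, take_length_s = 5,
                                     points_per_entity = 600))
  b1 <- simulate_timeline(sim_config(seed = 3, take_length_s = 5,
                                     points_per_entity = 300))
  expect_equal(nrow(b2[[3]]$cloud$points) / nrow(b1[[3]]$cloud$points), 2,
               tolerance = 0.05)
})

test_that("inject_noise drops and swaps at the configured rates", {
  b <- simulate_timeline(sim_config(seed = 8, take_length_s = 60),
                         geometry = FALSE)
  sq <- take_sequence(b)
  expect_identical(inject_noise(sq, 0, 0, seed = 1)$graphs, sq$graphs)
  allgone <- inject_noise(sq, 1, 0, seed = 1)
  expect_identical(sum(vapply(allgone$graphs, function(g) nrow(g$edges), 1L)),
                   0L)
  n_edges <- sum(vapply(sq$graphs, function(g) nrow(g$edges), 1L))
  kept <- sum(vapply(inject_noise(sq, 0.3, 0, seed = 2)$graphs,
                     function(g) nrow(g$edges), 1L))
  # binomial oracle: 3 sigma band around 0.7 * n
  expect_lt(abs(kept - 0.7 * n_edges), 3 * sqrt(n_edges * 0.3 * 0.7) + 1)
  # node sets untouched, reproducible
  nz <- inject_noise(sq, 0.5, 0.2, seed = 7)
  expect_identical(lapply(nz$graphs, node_ids), lapply(sq$graphs, node_ids))
  expect_identical(inject_noise(sq, 0.5, 0.2, seed = 7)$graphs, nz$graphs)
})

test_that("renderer produces consistent clouds and images", {
  b <- simulate_timeline(sim_config(seed = 10, take_length_s = 5, n_views = 4,
                                    image_res = 32))
  f <- b[[1]]
  expect_length(f$images, 4L)
  expect_identical(dim(f$images[[1]]), c(32L, 32L, 3L))
  expect_true(all(f$images[[1]] >= 0 & f$images[[1]] <= 1))
  # points of a box entity lie near its box
  lab <- f$cloud$entities$label[f$cloud$entities$entity_id == "op_table"]
  pts <- f$cloud$points[f$cloud$labels == lab, ]
  box <- f$boxes$op_table
  expect_true(all(abs(pts[, 1] - box$center[1]) < box$size[1] / 2 + 0.05))
})

test_that("PLY, labels and PPM round-trip through disk", {
  b <- simulate_timeline(sim_config(seed = 12, take_length_s = 2, n_views = 2,
                                    image_res = 16, points_per_entity = 60))
  d <- withr::local_tempdir()
  write_take(b, d)
  ply <- read_ply(file.path(d, "frame_0001.ply"))
  expect_equal(ply$points, b[[1]]$cloud$points, tolerance = 1e-5)
  expect_equal(ply$colors, b[[1]]$cloud$colors, tolerance = 1 / 255)
  labs <- read_labels(file.path(d, "frame_0001.labels.txt"))
  expect_identical(labs, b[[1]]$cloud$labels)
  img <- read_ppm(file.path(d, "frame_0001_view1.ppm"))
  expect_equal(img, b[[1]]$images[[1]], tolerance = 1 / 255)
  sq <- read_scene_sequence(file.path(d, "graphs.json"))
  expect_length(sq$graphs, 2L)
})
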