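test_that("hungarian_assign solves small instances optimally", {
  m <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2, byrow = TRUE)
  expect_identical(hungarian_assign(m), c(1L, 2L))
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n, n)
    a <- hungarian_assign(cost)
    o <- oracle_brute_assign(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), o$cost, tolerance = 1e-10)
  }
  # rectangular: every row matched when cols >= rows
  cost <- matrix(runif(12), 3, 4)
  a <- hungarian_assign(cost)
  expect_false(anyNA(a))
  expect_identical(anyDuplicated(a), 0L)
})

test_that("build_tracks keeps identity for static poses and gates jumps", {
  p1 <- rand_pose("A", c(0, 0)); p2 <- rand_pose("B", c(2, 0))
  frames <- replicate(10, list(p1, p2), simplify = FALSE)
  tr <- build_tracks(frames)
  expect_length(tr, 2L)
  expect_true(all(vapply(tr, function(t) length(t$frames), 1L) == 10L))
  ids <- vapply(tr, function(t) unique(unname(t$frames)), character(1))
  expect_setequal(ids, c("A", "B"))
  # a > gate jump terminates the track and births a new one
  frames2 <- list(list(p1), list(p1), list(rand_pose("A", c(3, 3))))
  tr2 <- build_tracks(frames2)
  expect_length(tr2, 2L)
  expect_identical(length(tr2[[1]]$frames), 2L)
  # tracks partition all detections
  nd <- sum(lengths(frames2))
  expect_identical(sum(vapply(tr2, function(t) length(t$frames), 1L)), nd)
})

test_that("heuristic scores reflect the printed role-evidence examples", {
  nodes <- list(entity("h1", "human"), entity("p", "patient"),
                entity("t", "operating table"))
  saw_g <- scene_graph(1, nodes,
                       data.frame(subject = "h1", relation = "Sawing",
                                  object = "p"))
  tr <- list(track_id = "T1", selected_graphs = rep(list(saw_g), 5),
             target_nodes = rep("h1", 5), K = 5)
  sc <- heuristic_role_scores(tr)
  expect_identical(names(which.max(sc)), "head surgeon")
  expect_equal(sum(sc), 1)
  lie_g <- scene_graph(1, nodes,
                       data.frame(subject = "p", relation = "LyingOn",
                                  object = "t"))
  trp <- list(track_id = "T2", selected_graphs = rep(list(lie_g), 4),
              target_nodes = rep("p", 4), K = 4)
  expect_identical(names(which.max(heuristic_role_scores(trp))), "patient")
  # edgeless track -> uniform
  tr0 <- list(track_id = "T3",
              selected_graphs = list(scene_graph(1, nodes)),
              target_nodes = "h1", K = 1)
  expect_equal(unname(heuristic_role_scores(tr0)), rep(0.2, 5))
})

test_that("greedy assignment reproduces the worked example and ties break deterministically", {
  m <- role_score_matrix(rbind(c(.6, .3, .1, 0, 0),
                               c(.5, .4, .1, 0, 0),
                               c(.1, .2, .7, 0, 0)),
                         c("h1", "h2", "h3"))
  colnames(m) <- clinical_roles() # patient, head surgeon, ... order irrelevant
  a <- assign_roles(m)
  expect_identical(unname(a["h3"]), colnames(m)[3])
  expect_identical(unname(a["h1"]), colnames(m)[1])
  expect_identical(unname(a["h2"]), colnames(m)[2])
  # single track -> its argmax
  m1 <- role_score_matrix(matrix(c(.1, .2, .4, .2, .1), 1))
  expect_identical(unname(assign_roles(m1)[1]), clinical_roles()[3])
  # identical rows: tie broken by track index, deterministic
  m2 <- role_score_matrix(rbind(c(.4, .3, .1, .1, .1),
                                c(.4, .3, .1, .1, .1)))
  a2 <- assign_roles(m2)
  expect_identical(unname(a2), clinical_roles()[1:2])
  expect_identical(assign_roles(m2), a2)
})

test_that("greedy assignment agrees with the independent re-simulation on random matrices", {
  set.seed(33)
  for (rep in 1:200) {
    nt <- sample(2:5, 1)
    m <- matrix(rexp(nt * 5), nt, 5)
    m <- m / rowSums(m)
    rownames(m) <- paste0("t", seq_len(nt))
    colnames(m) <- clinical_roles()
    a <- assign_roles(role_score_matrix(m, rownames(m)))
    o <- oracle_greedy_assign(m)
    expect_identical(a, o)
    assigned <- a[!is.na(a)]
    expect_identical(anyDuplicated(assigned), 0L) # injective over roles
  }
})

test_that("select_track_graphs bounds K and marks target nodes", {
  b <- simulate_timeline(sim_config(seed = 5, take_length_s = 50),
                         geometry = FALSE)
  sq <- take_sequence(b)
  frames <- setNames(rep("hs", 50), as.character(1:50))
  tr <- select_track_graphs(list(track_id = "T1", frames = frames), sq,
                            max_graphs = 8)
  expect_identical(tr$K, 8L)
  expect_true(all(tr$target_nodes == "hs"))
})

test_that("end-to-end role assignment on a simulated take recovers all roles", {
  b <- simulate_timeline(sim_config(seed = 9, take_length_s = 120),
                         geometry = FALSE)
  sq <- take_sequence(b)
  poses <- lapply(b, `[[`, "poses")
  res <- assign_take_roles(poses, sq)
  gt <- attr(b, "take")$roles
  expect_identical(res$node_roles[names(gt)], gt)
})

test_that("learned scorer is target-sensitive and at least matches the heuristic on noisy takes", {
  # scaled-down version of the train-on-takes / evaluate-held-out experiment:
  # noisy graphs so the heuristic is off ceiling; 3-seed median comparison
  mk_take <- function(seed) {
    b <- simulate_timeline(sim_config(seed = seed, take_length_s = 60),
                           geometry = FALSE)
    sq <- inject_noise(take_sequence(b), dropout = 0.3, swap = 0.1,
                       seed = seed + 1000)
    list(b = b, sq = sq, roles = attr(b, "take")$roles)
  }
  takes <- lapply(1:6, mk_take)
  get_tracks <- function(tk) {
    trs <- build_tracks(lapply(tk$b, `[[`, "poses"))
    trs <- lapply(trs, select_track_graphs, sequence = tk$sq, max_graphs = 12)
    keep <- vapply(trs, function(t) length(t$frames) >= 10, logical(1))
    trs[keep]
  }
  train_tracks <- unlist(lapply(takes[1:4], get_tracks), recursive = FALSE)
  train_roles <- unlist(lapply(takes[1:4], function(tk)
    unname(tk$roles[vapply(get_tracks(tk), function(t)
      unname(t$frames[1]), character(1))])))
  test_tracks <- unlist(lapply(takes[5:6], get_tracks), recursive = FALSE)
  test_roles <- unlist(lapply(takes[5:6], function(tk)
    unname(tk$roles[vapply(get_tracks(tk), function(t)
      unname(t$frames[1]), character(1))])))
  f1_of <- function(pred) role_prf(pred, test_roles)$macro["f1"]
  heur <- f1_of(vapply(test_tracks, function(t)
    names(which.max(heuristic_role_scores(t))), character(1)))
  learned <- vapply(1:3, function(s) {
    m <- train_role_model(train_tracks, train_roles,
                          role_model_config(dim = 24, epochs = 25, seed = s))
    f1_of(vapply(test_tracks, function(t)
      names(which.max(learned_role_scores(t, m))), character(1)))
  }, numeric(1))
  expect_gte(median(learned), heur)
  # target-flag sensitivity: same graphs, different targets -> different rows
  m <- train_role_model(train_tracks, train_roles,
                        role_model_config(dim = 24, epochs = 2, seed = 1))
  t1 <- train_tracks[[1]]
  alt <- t1
  alt$target_nodes <- rep("op_table", t1$K) # present in every frame
  expect_false(isTRUE(all.equal(learned_role_scores(t1, m),
                                learned_role_scores(alt, m))))
  # K = 1 degenerate track still yields a row
  t1k <- t1
  t1k$selected_graphs <- t1$selected_graphs[1]
  t1k$target_nodes <- t1$target_nodes[1]
  expect_equal(sum(learned_role_scores(t1k, m)), 1)
})
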