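# shared tiny fixture: a short geometric take
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_timeline(sim_config(seed = 55, take_length_s = 12,
                                             points_per_entity = 120,
                                             image_res = 32))
    cache
  }
})

tiny_cfg <- function(...) {
  defaults <- list(feat_dim = 16, hidden_dim = 12, img_dim = 8,
                   gcn_layers = 2, n_obj_points = 48, n_rel_points = 64,
                   learning_rate = 2e-3, epochs = 2, seed = 1,
                   max_pixels = 200)
  args <- utils::modifyList(defaults, list(...))
  do.call(sgg_config, args)
}

test_that("class_balanced_weights implements linear weighting", {
  expect_equal(class_balanced_weights(c(50, 50)), c(1, 1))
  expect_equal(class_balanced_weights(c(90, 10)), c(0.2, 1.8))
  expect_equal(class_balanced_weights(c(3, 7), mode = "none"), c(1, 1))
  expect_equal(mean(class_balanced_weights(rpois(15, 20) + 1)), 1)
  expect_error(class_balanced_weights(c(0, 0)), "positive")
})

test_that("encoders are invariant to point permutation and duplication", {
  b <- sim_small()
  f <- sgg_dataset(b)[[5]]
  cfg <- tiny_cfg()
  m <- train_sgg(list(f), cfg) # 2 cheap epochs; weights arbitrary but fixed
  st <- orssg:::sgg_frame_static(f$cloud, f$images, NULL, cfg,
                                 m$classes$entities, m$classes$relations)
  fr <- orssg:::prepare_sgg_frame(st, cfg, training = FALSE)
  out1 <- sgg_forward(m, fr)
  fr2 <- fr
  fr2$obj_list <- lapply(fr$obj_list, function(x)
    x[sample(nrow(x)), , drop = FALSE])
  fr2$rel_list <- lapply(fr$rel_list, function(x)
    x[sample(nrow(x)), , drop = FALSE])
  out2 <- sgg_forward(m, fr2)
  expect_equal(out1$node_logits, out2$node_logits, tolerance = 1e-5)
  expect_equal(out1$edge_logits, out2$edge_logits, tolerance = 1e-5)
  # duplicating points leaves the max-pooled features unchanged
  fr3 <- fr
  fr3$obj_list <- lapply(fr$obj_list, function(x) rbind(x, x))
  out3 <- sgg_forward(m, fr3)
  expect_equal(out1$node_logits, out3$node_logits, tolerance = 1e-5)
})

test_that("image fusion changes scores but not shapes; single entity has no pairs", {
  b <- sim_small()
  f <- sgg_dataset(b)[[5]]
  m_img <- train_sgg(list(f), tiny_cfg(use_images = TRUE))
  m_no <- train_sgg(list(f), tiny_cfg(use_images = FALSE))
  p_img <- predict_graph(m_img, f)
  p_no <- predict_graph(m_no, f)
  expect_setequal(node_ids(p_img), node_ids(p_no))
  # single-entity frame: node scores only
  cl <- f$cloud
  keep <- cl$entities$label[1]
  cl2 <- point_cloud_frame(cl$points, cl$colors,
                           ifelse(cl$labels == keep, keep, -1L),
                           entities = cl$entities[1, , drop = FALSE])
  g1 <- predict_graph(m_img, list(cloud = cl2, images = f$images))
  expect_length(g1$nodes, 1L)
  expect_identical(nrow(g1$edges), 0L)
})

test_that("training reduces the loss, is seed-deterministic, and predicts valid graphs", {
  b <- sim_small()
  frames <- sgg_dataset(b)
  cfg <- tiny_cfg(epochs = 6)
  m1 <- train_sgg(frames, cfg)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  m2 <- train_sgg(frames, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  g <- predict_graph(m1, frames[[3]], frame_id = 3L)
  expect_identical(validate_graph(g), character(0))
  expect_identical(predict_graph(m1, frames[[3]], 3L), g) # deterministic
})

test_that("analytic gradients match finite differences on a tiny frame", {
  set.seed(42)
  cfg <- sgg_config(feat_dim = 6, hidden_dim = 5, img_dim = 4, gcn_layers = 2,
                    n_obj_points = 12, n_rel_points = 16, use_images = TRUE,
                    augment = FALSE, max_pixels = 30)
  ents <- entity_vocabulary(); rels <- relation_vocabulary()
  params <- orssg:::init_sgg_params(cfg, length(ents$names), length(rels$all))
  params <- lapply(params, function(p) p + rnorm(length(p), 0, 0.05))
  model <- structure(list(params = params, config = cfg,
                          classes = list(entities = ents$names,
                                         relations = rels$all)),
                     class = "sgg_model")
  n <- 3
  fr <- list(ids = c("a", "b", "c"), n = n,
             pairs = local({pp <- expand.grid(i = 1:n, j = 1:n)
                            pp[pp$i != pp$j, ]}),
             obj_list = lapply(1:n, function(i) matrix(rnorm(12 * 9), 12, 9)),
             missing = c(FALSE, FALSE, TRUE),
             rel_list = lapply(1:6, function(q) matrix(rnorm(16 * 10), 16, 10)),
             rel_missing = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
             pix = matrix(runif(30 * 5), 30, 5),
             node_y = c(1, 5, NA), edge_y = c(2, 15, NA, 15, 4, 15))
  loss_of <- function(model) {
    fwd <- sgg_forward(model, fr, want_cache = TRUE)
    mn <- which(!is.na(fr$node_y)); me <- which(!is.na(fr$edge_y))
    w <- rep(1, 15); w[15] <- 0.3
    ln <- orssg:::ce_loss(fwd$node_logits[mn, , drop = FALSE], fr$node_y[mn])
    le <- orssg:::ce_loss(fwd$edge_logits[me, , drop = FALSE],
                          fr$edge_y[me], w)
    dnode <- fwd$node_logits * 0; dnode[mn, ] <- ln$dlogits
    dedge <- fwd$edge_logits * 0; dedge[me, ] <- le$dlogits
    list(loss = ln$loss + le$loss, fwd = fwd, dnode = dnode, dedge = dedge)
  }
  base <- loss_of(model)
  gr <- orssg:::sgg_backward(model, fr, base$fwd, base$dnode, base$dedge)
  eps <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- model
      m2$params[[nm]][i] <- p[i] + eps
      lp <- loss_of(m2)$loss
      m2$params[[nm]][i] <- p[i] - eps
      lm <- loss_of(m2)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("takes written to disk train and predict through the CLI path", {
  b <- sim_small()
  d <- withr::local_tempdir()
  write_take(b[1:4], file.path(d, "take_01"))
  frames <- read_take(file.path(d, "take_01"))
  expect_length(frames, 4L)
  expect_equal(frames[[1]]$cloud$points, b[[1]]$cloud$points,
               tolerance = 1e-5)
  expect_identical(frames[[1]]$cloud$labels, b[[1]]$cloud$labels)
  cfgf <- file.path(d, "cfg.json")
  jsonlite::write_json(list(feat_dim = 12, hidden_dim = 8, img_dim = 6,
                            gcn_layers = 1, n_obj_points = 32,
                            n_rel_points = 48, learning_rate = 1e-3,
                            epochs = 1, seed = 2, max_pixels = 150),
                       cfgf, auto_unbox = TRUE)
  mf <- file.path(d, "m.rds")
  orssg_cli(c("train-sgg", "--config", cfgf, "--takes", d, "--out", mf))
  expect_true(file.exists(mf))
  gout <- file.path(d, "pred.json")
  orssg_cli(c("predict", "--model", mf, "--take", file.path(d, "take_01"),
              "--out", gout))
  pred <- read_scene_sequence(gout)
  expect_length(pred$graphs, 4L)
  expect_length(unlist(lapply(pred$graphs, validate_graph)), 0L)
})

test_that("uniform weights recover plain cross-entropy", {
  set.seed(5)
  logits <- matrix(rnorm(40), 8, 5)
  y <- sample(5, 8, replace = TRUE)
  a <- orssg:::ce_loss(logits, y)
  b <- orssg:::ce_loss(logits, y, rep(1, 5))
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  expect_equal(a$loss, mean(-log(p[cbind(1:8, y)])), tolerance = 1e-12)
  expect_equal(a$loss, b$loss)
})
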