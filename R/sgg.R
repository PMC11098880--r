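#' Scene-graph network configuration
#'
#' @param feat_dim Pooled point-feature dimension (default 128).
#' @param hidden_dim Shared per-point MLP hidden width.
#' @param img_dim Global image-feature dimension (0 disables the image
#'   pathway regardless of `use_images`).
#' @param gcn_layers Graph-convolution rounds (default 2).
#' @param n_obj_points,n_rel_points Points sampled per entity / per pair
#'   (benchmark-scale defaults 4000 / 8000; desk-scale experiments use far
#'   fewer).
#' @param learning_rate Adam step size (benchmark default 3e-5).
#' @param epochs Training epochs.
#' @param seed RNG seed controlling init, sampling and augmentation.
#' @param use_images Fuse a global image feature into every node and edge.
#' @param class_weighting `"linear"` (see [class_balanced_weights()]) or
#'   `"none"`.
#' @param augment Apply the three augmentation families during training.
#' @param max_pixels Cap on foreground pixels fed to the image encoder.
#' @return List of class `sgg_config`.
#' @export
sgg_config <- function(feat_dim = 128L, hidden_dim = 64L, img_dim = 16L,
                       gcn_layers = 2L, n_obj_points = 4000L,
                       n_rel_points = 8000L, learning_rate = 3e-5,
                       epochs = 20L, seed = 1L, use_images = TRUE,
                       class_weighting = c("linear", "none"),
                       augment = TRUE, max_pixels = 1200L) {
  class_weighting <- match.arg(class_weighting)
  stopifnot(feat_dim > 0, hidden_dim > 0, gcn_layers > 0, learning_rate > 0,
            n_obj_points > 0, n_rel_points > 0)
  structure(list(feat_dim = as.integer(feat_dim),
                 hidden_dim = as.integer(hidden_dim),
                 img_dim = as.integer(img_dim),
                 gcn_layers = as.integer(gcn_layers),
                 n_obj_points = as.integer(n_obj_points),
                 n_rel_points = as.integer(n_rel_points),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), use_images = isTRUE(use_images),
                 class_weighting = class_weighting, augment = isTRUE(augment),
                 max_pixels = as.integer(max_pixels)),
            class = "sgg_config")
}

#' Class-balanced loss weights
#'
#' Linear weighting for rare relations: `w_c` proportional to
#' `1 - n_c / sum(n)`, renormalized to mean 1. `mode = "none"` returns unit
#' weights, in which limit the weighted loss is standard cross-entropy.
#'
#' @param counts Nonnegative per-class counts, at least one positive.
#' @param mode `"linear"` or `"none"`.
#' @return Numeric weight per class, mean 1.
#' @export
#' @examples
#' class_balanced_weights(c(90, 10)) # 0.2, 1.8
class_balanced_weights <- function(counts, mode = c("linear", "none")) {
  mode <- match.arg(mode)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be nonnegative with a positive total")
  if (mode == "none") return(rep(1, length(counts)))
  w <- 1 - counts / sum(counts)
  w / mean(w)
}

init_sgg_params <- function(config, n_entity_classes, n_relation_classes) {
  F <- config$feat_dim; H <- config$hidden_dim
  G <- if (config$use_images) config$img_dim else 0L
  D <- F + G
  p <- list(
    oW1 = he_init(9, H), ob1 = numeric(H),
    oW2 = he_init(H, F), ob2 = numeric(F),
    rW1 = he_init(10, H), rb1 = numeric(H),
    rW2 = he_init(H, F), rb2 = numeric(F),
    o_missing = stats::rnorm(F, 0, 0.1),
    r_missing = stats::rnorm(F, 0, 0.1),
    Wno = he_init(D, n_entity_classes), bno = numeric(n_entity_classes),
    Wre = he_init(D, n_relation_classes), bre = numeric(n_relation_classes))
  if (config$use_images) {
    p$iW1 <- he_init(5, H); p$ib1 <- numeric(H)
    p$iW2 <- he_init(H, G); p$ib2 <- numeric(G)
  }
  for (l in seq_len(config$gcn_layers)) {
    p[[paste0("Wm", l)]] <- he_init(2 * D, D)
    p[[paste0("bm", l)]] <- numeric(D)
    p[[paste0("Wn", l)]] <- he_init(2 * D, D)
    p[[paste0("bn", l)]] <- numeric(D)
    p[[paste0("We", l)]] <- he_init(3 * D, D)
    p[[paste0("be", l)]] <- numeric(D)
  }
  p
}

# Foreground pixels of all views as a (r, g, b, x, y) point set. Above the
# pixel budget, saturated pixels (rare, information-bearing under max
# pooling: small colored instruments) are always kept and the grey mass is
# stride-subsampled; deterministic, no RNG.
image_pixels <- function(images, max_pixels = 1200L) {
  out <- list()
  for (img in images) {
    res <- dim(img)[1]
    fg <- which(img[, , 1] + img[, , 2] + img[, , 3] > 0.02, arr.ind = TRUE)
    if (!nrow(fg)) next
    out[[length(out) + 1L]] <-
      cbind(img[cbind(fg, 1L)], img[cbind(fg, 2L)], img[cbind(fg, 3L)],
            (fg[, 2] - 0.5) / res, (fg[, 1] - 0.5) / res)
  }
  if (!length(out)) return(matrix(0, 0, 5))
  px <- do.call(rbind, out)
  if (nrow(px) > max_pixels) {
    sat <- pmax(px[, 1], px[, 2], px[, 3]) - pmin(px[, 1], px[, 2], px[, 3])
    keep <- which(sat > 0.25)
    rest <- setdiff(seq_len(nrow(px)), keep)
    budget <- max(max_pixels - length(keep), 50L)
    rest <- rest[round(seq(1, length(rest), length.out = min(budget,
                                                             length(rest))))]
    px <- px[c(keep, rest), , drop = FALSE]
  }
  px
}

# deterministic stride sample used at inference (no RNG)
stride_sample <- function(idx, n) {
  if (length(idx) >= n) idx[round(seq(1, length(idx), length.out = n))]
  else idx[((seq_len(n) - 1L) %% length(idx)) + 1L]
}

# Epoch-invariant per-frame data: entity point indices, pair composition,
# pixels, targets. Computed once; per-epoch sampling/augmentation happens in
# prepare_sgg_frame.
sgg_frame_static <- function(cloud, images, gt_graph, config,
                             entity_classes, relation_classes) {
  reg <- cloud$entities
  stopifnot(!is.null(reg))
  ids <- reg$entity_id
  n <- length(ids)
  ent_idx <- lapply(reg$label, function(l) which(cloud$labels == l))
  pairs <- if (n >= 2) {
    pp <- expand.grid(i = seq_len(n), j = seq_len(n))
    pp[pp$i != pp$j, , drop = FALSE]
  } else data.frame(i = integer(), j = integer())
  node_y <- edge_y <- NULL
  if (!is.null(gt_graph)) {
    cls <- node_classes(gt_graph)
    node_y <- match(unname(cls[ids]), entity_classes) # NA: not a gt entity
    none_id <- match("None", relation_classes)
    in_gt <- ids %in% names(gt_graph$nodes)
    edge_y <- ifelse(in_gt[pairs$i] & in_gt[pairs$j], none_id, NA_integer_)
    e <- gt_graph$edges
    if (nrow(e) && nrow(pairs)) {
      key <- paste(ids[pairs$i], ids[pairs$j], sep = "\r")
      ek <- paste(e$subject, e$object, sep = "\r")
      hit <- match(ek, key)
      ok <- !is.na(hit)
      edge_y[hit[ok]] <- match(e$relation[ok], relation_classes)
    }
  }
  pix <- if (config$use_images && !is.null(images))
    image_pixels(images, config$max_pixels) else matrix(0, 0, 5)
  list(ids = ids, n = n, ent_idx = ent_idx, pairs = pairs,
       points = cloud$points, colors = cloud$colors,
       pix = pix, node_y = node_y, edge_y = edge_y)
}

# Draw the per-epoch point samples (random + augmented when training,
# deterministic stride otherwise) from a static frame.
prepare_sgg_frame <- function(st, config, training = FALSE, poses = NULL,
                              aug = augment_params()) {
  n <- st$n
  draw <- function(idx, m) {
    if (!training) stride_sample(idx, m)
    else if (length(idx) >= m) sample(idx, m)
    else sample(idx, m, replace = TRUE)
  }
  do_aug <- training && config$augment
  colors <- st$colors
  if (do_aug) {
    # lighting is global: one brightness/hue draw per frame, applied to the
    # whole cloud; the per-entity and per-pair draws below are geometric
    br <- stats::runif(1, aug$brightness_range[1], aug$brightness_range[2])
    hu <- stats::runif(1, aug$hue_range_deg[1], aug$hue_range_deg[2])
    colors <- shift_hue(pmin(pmax(colors + br, 0), 1), hu)
  }
  obj_list <- vector("list", n)
  missing <- logical(n)
  for (k in seq_len(n)) {
    idx <- st$ent_idx[[k]]
    if (!length(idx)) { missing[k] <- TRUE; next }
    take <- draw(idx, config$n_obj_points)
    p <- st$points[take, , drop = FALSE]
    cl <- colors[take, , drop = FALSE]
    if (do_aug) p <- augment_geom(p, aug)
    ctr <- colMeans(p)
    p[, 1] <- p[, 1] - ctr[1]; p[, 2] <- p[, 2] - ctr[2]
    p[, 3] <- p[, 3] - ctr[3]
    obj_list[[k]] <- cbind(p, cl, matrix(ctr, nrow(p), 3, byrow = TRUE))
  }
  P <- nrow(st$pairs)
  rel_list <- vector("list", P)
  rel_missing <- logical(P)
  for (q in seq_len(P)) {
    ii <- st$ent_idx[[st$pairs$i[q]]]; jj <- st$ent_idx[[st$pairs$j[q]]]
    idx <- c(ii, jj)
    if (!length(idx)) { rel_missing[q] <- TRUE; next }
    flag <- rep(c(0, 1), c(length(ii), length(jj)))
    sel <- draw(seq_along(idx), config$n_rel_points)
    take <- idx[sel]
    pm <- cbind(st$points[take, , drop = FALSE],
                colors[take, , drop = FALSE], ind = flag[sel])
    if (do_aug) {
      for (gflag in c(0, 1)) { # the two entities move independently
        s <- pm[, 7] == gflag
        if (any(s)) pm[s, 1:3] <- augment_geom(pm[s, 1:3, drop = FALSE], aug)
      }
      if (!is.null(poses) && length(poses)) {
        cr <- crop_to_hands(pm[, 1:3, drop = FALSE], pm[, 4:6, drop = FALSE],
                            poses, aug)
        pm <- pm[cr$kept, , drop = FALSE]
      }
    }
    ctr <- c(mean(pm[, 1]), mean(pm[, 2]), mean(pm[, 3]))
    pm[, 1] <- pm[, 1] - ctr[1]; pm[, 2] <- pm[, 2] - ctr[2]
    pm[, 3] <- pm[, 3] - ctr[3]
    rel_list[[q]] <- cbind(pm[, 1:6, drop = FALSE],
                           matrix(ctr, nrow(pm), 3, byrow = TRUE),
                           pm[, 7])
  }
  list(ids = st$ids, n = n, pairs = st$pairs, obj_list = obj_list,
       missing = missing, rel_list = rel_list, rel_missing = rel_missing,
       pix = st$pix, node_y = st$node_y, edge_y = st$edge_y)
}

stack_groups <- function(lst, missing) {
  keep <- which(!missing)
  if (!length(keep)) return(list(x = matrix(0, 0, 0), group = integer(0),
                                 keep = keep))
  x <- do.call(rbind, lst[keep])
  group <- rep(seq_along(keep), vapply(lst[keep], nrow, 1L))
  list(x = x, group = group, keep = keep)
}

#' Forward pass of the scene-graph network
#'
#' Object and pair PointNet-style encoders (shared per-point MLP + symmetric
#' max pooling, hence permutation invariant), optional global image feature
#' (shared per-pixel MLP + max pooling over all views' foreground pixels)
#' concatenated to every node and edge feature, `gcn_layers` rounds of
#' edge-conditioned message passing over the fully connected candidate
#' graph, and linear classification heads.
#'
#' @param model A model from [train_sgg()] (or internal init).
#' @param fr A prepared frame (internal; see [predict_graph()] for the
#'   user-facing entry).
#' @param want_cache Keep intermediates for backprop.
#' @return List with `node_logits` (n x entity classes), `edge_logits`
#'   (pairs x 15) and optionally `cache`.
#' @export
sgg_forward <- function(model, fr, want_cache = FALSE) {
  p <- model$params; cfg <- model$config
  n <- fr$n; P <- nrow(fr$pairs)
  F <- cfg$feat_dim
  G <- if (cfg$use_images) cfg$img_dim else 0L
  D <- F + G
  cache <- list()
  # object encoder
  so <- stack_groups(fr$obj_list, fr$missing)
  Fo <- matrix(rep(p$o_missing, each = n), n, F)
  if (length(so$keep)) {
    po <- pointnet_fwd(so$x, so$group, length(so$keep),
                       p$oW1, p$ob1, p$oW2, p$ob2)
    Fo[so$keep, ] <- po$pooled
    cache$obj <- po$cache
  }
  cache$so <- so
  # pair encoder
  Fr <- matrix(0, P, F)
  if (P) {
    sr <- stack_groups(fr$rel_list, fr$rel_missing)
    Fr <- matrix(rep(p$r_missing, each = P), P, F)
    if (length(sr$keep)) {
      pr <- pointnet_fwd(sr$x, sr$group, length(sr$keep),
                         p$rW1, p$rb1, p$rW2, p$rb2)
      Fr[sr$keep, ] <- pr$pooled
      cache$rel <- pr$cache
    }
    cache$sr <- sr
  }
  # image pathway
  if (G > 0) {
    if (nrow(fr$pix)) {
      pi_ <- pointnet_fwd(fr$pix, rep(1L, nrow(fr$pix)), 1L,
                          p$iW1, p$ib1, p$iW2, p$ib2)
      g <- as.numeric(pi_$pooled)
      cache$img <- pi_$cache
    } else g <- numeric(G)
    H <- cbind(Fo, matrix(g, n, G, byrow = TRUE))
    E <- if (P) cbind(Fr, matrix(g, P, G, byrow = TRUE)) else matrix(0, 0, D)
    cache$g <- g
  } else {
    H <- Fo
    E <- if (P) Fr else matrix(0, 0, D)
  }
  cache$H0 <- H; cache$E0 <- E; cache$Fo <- Fo; cache$Fr <- Fr
  i_idx <- fr$pairs$i; j_idx <- fr$pairs$j
  layers <- list()
  for (l in seq_len(cfg$gcn_layers)) {
    lc <- list(H_in = H, E_in = E)
    if (P) {
      Min <- cbind(H[j_idx, , drop = FALSE], E)
      M <- relu(lin_fwd(Min, p[[paste0("Wm", l)]], p[[paste0("bm", l)]]))
      S <- rowsum(M, group = i_idx, reorder = FALSE)
      Magg <- matrix(0, n, D)
      Magg[as.integer(rownames(S)), ] <- S / (n - 1)
      lc$Min <- Min; lc$M <- M
    } else Magg <- matrix(0, n, D)
    Hin <- cbind(H, Magg)
    Hn <- relu(lin_fwd(Hin, p[[paste0("Wn", l)]], p[[paste0("bn", l)]]))
    lc$Hin <- Hin; lc$Hn <- Hn; lc$Magg <- Magg
    if (P) {
      Ein <- cbind(H[i_idx, , drop = FALSE], E, H[j_idx, , drop = FALSE])
      En <- relu(lin_fwd(Ein, p[[paste0("We", l)]], p[[paste0("be", l)]]))
      lc$Ein <- Ein; lc$En <- En
    } else En <- E
    H <- Hn; E <- En
    layers[[l]] <- lc
  }
  cache$layers <- layers
  cache$H_fin <- H; cache$E_fin <- E
  node_logits <- lin_fwd(H, p$Wno, p$bno)
  edge_logits <- if (P) lin_fwd(E, p$Wre, p$bre) else
    matrix(0, 0, ncol(p$Wre))
  out <- list(node_logits = node_logits, edge_logits = edge_logits)
  if (want_cache) out$cache <- cache
  out
}

# full backward pass; returns gradient list aligned with params
sgg_backward <- function(model, fr, fwd, dnode, dedge) {
  p <- model$params; cfg <- model$config
  cache <- fwd$cache
  n <- fr$n; P <- nrow(fr$pairs)
  F <- cfg$feat_dim
  G <- if (cfg$use_images) cfg$img_dim else 0L
  D <- F + G
  i_idx <- fr$pairs$i; j_idx <- fr$pairs$j
  gr <- grad_zero(p)
  # heads
  gr$Wno <- crossprod(cache$H_fin, dnode); gr$bno <- colSums(dnode)
  dH <- dnode %*% t(p$Wno)
  if (P) {
    gr$Wre <- crossprod(cache$E_fin, dedge); gr$bre <- colSums(dedge)
    dE <- dedge %*% t(p$Wre)
  } else dE <- matrix(0, 0, D)
  # GCN layers in reverse
  for (l in rev(seq_len(cfg$gcn_layers))) {
    lc <- cache$layers[[l]]
    dH_in <- matrix(0, n, D)
    dE_in <- if (P) matrix(0, P, D) else dE
    # node update
    gn <- lin_relu_bwd(dH, lc$Hn, lc$Hin, p[[paste0("Wn", l)]])
    gr[[paste0("Wn", l)]] <- gr[[paste0("Wn", l)]] + gn$dW
    gr[[paste0("bn", l)]] <- gr[[paste0("bn", l)]] + gn$db
    dH_in <- dH_in + gn$dx[, 1:D, drop = FALSE]
    dMagg <- gn$dx[, D + 1:D, drop = FALSE]
    if (P) {
      # edge update
      ge <- lin_relu_bwd(dE, lc$En, lc$Ein, p[[paste0("We", l)]])
      gr[[paste0("We", l)]] <- gr[[paste0("We", l)]] + ge$dW
      gr[[paste0("be", l)]] <- gr[[paste0("be", l)]] + ge$db
      dHi <- ge$dx[, 1:D, drop = FALSE]
      dE_in <- dE_in + ge$dx[, D + 1:D, drop = FALSE]
      dHj <- ge$dx[, 2 * D + 1:D, drop = FALSE]
      dH_in <- dH_in + rowsum_into(dHi, i_idx, n) + rowsum_into(dHj, j_idx, n)
      # message pathway
      dM <- dMagg[i_idx, , drop = FALSE] / (n - 1)
      gm <- lin_relu_bwd(dM, lc$M, lc$Min, p[[paste0("Wm", l)]])
      gr[[paste0("Wm", l)]] <- gr[[paste0("Wm", l)]] + gm$dW
      gr[[paste0("bm", l)]] <- gr[[paste0("bm", l)]] + gm$db
      dH_in <- dH_in + rowsum_into(gm$dx[, 1:D, drop = FALSE], j_idx, n)
      dE_in <- dE_in + gm$dx[, D + 1:D, drop = FALSE]
    }
    dH <- dH_in; dE <- dE_in
  }
  # split fused features
  dFo <- dH[, 1:F, drop = FALSE]
  dFr <- if (P) dE[, 1:F, drop = FALSE] else matrix(0, 0, F)
  if (G > 0) {
    dg <- colSums(dH[, F + 1:G, drop = FALSE])
    if (P) dg <- dg + colSums(dE[, F + 1:G, drop = FALSE])
    if (!is.null(cache$img)) {
      gi <- pointnet_bwd(matrix(dg, 1, G), cache$img, p$iW1, p$iW2)
      gr$iW1 <- gr$iW1 + gi$dW1; gr$ib1 <- gr$ib1 + gi$db1
      gr$iW2 <- gr$iW2 + gi$dW2; gr$ib2 <- gr$ib2 + gi$db2
    }
  }
  # object encoder
  so <- cache$so
  if (any(fr$missing))
    gr$o_missing <- gr$o_missing +
      colSums(dFo[fr$missing, , drop = FALSE])
  if (length(so$keep)) {
    go <- pointnet_bwd(dFo[so$keep, , drop = FALSE], cache$obj, p$oW1, p$oW2)
    gr$oW1 <- gr$oW1 + go$dW1; gr$ob1 <- gr$ob1 + go$db1
    gr$oW2 <- gr$oW2 + go$dW2; gr$ob2 <- gr$ob2 + go$db2
  }
  # pair encoder
  if (P) {
    sr <- cache$sr
    if (any(fr$rel_missing))
      gr$r_missing <- gr$r_missing +
        colSums(dFr[fr$rel_missing, , drop = FALSE])
    if (length(sr$keep)) {
      grel <- pointnet_bwd(dFr[sr$keep, , drop = FALSE], cache$rel,
                           p$rW1, p$rW2)
      gr$rW1 <- gr$rW1 + grel$dW1; gr$rb1 <- gr$rb1 + grel$db1
      gr$rW2 <- gr$rW2 + grel$dW2; gr$rb2 <- gr$rb2 + grel$db2
    }
  }
  gr
}

rowsum_into <- function(x, idx, n) {
  s <- rowsum(x, group = idx, reorder = FALSE)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(s)), ] <- s
  out
}

#' Train the scene-graph generation network
#'
#' End-to-end weighted cross-entropy over node entity classes and ordered-
#' pair relation classes (`"None"` explicit). Every unordered-pair ordering
#' without a ground-truth edge supervises `"None"`. One Adam step per frame;
#' augmentations redrawn per epoch; fully reproducible from `config$seed`.
#'
#' @param frames List of frames: each a list with `cloud` (labeled
#'   [point_cloud_frame()] with entity registry), `images` (list of view
#'   arrays, optional), `gt_graph` (a [scene_graph()]), `poses` (optional,
#'   for crop-to-hand).
#' @param config An [sgg_config()].
#' @param entities,relations Vocabularies.
#' @return List of class `sgg_model`: `params`, `config`, `classes`,
#'   `loss_history` (per-epoch mean loss), `rel_weights`.
#' @export
train_sgg <- function(frames, config = sgg_config(),
                      entities = entity_vocabulary(),
                      relations = relation_vocabulary()) {
  stopifnot(length(frames) >= 1)
  set.seed(config$seed)
  ent_classes <- entities$names
  rel_classes <- relations$all
  params <- init_sgg_params(config, length(ent_classes), length(rel_classes))
  model <- list(params = params, config = config,
                classes = list(entities = ent_classes,
                               relations = rel_classes))
  class(model) <- "sgg_model"
  # relation class counts over the pair universe for balancing
  counts <- stats::setNames(numeric(length(rel_classes)), rel_classes)
  for (f in frames) {
    g <- f$gt_graph
    n <- length(g$nodes)
    npairs <- n * (n - 1)
    tab <- table(factor(g$edges$relation, levels = rel_classes))
    counts <- counts + as.numeric(tab)
    counts["None"] <- counts["None"] + npairs - nrow(g$edges)
  }
  rel_w <- class_balanced_weights(counts, config$class_weighting)
  model$rel_weights <- rel_w
  opt <- adam_init(params)
  history <- numeric(config$epochs)
  aug <- augment_params()
  statics <- lapply(frames, function(f)
    sgg_frame_static(f$cloud, f$images, f$gt_graph, config,
                     ent_classes, rel_classes))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(frames))
    tot <- 0
    for (fi in ord) {
      f <- frames[[fi]]
      fr <- prepare_sgg_frame(statics[[fi]], config, training = TRUE,
                              poses = f$poses, aug = aug)
      fwd <- sgg_forward(model, fr, want_cache = TRUE)
      mn <- which(!is.na(fr$node_y))
      me <- which(!is.na(fr$edge_y))
      ln <- ce_loss(fwd$node_logits[mn, , drop = FALSE], fr$node_y[mn])
      le <- ce_loss(fwd$edge_logits[me, , drop = FALSE], fr$edge_y[me], rel_w)
      dnode <- fwd$node_logits * 0; dnode[mn, ] <- ln$dlogits
      dedge <- fwd$edge_logits * 0
      if (length(me)) dedge[me, ] <- le$dlogits
      loss <- ln$loss + le$loss
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf loss at epoch %d frame %d; reduce the learning rate",
                     ep, fi))
      grads <- sgg_backward(model, fr, fwd, dnode, dedge)
      upd <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- upd$params; opt <- upd$state
      tot <- tot + loss
    }
    history[ep] <- tot / length(frames)
  }
  model$loss_history <- history
  model
}

#' Predict a scene graph for one frame
#'
#' Node class = argmax over entity classes; each ordered pair receives its
#' argmax relation unless that is `"None"`. Inference sampling is
#' deterministic (stride subsampling, no RNG), so repeated calls agree
#' exactly. The output passes [validate_graph()].
#'
#' @param model A trained [train_sgg()] model.
#' @param frame List with `cloud` (labeled) and optionally `images`.
#' @param frame_id Frame index for the output graph.
#' @return A [scene_graph()] whose node ids are the entity registry ids.
#' @export
predict_graph <- function(model, frame, frame_id = 1L) {
  st <- sgg_frame_static(frame$cloud, frame$images, NULL, model$config,
                         model$classes$entities, model$classes$relations)
  fr <- prepare_sgg_frame(st, model$config, training = FALSE)
  fwd <- sgg_forward(model, fr)
  node_cls <- model$classes$entities[max.col(fwd$node_logits, "first")]
  nodes <- Map(function(id, cl) entity(id, cl), fr$ids, node_cls)
  edges <- NULL
  if (nrow(fr$pairs)) {
    rel <- model$classes$relations[max.col(fwd$edge_logits, "first")]
    keep <- rel != "None"
    if (any(keep))
      edges <- data.frame(subject = fr$ids[fr$pairs$i[keep]],
                          relation = rel[keep],
                          object = fr$ids[fr$pairs$j[keep]],
                          stringsAsFactors = FALSE)
  }
  scene_graph(frame_id, nodes, edges)
}

#' Save or load a trained model checkpoint
#'
#' Single-file checkpoint with the configuration embedded (RDS; a run-time
#' artifact, not a distribution format).
#' @param model An `sgg_model` (or `role_model`).
#' @param path Checkpoint file path.
#' @return `load_sgg_model` returns the model.
#' @export
save_sgg_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sgg_model
#' @export
load_sgg_model <- function(path) readRDS(path)

#' Build SGG training frames from simulator bundles
#'
#' Uses the simulator's ground-truth instance labels (or recomputes them
#' geometrically from poses and boxes when `use_gt_labels = FALSE`).
#'
#' @param bundles Output of [simulate_timeline()] with geometry.
#' @param use_gt_labels Use the rendering ground truth (default) or
#'   [compute_instance_labels()].
#' @param use_images Keep view images in the frames.
#' @return List of frames consumable by [train_sgg()].
#' @export
sgg_dataset <- function(bundles, use_gt_labels = TRUE, use_images = TRUE) {
  lapply(bundles, function(b) {
    cloud <- b$cloud
    if (!use_gt_labels)
      cloud <- compute_instance_labels(cloud, b$poses, b$boxes)
    list(cloud = cloud, images = if (use_images) b$images,
         gt_graph = b$gt_graph, poses = b$poses, frame_id = b$frame_id)
  })
}
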