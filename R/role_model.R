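#' Learned role-scorer configuration
#'
#' A compact target-marked graph encoder: node inputs are a class one-hot
#' plus a binary target flag (set only on the track's human node), two
#' rounds of relation-conditioned message passing update node states, the
#' target-node embeddings are averaged over the track's selected graphs, and
#' a linear head with softmax yields the 5 role scores. A contract-equivalent
#' stand-in for heavyweight graph transformers.
#'
#' @param dim Node state width.
#' @param rounds Message-passing rounds.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @return List of class `role_model_config`.
#' @export
role_model_config <- function(dim = 32L, rounds = 2L, learning_rate = 5e-3,
                              epochs = 40L, seed = 1L) {
  structure(list(dim = as.integer(dim), rounds = as.integer(rounds),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)), class = "role_model_config")
}

role_graph_inputs <- function(graph, target_id, entities, relations) {
  ids <- node_ids(graph)
  C <- length(entities$names)
  x <- matrix(0, length(ids), C + 1)
  cls <- node_classes(graph)
  x[cbind(seq_along(ids), match(unname(cls[ids]), entities$names))] <- 1
  x[match(target_id, ids), C + 1] <- 1
  e <- graph$edges
  list(x = x, s = match(e$subject, ids), o = match(e$object, ids),
       r = match(e$relation, relations$names),
       target = match(target_id, ids), n = length(ids))
}

role_encoder_fwd <- function(p, gi, cfg, nr) {
  H <- relu(lin_fwd(gi$x, p$W0, p$b0))
  d <- cfg$dim
  layers <- list()
  E <- length(gi$s)
  R1 <- matrix(0, E, nr)
  if (E) R1[cbind(seq_len(E), gi$r)] <- 1
  for (l in seq_len(cfg$rounds)) {
    lc <- list(H_in = H)
    if (E) {
      Min <- cbind(H[gi$s, , drop = FALSE], R1)
      Mi <- relu(lin_fwd(Min, p[[paste0("Wmi", l)]], p[[paste0("bmi", l)]]))
      Mout <- cbind(H[gi$o, , drop = FALSE], R1)
      Mo <- relu(lin_fwd(Mout, p[[paste0("Wmo", l)]], p[[paste0("bmo", l)]]))
      cin <- tabulate(gi$o, gi$n); cout <- tabulate(gi$s, gi$n)
      Ain <- rowsum_into(Mi, gi$o, gi$n) / pmax(cin, 1)
      Aout <- rowsum_into(Mo, gi$s, gi$n) / pmax(cout, 1)
      lc$Min <- Min; lc$Mi <- Mi; lc$Mout <- Mout; lc$Mo <- Mo
      lc$cin <- cin; lc$cout <- cout
    } else { Ain <- Aout <- matrix(0, gi$n, d) }
    U <- cbind(H, Ain, Aout)
    H <- relu(lin_fwd(U, p[[paste0("Wu", l)]], p[[paste0("bu", l)]]))
    lc$U <- U; lc$H_out <- H
    layers[[l]] <- lc
  }
  list(H = H, layers = layers, R1 = R1)
}

role_encoder_bwd <- function(p, gi, cfg, fwd, dH, gr) {
  d <- cfg$dim
  E <- length(gi$s)
  for (l in rev(seq_len(cfg$rounds))) {
    lc <- fwd$layers[[l]]
    gu <- lin_relu_bwd(dH, lc$H_out, lc$U, p[[paste0("Wu", l)]])
    gr[[paste0("Wu", l)]] <- gr[[paste0("Wu", l)]] + gu$dW
    gr[[paste0("bu", l)]] <- gr[[paste0("bu", l)]] + gu$db
    dH_in <- gu$dx[, 1:d, drop = FALSE]
    if (E) {
      dAin <- gu$dx[, d + 1:d, drop = FALSE]
      dAout <- gu$dx[, 2 * d + 1:d, drop = FALSE]
      dMi <- dAin[gi$o, , drop = FALSE] / pmax(lc$cin, 1)[gi$o]
      dMo <- dAout[gi$s, , drop = FALSE] / pmax(lc$cout, 1)[gi$s]
      gmi <- lin_relu_bwd(dMi, lc$Mi, lc$Min, p[[paste0("Wmi", l)]])
      gmo <- lin_relu_bwd(dMo, lc$Mo, lc$Mout, p[[paste0("Wmo", l)]])
      gr[[paste0("Wmi", l)]] <- gr[[paste0("Wmi", l)]] + gmi$dW
      gr[[paste0("bmi", l)]] <- gr[[paste0("bmi", l)]] + gmi$db
      gr[[paste0("Wmo", l)]] <- gr[[paste0("Wmo", l)]] + gmo$dW
      gr[[paste0("bmo", l)]] <- gr[[paste0("bmo", l)]] + gmo$db
      dH_in <- dH_in + rowsum_into(gmi$dx[, 1:d, drop = FALSE], gi$s, gi$n) +
        rowsum_into(gmo$dx[, 1:d, drop = FALSE], gi$o, gi$n)
    }
    dH <- dH_in
  }
  g0 <- lin_relu_bwd(dH, relu(lin_fwd(gi$x, p$W0, p$b0)), gi$x, p$W0)
  gr$W0 <- gr$W0 + g0$dW; gr$b0 <- gr$b0 + g0$db
  gr
}

#' Train the learned role scorer
#'
#' Cross-entropy over tracks with known roles.
#'
#' @param tracks List of tracks with `selected_graphs` and `target_nodes`
#'   (see [select_track_graphs()]).
#' @param roles Character vector of ground-truth roles, one per track.
#' @param config A [role_model_config()].
#' @param entities,relations Vocabularies.
#' @return List of class `role_model`.
#' @export
train_role_model <- function(tracks, roles, config = role_model_config(),
                             entities = entity_vocabulary(),
                             relations = relation_vocabulary()) {
  stopifnot(length(tracks) == length(roles), all(roles %in% clinical_roles()))
  set.seed(config$seed)
  d <- config$dim
  C <- length(entities$names)
  nr <- length(relations$names)
  p <- list(W0 = he_init(C + 1, d), b0 = numeric(d),
            Whead = he_init(d, 5), bhead = numeric(5))
  for (l in seq_len(config$rounds)) {
    p[[paste0("Wmi", l)]] <- he_init(d + nr, d)
    p[[paste0("bmi", l)]] <- numeric(d)
    p[[paste0("Wmo", l)]] <- he_init(d + nr, d)
    p[[paste0("bmo", l)]] <- numeric(d)
    p[[paste0("Wu", l)]] <- he_init(3 * d, d)
    p[[paste0("bu", l)]] <- numeric(d)
  }
  y <- match(roles, clinical_roles())
  inputs <- lapply(tracks, function(tr)
    Map(role_graph_inputs, tr$selected_graphs, tr$target_nodes,
        MoreArgs = list(entities = entities, relations = relations)))
  opt <- adam_init(p)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(tracks))
    tot <- 0
    for (ti in ord) {
      gis <- inputs[[ti]]
      K <- length(gis)
      fwds <- lapply(gis, role_encoder_fwd, p = p, cfg = config, nr = nr)
      emb <- Reduce(`+`, Map(function(fw, gi) fw$H[gi$target, ], fwds, gis)) / K
      logits <- matrix(emb, 1, d) %*% p$Whead
      logits <- logits + matrix(p$bhead, 1, 5)
      ce <- ce_loss(logits, y[ti])
      tot <- tot + ce$loss
      gr <- grad_zero(p)
      gr$Whead <- crossprod(matrix(emb, 1, d), ce$dlogits)
      gr$bhead <- as.numeric(ce$dlogits)
      demb <- as.numeric(ce$dlogits %*% t(p$Whead)) / K
      for (k in seq_len(K)) {
        dH <- matrix(0, gis[[k]]$n, d)
        dH[gis[[k]]$target, ] <- demb
        gr <- role_encoder_bwd(p, gis[[k]], config, fwds[[k]], dH, gr)
      }
      upd <- adam_step(p, gr, opt, config$learning_rate)
      p <- upd$params; opt <- upd$state
    }
    history[ep] <- tot / length(tracks)
  }
  structure(list(params = p, config = config,
                 entities = entities, relations = relations,
                 loss_history = history), class = "role_model")
}

#' Learned role likelihoods for one track
#'
#' @param track Track with `selected_graphs` and `target_nodes`.
#' @param model A trained [train_role_model()].
#' @return Named numeric vector over [clinical_roles()], summing to 1.
#' @export
learned_role_scores <- function(track, model) {
  if (!inherits(model, "role_model")) stop("untrained or invalid role model")
  cfg <- model$config
  nr <- length(model$relations$names)
  gis <- Map(role_graph_inputs, track$selected_graphs, track$target_nodes,
             MoreArgs = list(entities = model$entities,
                             relations = model$relations))
  K <- length(gis)
  emb <- Reduce(`+`, lapply(seq_len(K), function(k) {
    fw <- role_encoder_fwd(model$params, gis[[k]], cfg, nr)
    fw$H[gis[[k]]$target, ]
  })) / K
  z <- as.numeric(matrix(emb, 1) %*% model$params$Whead) + model$params$bhead
  z <- z - max(z)
  stats::setNames(exp(z) / sum(exp(z)), clinical_roles())
}
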