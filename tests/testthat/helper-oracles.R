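# Independent oracles, deliberately written from scratch (not via package
# internals), used to cross-check the implementation.

# step-by-step re-simulation of the printed greedy role assignment
oracle_greedy_assign <- function(m) {
  roles <- colnames(m)
  out <- setNames(rep(NA_character_, nrow(m)), rownames(m))
  open_t <- seq_len(nrow(m))
  open_r <- seq_len(ncol(m))
  while (length(open_t) && length(open_r)) {
    best_val <- -1; best <- NULL
    for (t in open_t) for (r in open_r) { # row-major scan = tie-break order
      if (m[t, r] > best_val) { best_val <- m[t, r]; best <- c(t, r) }
    }
    if (best_val == 0) best <- c(open_t[1], open_r[1])
    out[best[1]] <- roles[best[2]]
    open_t <- setdiff(open_t, best[1])
    open_r <- setdiff(open_r, best[2])
    for (t in open_t) {
      m[t, best[2]] <- 0
      s <- sum(m[t, open_r])
      if (s > 0) m[t, open_r] <- m[t, open_r] / s
    }
  }
  out
}

# brute-force min-cost assignment by permutation enumeration (square or
# rows <= cols)
oracle_brute_assign <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- Inf; besta <- NULL
  for (p in perms(seq_len(nc))) {
    a <- p[seq_len(nr)]
    s <- sum(cost[cbind(seq_len(nr), a)])
    if (s < best - 1e-12) { best <- s; besta <- a }
  }
  list(assign = besta, cost = best)
}

# naive multi-class precision/recall/F1
oracle_prf <- function(pred, truth, classes) {
  per <- t(vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }, numeric(3)))
  colnames(per) <- c("precision", "recall", "f1")
  per
}

# small hand-built graph fixtures
fix_graph <- function(frame_id = 1L) {
  scene_graph(frame_id,
              list(entity("hs1", "head surgeon"),
                   entity("p1", "patient"),
                   entity("t1", "operating table")),
              data.frame(subject = c("hs1", "p1"),
                         relation = c("Sawing", "LyingOn"),
                         object = c("p1", "t1")))
}

rand_pose <- function(id, center = c(0, 0)) {
  human_pose(id, orssg:::standing_pose_joints(center))
}
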