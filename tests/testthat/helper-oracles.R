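# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops, exhaustive enumeration.

# Rolling-ball baseline for one column: enumerate every ball position p,
# push the semicircular element up until it touches the profile, and take
# the upper envelope of all placed balls.
oracle_rolling_ball_col <- function(v, r, dx = 1) {
  n <- length(v)
  m <- floor(r / dx)
  h <- sqrt(r^2 - ((-m:m) * dx)^2)
  baseline <- rep(-Inf, n)
  for (p in seq_len(n)) {
    js <- (-m:m)[p + (-m:m) >= 1 & p + (-m:m) <= n]
    c_p <- min(v[p + js] - h[js + m + 1])
    for (j in js) {
      i <- p + j
      baseline[i] <- max(baseline[i], c_p + h[j + m + 1])
    }
  }
  baseline
}

# Connected components by repeated flood fill over an explicit queue.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(rr, cc), 1)
    lab[rr, cc] <- nxt
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb$dr[k]; c2 <- p[2] + nb$dc[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue <- rbind(queue, c(r2, c2))
        }
      }
    }
  }
  lab
}

# Union of the +/- h neighborhood of every pixel, clipped to the image.
oracle_dilate <- function(px, shape, h = 2) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(px))) {
    for (dr in -h:h) for (dc in -h:h) {
      r2 <- px[i, 1] + dr; c2 <- px[i, 2] + dc
      if (r2 >= 1 && r2 <= shape[1] && c2 >= 1 && c2 <= shape[2])
        out[r2, c2] <- TRUE
    }
  }
  which(out, arr.ind = TRUE)
}

# Exhaustive maximum-cardinality matching among candidate pairs (<= ~20
# candidates): enumerate subsets of candidate pairs.
oracle_max_matching <- function(cand) {
  if (!nrow(cand)) return(0L)
  best <- 0L
  n <- nrow(cand)
  recurse <- function(k, used_b, used_r, size) {
    if (size + (n - k + 1) <= best) return()
    if (k > n) { best <<- max(best, size); return() }
    b <- cand[k, 1]; r <- cand[k, 2]
    if (!(b %in% used_b) && !(r %in% used_r))
      recurse(k + 1, c(used_b, b), c(used_r, r), size + 1L)
    recurse(k + 1, used_b, used_r, size)
  }
  recurse(1L, integer(0), integer(0), 0L)
  best
}

# Greedy recall/false-positive scoring of detections against a truth table
# (match = centroid within `tol` px of a truth center, one-to-one).
match_truth <- function(truth_rc, spots_tab, tol = 2) {
  if (!nrow(truth_rc) || !nrow(spots_tab))
    return(list(recall = 0, fp = if (nrow(spots_tab)) 1 else 0,
                matched = integer(0)))
  d <- sqrt(outer(truth_rc$row, spots_tab$centroid_row, "-")^2 +
            outer(truth_rc$col, spots_tab$centroid_col, "-")^2)
  hit_t <- apply(d, 1, min) <= tol
  hit_s <- apply(d, 2, min) <= tol
  list(recall = mean(hit_t), fp = mean(!hit_s),
       matched = apply(d, 1, which.min)[hit_t],
       matched_truth = which(hit_t))
}

truth_channel <- function(truth, channel) {
  keep <- truth$channel %in% c(channel, "both")
  truth[keep, , drop = FALSE]
}

# Small fast scene for unit tests (256x256, 40 emitters).
small_scene_params <- function(seed = 1, ...) {
  over <- list(...)
  args <- list(image_shape = c(256L, 256L), n_vesicles = 40L, seed = seed)
  args[names(over)] <- over
  do.call(scene_params, args)
}
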