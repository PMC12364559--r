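# Independent reference implementations: plain scalar loops over pixels
# and channels, and a cutoff-enumeration mAP evaluator.  These stay
# deliberately naive and separate from the package's vectorised code.

clip_scalar <- function(x) min(max(x, 0), 1)

oracle_fd_abs <- function(seq, t, dt, up) {
  cur <- get_frame(seq, t)
  prev <- get_frame(seq, t - dt)
  nxt <- get_frame(seq, t + dt)
  d <- dim(cur)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
    v <- up * 0.5 * (abs(cur[i, j, c] - prev[i, j, c]) +
                       abs(cur[i, j, c] - nxt[i, j, c]))
    out[i, j, c] <- clip_scalar(v)
  }
  out
}

oracle_fd_dir <- function(seq, t, dt, up) {
  cur <- get_frame(seq, t)
  prev <- get_frame(seq, t - dt)
  nxt <- get_frame(seq, t + dt)
  d <- dim(cur)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
    v <- 0.5 + (up / 4) * ((cur[i, j, c] - prev[i, j, c]) +
                             (nxt[i, j, c] - prev[i, j, c]))
    out[i, j, c] <- clip_scalar(v)
  }
  out
}

oracle_background <- function(seq, t, n_b, dtb) {
  d <- dim(get_frame(seq, t))
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
    s <- 0
    for (k in seq_len(n_b)) {
      s <- s + get_frame(seq, t - k * dtb)[i, j, c]
    }
    out[i, j, c] <- s / n_b
  }
  out
}

oracle_bs_fd <- function(seq, t, n_b, dtb, up) {
  fb <- oracle_background(seq, t, n_b, dtb)
  cur <- get_frame(seq, t)
  d <- dim(cur)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
    out[i, j, c] <- clip_scalar(0.5 + (up / 2) * (cur[i, j, c] - fb[i, j, c]))
  }
  out
}

oracle_knn <- function(seq, t, history, k, thr) {
  cur <- get_frame(seq, t)
  d <- dim(cur)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    dist <- numeric(history)
    for (h in seq_len(history)) {
      past <- get_frame(seq, t - h)
      dist[h] <- sqrt((cur[i, j, 1] - past[i, j, 1])^2 +
                        (cur[i, j, 2] - past[i, j, 2])^2 +
                        (cur[i, j, 3] - past[i, j, 3])^2)
    }
    kk <- min(k, history)
    nearest <- sort(dist)[seq_len(kk)]
    out[i, j] <- as.numeric(sum(nearest > thr) >= floor(kk / 2) + 1)
  }
  out
}

oracle_collapse <- function(vals) {
  d <- dim(vals)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    out[i, j] <- (vals[i, j, 1] + vals[i, j, 2] + vals[i, j, 3]) / 3
  }
  out
}

oracle_flow_magnitude <- function(vx, vy, r_max) {
  out <- matrix(0, nrow(vx), ncol(vx))
  for (i in seq_len(nrow(vx))) for (j in seq_len(ncol(vx))) {
    out[i, j] <- clip_scalar(sqrt(vx[i, j]^2 + vy[i, j]^2) / r_max)
  }
  out
}

oracle_apply_pca <- function(model, frame) {
  d <- dim(frame)
  out <- array(0, c(d[1], d[2], 2))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    px <- c(frame[i, j, 1], frame[i, j, 2], frame[i, j, 3]) - model$mean
    for (comp in 1:2) {
      s <- sum(px * model$components[, comp]) * model$whitening_scale[comp]
      s <- (s - model$range_offset[comp]) * model$range_scale[comp]
      out[i, j, comp] <- clip_scalar(s)
    }
  }
  out
}

# --- mAP oracle ------------------------------------------------------

oracle_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) {
    return(0)
  }
  inter <- iw * ih
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (aa + ab - inter)
}

corners_of <- function(tbl, i) {
  c(tbl$cx[i] - tbl$bw[i] / 2, tbl$cy[i] - tbl$bh[i] / 2,
    tbl$cx[i] + tbl$bw[i] / 2, tbl$cy[i] + tbl$bh[i] / 2)
}

# TP count among detections with score >= cutoff, matching greedily in
# descending score order against unmatched same-image ground truth.
oracle_tp_at_cutoff <- function(dets, gts, thresh, cutoff) {
  keep <- which(dets$score >= cutoff)
  keep <- keep[order(-dets$score[keep])]
  used <- rep(FALSE, nrow(gts))
  tp <- 0
  for (i in keep) {
    best <- 0
    best_j <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$image_ref[j] != dets$image_ref[i]) next
      v <- oracle_iou(corners_of(dets, i), corners_of(gts, j))
      if (v > best) {
        best <- v
        best_j <- j
      }
    }
    if (best_j > 0 && best >= thresh) {
      tp <- tp + 1
      used[best_j] <- TRUE
    }
  }
  tp
}

# All-point AP by enumerating every score cutoff and recomputing
# precision/recall from scratch at each.
oracle_ap <- function(dets, gts, class_id, thresh) {
  g <- gts[gts$class_id == class_id, ]
  d <- dets[dets$class_id == class_id, ]
  if (nrow(g) == 0) {
    return(NA_real_)
  }
  if (nrow(d) == 0) {
    return(0)
  }
  cutoffs <- sort(unique(d$score), decreasing = TRUE)
  rec <- prec <- numeric(length(cutoffs))
  for (k in seq_along(cutoffs)) {
    tp <- oracle_tp_at_cutoff(d, g, thresh, cutoffs[k])
    nd <- sum(d$score >= cutoffs[k])
    rec[k] <- tp / nrow(g)
    prec[k] <- tp / nd
  }
  levels <- sort(unique(rec))
  ap <- 0
  prev_r <- 0
  for (r in levels) {
    p_int <- max(prec[rec >= r])
    ap <- ap + (r - prev_r) * p_int
    prev_r <- r
  }
  ap
}

oracle_map <- function(dets, gts, thresh) {
  classes <- sort(unique(gts$class_id))
  mean(vapply(classes, function(cl) oracle_ap(dets, gts, cl, thresh),
              numeric(1)))
}
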