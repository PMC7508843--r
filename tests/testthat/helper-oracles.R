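# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (flood fill, O(n^2) concordance, per-timestep
# loops, exhaustive rule tables) and must stay independent of the package
# implementation they check.

# breadth-first flood fill over a 3-D binary array
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        n <- co + offs[r, ]
        if (any(n < 1) || any(n > d)) next
        ni <- n[1] + (n[2] - 1) * d[1] + (n[3] - 1) * d[1] * d[2]
        if (mask[ni] && lab[ni] == 0L) {
          lab[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  list(labels = lab, count = cur)
}

# pairwise concordance probability (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# straightforward per-timestep loop for the weighted sequence loss
oracle_loss <- function(Y, Yhat, lambda) {
  eps <- 1e-7
  total <- 0
  for (n in seq_len(nrow(Y))) {
    s <- 0
    for (t in seq_len(ncol(Y))) {
      y <- Y[n, t]
      p <- min(max(Yhat[n, t], eps), 1 - eps)
      yb <- if (y == 1) 1 else 0
      s <- s + (yb * log(p) + (1 - yb) * log(1 - p)) * lambda[y + 1]
    }
    total <- total - s / ncol(Y)
  }
  total / nrow(Y)
}

# outcome-labeling rule applied literally to one observation
oracle_label <- function(event_month, dry_months, obs_month, k) {
  if (!is.na(event_month) && event_month - obs_month <= k) return("progressor")
  if (any(dry_months > obs_month + k)) return("non_progressor")
  "censored"
}

# rasterised point-in-convex-hull area (mm^2) on a fine grid
oracle_hull_area <- function(px, py, xmax, ymax, step = 0.01) {
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  gx <- seq(step / 2, xmax, by = step)
  gy <- seq(step / 2, ymax, by = step)
  inside <- 0L
  nh <- length(hx)
  for (xi in gx) {
    for (yi in gy) {
      # ray-casting point-in-polygon
      cross <- 0L
      for (a in seq_len(nh)) {
        b <- if (a == nh) 1L else a + 1L
        if ((hy[a] > yi) != (hy[b] > yi)) {
          xint <- hx[a] + (yi - hy[a]) * (hx[b] - hx[a]) / (hy[b] - hy[a])
          if (xi < xint) cross <- cross + 1L
        }
      }
      if (cross %% 2L == 1L) inside <- inside + 1L
    }
  }
  inside * step^2
}

# tiny deterministic test cohort used by several files
tiny_cohort <- function(n_eyes = 30L, seed = 42L, months = 24L) {
  generate_cohort(cohort_spec(n_eyes = n_eyes, months = months, seed = seed))
}

# hand-built eye history from a skeleton of (month, status) pairs
make_history <- function(dry_months, event_month = NA_real_) {
  visits <- data.frame(
    patient_id = "P1", eye_id = "E1", month = dry_months,
    dx_status = "dry", treated = FALSE
  )
  for (fn in drusenseq::feature_names(FALSE)) visits[[fn]] <- 0.1
  if (!is.na(event_month)) {
    marker <- visits[1, ]
    marker$month <- event_month
    marker$dx_status <- "exudative"
    marker$treated <- TRUE
    visits <- rbind(visits, marker)
  }
  drusenseq::eye_histories(visits)[["E1"]]
}
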