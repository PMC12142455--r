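# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with the slowest, most explicit method available
# (per-cell loops, all-pairs scans, exhaustive enumeration) and share no code
# with the package internals.

# 3x3-neighborhood gradient: per focal cell, mean of adjacent-pair
# differences along each axis divided by cell size, vector-summed.
oracle_gradient <- function(M, cell_size) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ew <- c(); ns <- c()
    for (r in max(1, i - 1):min(nr, i + 1)) {
      for (cc in max(1, j - 1):(min(nc, j + 1) - 1)) {
        if (cc >= max(1, j - 1) && cc + 1 <= min(nc, j + 1)) {
          d <- (M[r, cc + 1] - M[r, cc]) / cell_size
          if (!is.na(d)) ew <- c(ew, d)
        }
      }
    }
    for (cc in max(1, j - 1):min(nc, j + 1)) {
      for (r in max(1, i - 1):(min(nr, i + 1) - 1)) {
        if (r >= max(1, i - 1) && r + 1 <= min(nr, i + 1)) {
          d <- (M[r, cc] - M[r + 1, cc]) / cell_size
          if (!is.na(d)) ns <- c(ns, d)
        }
      }
    }
    if (length(ew) || length(ns)) {
      ew_m <- if (length(ew)) mean(ew) else NA_real_
      ns_m <- if (length(ns)) mean(ns) else NA_real_
      out[i, j] <- sqrt(ew_m^2 + ns_m^2)
    }
  }
  out
}

# Exhaustive all-pairs analog search (O(N^2)); ties broken by smaller
# dissimilarity then row-major index, matching the documented contract.
oracle_analog <- function(a_list, b_list, s_list, cell_size, threshold,
                          radius_km) {
  nr <- nrow(a_list[[1]]); nc <- ncol(a_list[[1]])
  dist_out <- matrix(NA_real_, nr, nc)
  idx_out <- matrix(NA_integer_, nr, nc)
  no_analog <- matrix(FALSE, nr, nc)
  invalid <- matrix(FALSE, nr, nc)
  thr2 <- threshold^2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    bad <- FALSE
    for (k in seq_along(a_list)) {
      if (is.na(a_list[[k]][i, j]) || is.na(s_list[[k]][i, j]) ||
          s_list[[k]][i, j] <= 0) bad <- TRUE
    }
    if (bad) { invalid[i, j] <- TRUE; next }
    best_d <- Inf; best_dis <- Inf; best_idx <- NA_integer_
    for (ci in seq_len(nr)) for (cj in seq_len(nc)) {
      d <- cell_size * sqrt((ci - i)^2 + (cj - j)^2)
      if (d > radius_km) next
      dis2 <- 0; miss <- FALSE
      for (k in seq_along(a_list)) {
        bv <- b_list[[k]][ci, cj]
        if (is.na(bv)) { miss <- TRUE; break }
        dis2 <- dis2 + ((bv - a_list[[k]][i, j]) / s_list[[k]][i, j])^2
      }
      if (miss || dis2 > thr2) next
      idx <- (ci - 1) * nc + cj  # row-major, 1-based
      if (d < best_d ||
          (d == best_d && dis2 < best_dis) ||
          (d == best_d && dis2 == best_dis && idx < best_idx)) {
        best_d <- d; best_dis <- dis2; best_idx <- idx
      }
    }
    if (is.finite(best_d)) {
      dist_out[i, j] <- best_d; idx_out[i, j] <- best_idx
    } else no_analog[i, j] <- TRUE
  }
  list(distance = dist_out, analog = idx_out, no_analog = no_analog,
       invalid = invalid)
}

# Greedy nearest-neighbour matching without replacement, plain R loop.
# treated processed in the given order; ties by smaller control id.
oracle_greedy_match <- function(treated_scores, control_scores, control_ids,
                                caliper) {
  used <- rep(FALSE, length(control_scores))
  out_id <- rep(NA_integer_, length(treated_scores))
  for (t in seq_along(treated_scores)) {
    d <- abs(control_scores - treated_scores[t])
    d[used] <- Inf
    if (all(is.infinite(d))) next
    best <- which(d == min(d))
    best <- best[which.min(control_ids[best])]
    if (d[best] <= caliper) {
      out_id[t] <- control_ids[best]
      used[best] <- TRUE
    }
  }
  out_id
}

# All-pairs concordance count for the C-statistic (ties count 1/2).
oracle_c_statistic <- function(scores, treatment) {
  st <- scores[treatment]; sc <- scores[!treatment]
  conc <- 0
  for (a in st) for (b in sc)
    conc <- conc + (a > b) + 0.5 * (a == b)
  auc <- conc / (length(st) * length(sc))
  max(auc, 1 - auc)
}

# Shared planar two-period setup with exactly known velocity r/g.
planar_setup <- function(grid, trend = 0.05, gradient = 0.01, noise_sd = 0,
                         seed = NULL, axis = "x") {
  b <- make_planar_series(grid, 1981:2010, temporal_trend = trend,
                          spatial_gradient = gradient, noise_sd = noise_sd,
                          gradient_axis = axis, seed = seed)
  f <- make_planar_series(grid, 2041:2070, temporal_trend = trend,
                          spatial_gradient = gradient, noise_sd = noise_sd,
                          gradient_axis = axis, ref_year = 1981,
                          period_label = "future",
                          seed = if (is.null(seed)) NULL else seed + 1)
  list(baseline = b, future = f)
}

# Vectorized all-pairs analog oracle (one vector pass per focal cell);
# independently re-derives the same contract as oracle_analog but scales to
# the 40x40 acceptance grids. Tie-breaks: distance, dissimilarity, row-major.
oracle_analog_vec <- function(a_list, b_list, s_list, cell_size, threshold,
                              radius_km) {
  nr <- nrow(a_list[[1]]); nc <- ncol(a_list[[1]])
  row_i <- matrix(seq_len(nr), nr, nc)
  col_j <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rowmajor <- (row_i - 1) * nc + col_j
  dist_out <- matrix(NA_real_, nr, nc)
  idx_out <- matrix(NA_integer_, nr, nc)
  no_analog <- matrix(FALSE, nr, nc)
  thr2 <- threshold^2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (k in seq_along(a_list))
      if (is.na(a_list[[k]][i, j]) || is.na(s_list[[k]][i, j]) ||
          s_list[[k]][i, j] <= 0) ok <- FALSE
    if (!ok) next
    dis2 <- 0
    for (k in seq_along(a_list))
      dis2 <- dis2 + ((b_list[[k]] - a_list[[k]][i, j]) / s_list[[k]][i, j])^2
    d <- cell_size * sqrt((row_i - i)^2 + (col_j - j)^2)
    qual <- which(!is.na(dis2) & dis2 <= thr2 & d <= radius_km)
    if (!length(qual)) { no_analog[i, j] <- TRUE; next }
    o <- qual[order(d[qual], dis2[qual], rowmajor[qual])][1]
    dist_out[i, j] <- d[o]
    idx_out[i, j] <- rowmajor[o]
  }
  list(distance = dist_out, analog = idx_out, no_analog = no_analog)
}
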