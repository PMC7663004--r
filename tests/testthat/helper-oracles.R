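# Brute-force reference implementations, deliberately naive: double loops
# over pixels and offsets, BFS flood fill, exhaustive matching. They share
# no code with the package internals.

oracle_erode <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  off <- se$offsets
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    keep <- TRUE
    for (k in seq_len(nrow(off))) {
      rr <- r + off[k, 1L]; cc <- c + off[k, 2L]
      if (rr < 1 || rr > H || cc < 1 || cc > W || mask[rr, cc] == 0L) {
        keep <- FALSE
        break
      }
    }
    if (keep) out[r, c] <- 1L
  }
  out
}

oracle_dilate <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  off <- se$offsets
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    for (k in seq_len(nrow(off))) {
      rr <- r - off[k, 1L]; cc <- c - off[k, 2L]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc] == 1L) {
        out[r, c] <- 1L
        break
      }
    }
  }
  out
}

oracle_open <- function(mask, se) oracle_dilate(oracle_erode(mask, se), se)
oracle_close <- function(mask, se) oracle_erode(oracle_dilate(mask, se), se)

# BFS flood-fill labeling; returns label matrix with labels in raster-scan
# (row-major) order of first pixel
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  nb <- if (connectivity == 8) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  }
  lab <- matrix(0L, H, W)
  next_lab <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {      # row-major scan
    if (mask[r, c] == 1L && lab[r, c] == 0L) {
      next_lab <- next_lab + 1L
      queue <- list(c(r, c))
      lab[r, c] <- next_lab
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (k in seq_len(nrow(nb))) {
          rr <- p[1L] + nb[k, 1L]; cc <- p[2L] + nb[k, 2L]
          if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
              mask[rr, cc] == 1L && lab[rr, cc] == 0L) {
            lab[rr, cc] <- next_lab
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# exhaustive maximum-cardinality matching of detections to ground truth
# within a radius (recursion over detections)
oracle_max_matching <- function(det, gt, radius) {
  nd <- nrow(det); ng <- nrow(gt)
  if (nd == 0L || ng == 0L) return(0L)
  dmat <- sqrt(outer(det$row, gt$row, "-")^2 + outer(det$col, gt$col, "-")^2)
  best <- 0L
  recurse <- function(i, used, tp) {
    if (tp + (nd - i + 1L) <= best) return()
    if (i > nd) {
      if (tp > best) best <<- tp
      return()
    }
    for (j in seq_len(ng)) {
      if (!used[j] && dmat[i, j] <= radius) {
        used[j] <- TRUE
        recurse(i + 1L, used, tp + 1L)
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, tp)
  }
  recurse(1L, logical(ng), 0L)
  best
}

disk_mask <- function(H, W, cy, cx, r) {
  m <- matrix(0L, H, W)
  m[outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+") <= r^2] <- 1L
  m
}

add_disk <- function(mask, cy, cx, r) {
  matrix(as.integer(mask | disk_mask(nrow(mask), ncol(mask), cy, cx, r)),
         nrow(mask), ncol(mask))
}

random_mask <- function(H, W, p = 0.4) {
  matrix(rbinom(H * W, 1L, p), H, W)
}

# independent rerun of the iterative counting loop built only from oracle
# primitives; returns the fragment count
oracle_count <- function(mask, th = 13, connectivity = 8) {
  se <- make_se("diamond", 2)
  count <- 0L
  ig <- mask
  repeat {
    lab <- oracle_label(ig, connectivity)
    n <- max(lab)
    if (n == 0L) break
    small <- integer()
    for (k in seq_len(n)) {
      area <- sum(lab == k)
      if (sqrt(4 * area / pi) < th) small <- c(small, k)
    }
    count <- count + length(small)
    ig[lab %in% small] <- 0L
    if (length(small) == n) break
    ig <- oracle_erode(ig, se)
  }
  count
}
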