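# Independent brute-force oracles. These deliberately share no code with the
# package implementations: pairs, runs and zones are enumerated voxel by
# voxel; AUC and Youden come from exhaustive pair / threshold enumeration.

# all 13 direction offsets, as used by the package (fixed convention)
oracle_offsets <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one of each +/- pair (first nonzero component positive)
  keep <- apply(offs, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  unname(offs[keep, , drop = FALSE])
}

# symmetric merged GLCM by enumerating every voxel pair at every offset
oracle_glcm <- function(levels, ng, offsets = oracle_offsets()) {
  d <- dim(levels)
  m <- matrix(0, ng, ng)
  idx <- arrayInd(which(levels > 0), d)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    for (k in seq_len(nrow(offsets))) {
      q <- p + offsets[k, ]
      if (any(q < 1) || any(q > d)) next
      lq <- levels[q[1], q[2], q[3]]
      if (lq == 0) next
      lp <- levels[p[1], p[2], p[3]]
      m[lp, lq] <- m[lp, lq] + 1
      m[lq, lp] <- m[lq, lp] + 1
    }
  }
  m
}

# GLRLM by walking every line in every direction and measuring maximal runs
oracle_glrlm <- function(levels, ng, offsets = oracle_offsets()) {
  d <- dim(levels)
  runs <- list()
  for (k in seq_len(nrow(offsets))) {
    off <- offsets[k, ]
    all_idx <- arrayInd(seq_along(levels), d)
    # starts: voxels whose predecessor is outside the grid
    pred <- sweep(all_idx, 2, off, `-`)
    is_start <- pred[, 1] < 1 | pred[, 1] > d[1] | pred[, 2] < 1 |
      pred[, 2] > d[2] | pred[, 3] < 1 | pred[, 3] > d[3]
    for (s in which(is_start)) {
      p <- all_idx[s, ]
      cur_lev <- 0L; cur_len <- 0L
      while (all(p >= 1) && all(p <= d)) {
        lv <- levels[p[1], p[2], p[3]]
        if (lv == cur_lev && lv > 0L) {
          cur_len <- cur_len + 1L
        } else {
          if (cur_lev > 0L) runs[[length(runs) + 1L]] <- c(cur_lev, cur_len)
          cur_lev <- lv; cur_len <- 1L
        }
        p <- p + off
      }
      if (cur_lev > 0L) runs[[length(runs) + 1L]] <- c(cur_lev, cur_len)
    }
  }
  rr <- do.call(rbind, runs)
  nr <- max(rr[, 2])
  m <- matrix(0, ng, nr)
  for (i in seq_len(nrow(rr))) m[rr[i, 1], rr[i, 2]] <- m[rr[i, 1], rr[i, 2]] + 1
  m
}

# GLSZM by naive region growing over 26-connected equal-level zones
oracle_glszm <- function(levels, ng) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (v in which(levels > 0)) {
    if (seen[v]) next
    p0 <- arrayInd(v, d)
    lv <- levels[v]
    stack <- list(as.integer(p0))
    seen[v] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        ql <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (!seen[ql] && levels[ql] == lv) {
          seen[ql] <- TRUE
          stack[[length(stack) + 1L]] <- as.integer(q)
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lv, size)
  }
  zz <- do.call(rbind, zones)
  ns <- max(zz[, 2])
  m <- matrix(0, ng, ns)
  for (i in seq_len(nrow(zz))) m[zz[i, 1], zz[i, 2]] <- m[zz[i, 1], zz[i, 2]] + 1
  m
}

# AUC as the fraction of concordant (pos, neg) pairs, ties counting 1/2
oracle_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]; neg <- scores[y01 == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# maximal Youden J over every candidate threshold (score >= t => positive)
oracle_max_youden <- function(scores, y01) {
  cand <- c(sort(unique(scores)), Inf)
  best <- -Inf
  for (t in cand) {
    sens <- sum(scores >= t & y01 == 1) / sum(y01 == 1)
    spec <- sum(scores < t & y01 == 0) / sum(y01 == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}
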