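# Independent oracles used across the suite.

# Exhaustive Otsu: scan every candidate threshold, maximise between-class
# variance directly.
naive_otsu <- function(x) {
  x <- as.numeric(x)
  cand <- sort(unique(x))
  best <- -Inf; best_t <- NA_real_
  for (t in cand[-length(cand)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

# Brute-force largest centred odd cube inside a voxel mask.
naive_max_cube <- function(mask, centre) {
  d <- dim(mask)
  hmax <- min(c(centre, d - 1L - centre))
  best <- 0L
  for (h in 0L:hmax) {
    blk <- mask[(centre[1L] - h):(centre[1L] + h) + 1L,
                (centre[2L] - h):(centre[2L] + h) + 1L,
                (centre[3L] - h):(centre[3L] + h) + 1L]
    if (any(!blk)) break
    best <- h
  }
  2L * best + 1L
}

# Euler characteristic oracle: scikit-image's integral-geometry Euler number
# under the 26/6 convention (independent implementation, called through the
# system python).
python_euler <- function(vol) {
  d <- dim(vol)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(c(paste(d, collapse = " "),
               paste(as.integer(vol), collapse = " ")), f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import sys, numpy as np; from skimage.measure import euler_number\n",
    "lines = open(sys.argv[1]).read().split('\\n')\n",
    "d = [int(v) for v in lines[0].split()]\n",
    "a = np.array([int(v) for v in lines[1].split()], dtype=bool)\n",
    "a = a.reshape(d, order='F')\n",
    "print(euler_number(a, connectivity=3))")), f), stdout = TRUE)
  as.numeric(out[length(out)])
}

has_python_skimage <- function() {
  suppressWarnings(
    identical(tryCatch(system2("python", c("-c", "'import skimage'"),
                               stdout = FALSE, stderr = FALSE),
                       error = function(e) 1L), 0L))
}

# Exhaustive ER Mk likelihood: sum over every internal-node state assignment.
naive_mk_er_loglik <- function(tree, states, rate) {
  lev <- sort(unique(states))
  k <- length(lev)
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  idx <- integer(N)
  idx[seq_len(ntip)] <- match(states[tree$tip.label], lev)
  pmat <- function(t) {
    e <- exp(-k * rate * t)
    m <- matrix((1 - e) / k, k, k)
    diag(m) <- 1 / k + (k - 1) * e / k
    m
  }
  internals <- (ntip + 1L):N
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    idx[internals] <- combos[r, ]
    pr <- 1 / k  # uniform root prior
    for (e in seq_len(nrow(tree$edge))) {
      P <- pmat(tree$edge.length[e])
      pr <- pr * P[idx[tree$edge[e, 1L]], idx[tree$edge[e, 2L]]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Brute-force minimum number of state changes (uniform-cost parsimony) by
# enumerating all internal assignments.
naive_parsimony_steps <- function(tree, states) {
  lev <- sort(unique(states))
  k <- length(lev)
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  idx <- integer(N)
  idx[seq_len(ntip)] <- match(states[tree$tip.label], lev)
  internals <- (ntip + 1L):N
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    idx[internals] <- combos[r, ]
    ch <- sum(idx[tree$edge[, 1L]] != idx[tree$edge[, 2L]])
    if (ch < best) best <- ch
  }
  best
}

# 90-degree rotation of a 3-D array about the given axis.
rot90_3d <- function(a, axis) {
  d <- dim(a)
  if (axis == 1L) {
    b <- aperm(a, c(1L, 3L, 2L))
    idx <- lapply(dim(b), seq_len); idx[[3L]] <- rev(idx[[3L]])
  } else if (axis == 2L) {
    b <- aperm(a, c(3L, 2L, 1L))
    idx <- lapply(dim(b), seq_len); idx[[3L]] <- rev(idx[[3L]])
  } else {
    b <- aperm(a, c(2L, 1L, 3L))
    idx <- lapply(dim(b), seq_len); idx[[2L]] <- rev(idx[[2L]])
  }
  do.call(`[`, c(list(b), idx, list(drop = FALSE)))
}
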