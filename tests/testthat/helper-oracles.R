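# Independently coded brute-force oracles. These deliberately use naive
# per-pixel double loops and share no code with the package internals.

# edge-replicated pixel fetch
.at <- function(x, r, c) {
  r <- min(max(r, 1L), nrow(x)); c <- min(max(c, 1L), ncol(x))
  x[r, c]
}

# one-step / multi-step eight-neighbour diffusion, per-pixel loops
oracleDiffuse <- function(x, psi, kappa, iterations) {
  dirs <- list(c(-1, 0), c(1, 0), c(0, 1), c(0, -1),
               c(-1, 1), c(-1, -1), c(1, 1), c(1, -1))
  for (it in seq_len(iterations)) {
    out <- x
    for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
      s <- 0
      for (d in dirs) {
        g <- .at(x, r + d[1], c + d[2]) - x[r, c]
        s <- s + g * (1 / (1 + (g / kappa)^2))
      }
      out[r, c] <- x[r, c] + psi * s
    }
    x <- out
  }
  x
}

# neighbour-minus-centre for one direction, per-pixel loop
oracleDirGrad <- function(x, dr, dc) {
  out <- x
  for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x)))
    out[r, c] <- .at(x, r + dr, c + dc) - x[r, c]
  out
}

# isodata recomputing class means from the full histogram at every step
oracleThreshold <- function(v, t0 = 15, tol = 0.5, maxIter = 100) {
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(list(threshold = lo, iterations = 1L))
  counts <- table(v)
  vals <- as.numeric(names(counts))
  n <- as.numeric(counts)
  t <- if (t0 >= lo && t0 <= hi) t0 else (lo + hi) / 2
  it <- 0L
  repeat {
    it <- it + 1L
    hiSel <- vals > t
    m1 <- if (any(hiSel)) sum(vals[hiSel] * n[hiSel]) / sum(n[hiSel]) else t
    m2 <- if (any(!hiSel)) sum(vals[!hiSel] * n[!hiSel]) / sum(n[!hiSel]) else t
    tn <- (m1 + m2) / 2
    d <- abs(tn - t); t <- tn
    if (d < tol || it >= maxIter) break
  }
  list(threshold = t, iterations = it)
}

# binary erosion/dilation by set definition, per-pixel loops.
# Erosion: out-of-image is foreground; dilation (reflected hit):
# out-of-image is background.
oracleErode <- function(m, off) {
  out <- m
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    ok <- TRUE
    for (i in seq_len(nrow(off))) {
      rr <- r + off[i, 1]; cc <- c + off[i, 2]
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) && !m[rr, cc]) {
        ok <- FALSE; break
      }
    }
    out[r, c] <- ok
  }
  out
}

oracleDilate <- function(m, off) {
  out <- m
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    hit <- FALSE
    for (i in seq_len(nrow(off))) {
      rr <- r - off[i, 1]; cc <- c - off[i, 2]
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) && m[rr, cc]) {
        hit <- TRUE; break
      }
    }
    out[r, c] <- hit
  }
  out
}

# greyscale min/max filters with +Inf/-Inf outside
oracleErodeGrey <- function(x, off) {
  out <- x
  for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
    v <- Inf
    for (i in seq_len(nrow(off))) {
      rr <- r + off[i, 1]; cc <- c + off[i, 2]
      if (rr >= 1 && rr <= nrow(x) && cc >= 1 && cc <= ncol(x))
        v <- min(v, x[rr, cc])
    }
    out[r, c] <- v
  }
  out
}

# flood fill from border-touching foreground, 4-connectivity
oracleClearBorder <- function(m) {
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  queue <- which(m & (row(m) %in% c(1, H) | col(m) %in% c(1, W)))
  seen[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
          m[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        queue <- c(queue, (cc - 1) * H + rr)
      }
    }
  }
  m & !seen
}

# BFS component labelling
oracleLabel <- function(m, connectivity = 8) {
  H <- nrow(m); W <- ncol(m)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (p in which(m)) {
    if (lab[p] > 0L) next
    nxt <- nxt + 1L
    queue <- p; lab[p] <- nxt
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1) %% H + 1; c <- (q - 1) %/% H + 1
      for (d in offs) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, (cc - 1) * H + rr)
        }
      }
    }
  }
  lab
}

seFootprintOffsets <- function(s) {
  idx <- which(s@footprint, arr.ind = TRUE)
  cbind(idx[, 1] - s@origin[1], idx[, 2] - s@origin[2])
}

randomMask <- function(H, W, p = 0.5) matrix(stats::runif(H * W) < p, H, W)

# small phantom used by unit tests that only need plausible structure
smallPhantom <- function(seed = 1, ...) {
  args <- list(height = 128, width = 128, odCenter = c(64, 85),
               odRadius = 10, nRoots = 4, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  generatePhantom(do.call(phantomSpec, args))
}
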