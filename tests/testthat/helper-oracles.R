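# Brute-force oracles, written independently of the implementation: plain R
# loops and set algebra, no shared helpers with the package internals.

randomMask <- function(h, w, p = 0.4) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# Flood-fill component labelling.
oracleLabel <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        ni <- p[1] + nb[k, 1]; nj <- p[2] + nb[k, 2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] == 1 && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

oracleRemoveSmall <- function(mask, minSize, connectivity = 8) {
  lab <- oracleLabel(mask, connectivity)
  out <- mask * 0L
  if (max(lab) == 0) return(out)
  for (z in seq_len(max(lab)))
    if (sum(lab == z) >= minSize) out[lab == z] <- 1L
  out
}

oracleDiscOffsets <- function(radius) {
  off <- NULL
  r <- floor(radius)
  for (dy in -r:r) for (dx in -r:r)
    if (dy^2 + dx^2 <= radius^2) off <- rbind(off, c(dy, dx))
  off
}

# Closing = dilation then erosion over an implicit background-padded plane.
oracleClose <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  off <- oracleDiscOffsets(radius)
  at <- function(m, i, j) {
    if (i < 1 || i > nrow(m) || j < 1 || j > ncol(m)) 0L else m[i, j]
  }
  r <- ceiling(radius)
  dil <- matrix(0L, h + 2 * r, w + 2 * r)
  for (j in seq_len(ncol(dil))) for (i in seq_len(nrow(dil))) {
    v <- 0L
    for (k in seq_len(nrow(off)))
      if (at(mask, i - r + off[k, 1], j - r + off[k, 2]) == 1L) { v <- 1L; break }
    dil[i, j] <- v
  }
  out <- matrix(0L, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    v <- 1L
    for (k in seq_len(nrow(off)))
      if (at(dil, i + r + off[k, 1], j + r + off[k, 2]) == 0L) { v <- 0L; break }
    out[i, j] <- v
  }
  out
}

oracleMaxFilter <- function(img, size) {
  h <- nrow(img); w <- ncol(img)
  lo <- -((size - 1) %/% 2); hi <- lo + size - 1
  out <- img
  for (j in seq_len(w)) for (i in seq_len(h)) {
    ii <- max(1, i + lo):min(h, i + hi)
    jj <- max(1, j + lo):min(w, j + hi)
    out[i, j] <- max(img[ii, jj])
  }
  out
}

# Distance-minus-one convention: white pixels carry (min distance to a black
# pixel) - 1; black pixels 0.
oracleEdt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  blacks <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1) {
      d <- sqrt((blacks[, 1] - i)^2 + (blacks[, 2] - j)^2)
      out[i, j] <- min(d) - 1
    }
  }
  out
}

oracleEntropy <- function(mask, radius) {
  off <- oracleDiscOffsets(radius)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    vals <- c()
    for (k in seq_len(nrow(off))) {
      ni <- i + off[k, 1]; nj <- j + off[k, 2]
      if (ni >= 1 && ni <= h && nj >= 1 && nj <= w)
        vals <- c(vals, mask[ni, nj])
    }
    p <- table(vals) / length(vals)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

# Exhaustive between-class-variance scan over midpoints of consecutive
# distinct values; lowest threshold on ties.
oracleOtsu <- function(img) {
  v <- sort(unique(as.vector(img)))
  cand <- (v[-length(v)] + v[-1]) / 2
  best <- -Inf; bestT <- NA
  for (t in cand) {
    lo <- as.vector(img)[img <= t]; hi <- as.vector(img)[img > t]
    bc <- length(lo) * length(hi) *
      (mean(lo) - mean(hi))^2 / length(img)^2
    if (bc > best + 1e-15) { best <- bc; bestT <- t }
  }
  bestT
}

oraclePixelScores <- function(i, t) {
  S <- length(i)
  mP <- 0; mN <- 0
  for (k in seq_len(S)) {
    if (i[k] == 1 && t[k] == 0) mP <- mP + 1
    if (t[k] == 1 && i[k] == 0) mN <- mN + 1
  }
  c(mP = mP / S, mN = mN / S, m = (mP + mN) / S)
}

# Per-zone enumeration of F_A and F_G.
oracleZoneScores <- function(i, t, va = 0.8, rc = 0.5, connectivity = 8) {
  li <- oracleLabel(i, connectivity); lt <- oracleLabel(t, connectivity)
  fa <- NA_real_; fg <- NA_real_
  if (max(li) > 0) {
    ok <- 0
    for (z in seq_len(max(li))) {
      sel <- li == z
      if (sum(sel & t == 1) / sum(sel) >= va) ok <- ok + 1
    }
    fa <- ok / max(li)
  }
  if (max(lt) > 0) {
    ok <- 0
    for (z in seq_len(max(lt))) {
      sel <- lt == z
      if (sum(sel & i == 1) / sum(sel) >= rc) ok <- ok + 1
    }
    fg <- ok / max(lt)
  }
  c(fa = fa, fg = fg)
}

# Filled disc mask helper for fixtures.
discMask <- function(h, w, ci, cj, r) {
  m <- matrix(0L, h, w)
  for (j in seq_len(w)) for (i in seq_len(h))
    if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- 1L
  m
}
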