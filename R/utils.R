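# Internal helpers shared across modules.

# Vectorized bilinear interpolation of matrix `m` at fractional 1-based
# (row, col) coordinates. Coordinates must lie inside [1, nrow] x [1, ncol].
.bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  if (any(row < 1 | row > nr | col < 1 | col > nc))
    stop("interpolation coordinates outside image bounds")
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# Centroid (row, col) of a logical mask; NULL for an empty mask.
.maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(mean(idx[, 1L]), mean(idx[, 2L]))
}

# Squared distance (mm^2) of every voxel centre of an nr x nc grid from
# `center` = c(row, col) in 1-based voxel coordinates.
.distSq <- function(nr, nc, center, spacing) {
  dr <- (seq_len(nr) - center[1L]) * spacing
  dc <- (seq_len(nc) - center[2L]) * spacing
  outer(dr^2, dc^2, `+`)
}

# Centroid of the phantom body disk (everything clearly denser than air).
.bodyCentroid <- function(slice2d, airThresholdHU = -400) {
  ctr <- .maskCentroid(slice2d > airThresholdHU)
  if (is.null(ctr)) c((nrow(slice2d) + 1) / 2, (ncol(slice2d) + 1) / 2) else ctr
}

# Largest connected component of a logical matrix under 8-connectivity.
# Iterative flood fill (no recursion) over the queue of seed pixels.
.largestComponent <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      rr <- r + off$dr; cc <- c + off$dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- lab
        queue <- c(queue, nb)
      }
    }
  }
  if (lab == 0L) return(mask)  # empty mask unchanged
  sizes <- tabulate(labels[labels > 0L], nbins = lab)
  labels == which.max(sizes)
}

# stats::sd returns NA for length-1 input; metrics report 0 spread instead.
.sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
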