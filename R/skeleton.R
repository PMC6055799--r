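# Topology-preserving 2D thinning (Zhang & Suen's parallel algorithm).
# Both subiterations are applied in parallel over the whole image, so the
# result is deterministic and independent of any pixel visiting order.

#' Thin a binary mask to a 1-pixel-wide skeleton
#'
#' @param mask binary matrix.
#' @return 0/1 integer matrix, a subset of the input (anti-extensive).
#' @export
thin_mask <- function(mask) {
  m <- check_mask(mask)
  H <- nrow(m); W <- ncol(m)
  if (sum(m) == 0L) return(m)
  shift <- function(p, dr, dc)
    p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- matrix(0L, H + 2L, W + 2L)
      p[2:(H + 1L), 2:(W + 1L)] <- m
      P2 <- shift(p, -1L, 0L); P3 <- shift(p, -1L, 1L)
      P4 <- shift(p, 0L, 1L);  P5 <- shift(p, 1L, 1L)
      P6 <- shift(p, 1L, 0L);  P7 <- shift(p, 1L, -1L)
      P8 <- shift(p, 0L, -1L); P9 <- shift(p, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (sub == 1L) {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  condense_skeleton(m)
}

# Zhang-Suen can leave 2x2 blocks (at junctions and on thick diagonals).
# Remove pixels of such blocks when deletion preserves local topology
# (one 8-connected foreground component in the ring, at least one
# background 4-neighbour). Raster order makes the result deterministic.
condense_skeleton <- function(m) {
  H <- nrow(m); W <- ncol(m)
  # 8-adjacency among the ring positions 1..8 =
  # (NW, W, SW, N, S, NE, E, SE) in column-major order of the 3x3 patch
  ring_off <- cbind(dr = c(-1, 0, 1, -1, 1, -1, 0, 1),
                    dc = c(-1, -1, -1, 0, 0, 1, 1, 1))
  adj <- which(outer(seq_len(8), seq_len(8), Vectorize(function(i, j)
    i < j && max(abs(ring_off[i, ] - ring_off[j, ])) <= 1)), arr.ind = TRUE)
  ring_comp <- function(fg) {
    lab <- seq_len(8); lab[!fg] <- 0L
    repeat {
      ch <- FALSE
      for (k in seq_len(nrow(adj))) {
        i <- adj[k, 1]; j <- adj[k, 2]
        if (fg[i] && fg[j] && lab[i] != lab[j]) {
          l <- min(lab[i], lab[j]); lab[i] <- l; lab[j] <- l; ch <- TRUE
        }
      }
      if (!ch) break
    }
    length(unique(lab[fg]))
  }
  repeat {
    blk <- m[-H, -W] & m[-1, -W] & m[-H, -1] & m[-1, -1]
    if (!any(blk)) break
    mem <- matrix(FALSE, H, W)
    mem[-H, -W] <- mem[-H, -W] | blk
    mem[-1, -W] <- mem[-1, -W] | blk
    mem[-H, -1] <- mem[-H, -1] | blk
    mem[-1, -1] <- mem[-1, -1] | blk
    cand <- which(mem & m == 1L)
    changed <- FALSE
    for (id in cand) {
      if (m[id] == 0L) next
      r <- (id - 1L) %% H + 1L; c <- (id - 1L) %/% H + 1L
      if (r == 1L || r == H || c == 1L || c == W) next
      patch <- m[(r - 1):(r + 1), (c - 1):(c + 1)]
      fg <- as.logical(patch[-5])
      n <- sum(fg)
      if (n < 2L || n > 6L) next
      if (!(patch[1, 2] == 0L || patch[2, 1] == 0L ||
            patch[2, 3] == 0L || patch[3, 2] == 0L)) next
      if (ring_comp(fg) == 1L) { m[id] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}
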