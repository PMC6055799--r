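#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom grDevices hsv col2rgb
NULL

# Run code with a private, restored RNG state so that library calls never
# perturb the caller's stream and a NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_ernet <- function(...) stop(..., call. = FALSE)

# derive a stream-specific seed without integer overflow
derive_seed <- function(seed, k) (as.numeric(seed) * 131 + k) %% 2147483647

check_mask <- function(m, name = "mask") {
  if (!is.matrix(m)) stop_ernet(name, " must be a matrix")
  storage.mode(m) <- "integer"
  m[m != 0L] <- 1L
  m
}

# mirror-pad a matrix by k pixels on every side
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(k, nr))), seq_len(nr), nr + 1 - seq_len(min(k, nr)))
  ci <- c(rev(seq_len(min(k, nc))), seq_len(nc), nc + 1 - seq_len(min(k, nc)))
  m[ri, ci, drop = FALSE]
}

# Gaussian smoothing with reflective boundaries; sigma = 0 is the identity.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  pad <- max(1L, ceiling(3 * sigma))
  p <- pad_reflect(m, pad)
  s <- as.matrix(EBImage::gblur(p, sigma = sigma))
  s[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m)), drop = FALSE]
}

# 3x3 neighbour count of a binary matrix (8-connectivity), zeros outside.
neighbour_count8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  acc
}

# Crossing number: count of 0->1 transitions in the circular 8-neighbour
# ring of each pixel. 1 = line end, 2 = line interior, >= 3 = branch point.
# A plain neighbour count misfires on diagonal staircase corners.
ring_transitions <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  P2 <- sh(-1L, 0L); P3 <- sh(-1L, 1L); P4 <- sh(0L, 1L); P5 <- sh(1L, 1L)
  P6 <- sh(1L, 0L); P7 <- sh(1L, -1L); P8 <- sh(0L, -1L); P9 <- sh(-1L, -1L)
  (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
  (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
  (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
  (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
}

# 8-connected labelling of a binary matrix (EBImage::bwlabel is 4-connected).
label8 <- function(m) {
  m <- check_mask(m)
  idx <- which(m != 0L)
  out <- matrix(0L, nrow(m), ncol(m))
  if (length(idx) == 0L) return(out)
  nr <- nrow(m); nc <- ncol(m)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  edges <- list()
  k <- 1L
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1L]; c2 <- c + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- integer(length(idx)); nb[!ok] <- 0L
    nb[ok] <- pos[(c2[ok] - 1L) * nr + r2[ok]]
    sel <- which(nb > 0L)
    if (length(sel)) { edges[[k]] <- cbind(sel, nb[sel]); k <- k + 1L }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(list(cbind(seq_along(idx), seq_along(idx))), edges)),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

# disc structuring element of given pixel radius
disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
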