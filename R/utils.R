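#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout the package:
#   images are [row, col(, channel)] arrays; pixel centers sit at 0-based
#   integer coordinates with x = col - 1 (rightward), y = row - 1 (downward),
#   origin at the top-left pixel center.

#' Round half away from zero
#'
#' Display rounding for printed percentages: .5 always rounds up in
#' magnitude (unlike [round()], which rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Rasterize a binary disk kernel
#'
#' Center-in-circle rasterization: the kernel entry is 1 iff its center
#' lies within `radius_px` of the kernel center.
#'
#' @param radius_px integer radius in pixels, >= 0.
#' @return a (2r+1) x (2r+1) 0/1 matrix with attribute `pixel_count`.
#' @export
disk_kernel <- function(radius_px) {
  stopifnot(length(radius_px) == 1, radius_px >= 0)
  r <- as.integer(round(radius_px))
  s <- 2L * r + 1L
  d2 <- (row(matrix(0, s, s)) - r - 1L)^2 + (col(matrix(0, s, s)) - r - 1L)^2
  k <- matrix(0, s, s)
  k[d2 <= r^2] <- 1
  attr(k, "pixel_count") <- sum(k)
  k
}

#' Block-mean downsampling of a matrix
#'
#' Aggregates `block` x `block` pixel blocks by their mean; partial blocks
#' at the right/bottom edge are averaged over the pixels they contain.
#'
#' @param m numeric matrix.
#' @param block integer block side length, >= 1.
#' @return the downsampled matrix.
#' @export
block_mean <- function(m, block) {
  stopifnot(is.matrix(m), block >= 1)
  block <- as.integer(block)
  if (block == 1L) return(m)
  h <- nrow(m); w <- ncol(m)
  oh <- ceiling(h / block); ow <- ceiling(w / block)
  ri <- rep(seq_len(oh), each = block)[seq_len(h)]
  ci <- rep(seq_len(ow), each = block)[seq_len(w)]
  # sum into blocks, then divide by per-block pixel counts
  sums <- rowsum(m, ri)             # oh x w
  sums <- t(rowsum(t(sums), ci))    # oh x ow
  cnt <- tabulate(ri, oh) %o% tabulate(ci, ow)
  out <- sums / cnt
  dimnames(out) <- NULL
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label connected components with 8-connectivity
#'
#' Foreground pixels (non-zero) are grouped into components where pixels
#' touching edge- or corner-wise belong to the same object, the standard
#' convention for blob counting. Built on EBImage's 4-connected labeling
#' with a union-find merge across diagonal adjacencies.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbor label pairs (down-right and down-left)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Centroids of labeled components
#'
#' @param lab integer label matrix from [label_components()].
#' @return data.frame with columns `x`, `y` (0-based pixel coordinates of
#'   the component centroid) and `size` (pixel count), one row per label.
#' @export
component_centroids <- function(lab) {
  stopifnot(is.matrix(lab))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), size = integer(0)))
  }
  l <- lab[idx]
  ys <- (idx - 1L) %% nrow(lab)        # 0-based row
  xs <- (idx - 1L) %/% nrow(lab)       # 0-based col
  n <- tabulate(l)
  data.frame(
    x = as.vector(tapply(xs, l, mean)),
    y = as.vector(tapply(ys, l, mean)),
    size = n[n > 0L],
    row.names = NULL
  )
}

# Vectorized image sampling at continuous 0-based coordinates.
# Returns list(values, valid); out-of-frame samples are 0 with valid FALSE.
sample_image <- function(m, x, y, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  h <- nrow(m); w <- ncol(m)
  if (interpolation == "nearest") {
    xi <- round(x); yi <- round(y)
    valid <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
    v <- numeric(length(x))
    v[valid] <- m[cbind(yi[valid] + 1L, xi[valid] + 1L)]
    return(list(values = v, valid = valid))
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  valid <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  v <- numeric(length(x))
  if (any(valid)) {
    xv0 <- clamp(x0[valid], 0, w - 1); yv0 <- clamp(y0[valid], 0, h - 1)
    xv1 <- clamp(xv0 + 1, 0, w - 1);   yv1 <- clamp(yv0 + 1, 0, h - 1)
    fxa <- fx[valid]; fya <- fy[valid]
    v00 <- m[cbind(yv0 + 1L, xv0 + 1L)]
    v01 <- m[cbind(yv0 + 1L, xv1 + 1L)]
    v10 <- m[cbind(yv1 + 1L, xv0 + 1L)]
    v11 <- m[cbind(yv1 + 1L, xv1 + 1L)]
    v[valid] <- (1 - fya) * ((1 - fxa) * v00 + fxa * v01) +
      fya * ((1 - fxa) * v10 + fxa * v11)
  }
  list(values = v, valid = valid)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1000L
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
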