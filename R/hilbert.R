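# Hilbert space-filling-curve layout of chromosome-length signal vectors.
# Convention (fixed and documented): the grid origin is the lower-left cell
# (x = 0, y = 0); index 0 maps there and the first step is along +y, so an
# order-1 curve visits (0,0), (0,1), (1,1), (1,0). Published tools differ
# in rotation/reflection; any such variant is a relabelling of the same
# locality-preserving layout.

#' Hilbert-curve cell coordinates for linear indices
#'
#' @param order curve order `k`; the grid is `2^k x 2^k` and indices run
#'   `0 .. 4^k - 1`.
#' @param d integer vector of 0-based linear indices.
#' @return Integer matrix with columns `x`, `y` (0-based, origin lower
#'   left).
#' @export
hilbert_d2xy <- function(order, d) {
  if (order < 1 || order != floor(order)) stop("order must be a positive integer")
  n <- 2^order
  if (any(d < 0 | d >= n * n)) stop("index out of range for this order")
  t <- as.integer(d)
  x <- integer(length(d)); y <- integer(length(d))
  s <- 1L
  while (s < n) {
    rx <- bitwAnd(1L, t %/% 2L)
    ry <- bitwAnd(1L, bitwXor(t, rx))
    idx <- which(ry == 0L)
    if (length(idx)) {
      xi <- x[idx]; yi <- y[idx]
      f <- rx[idx] == 1L
      xi[f] <- s - 1L - xi[f]
      yi[f] <- s - 1L - yi[f]
      x[idx] <- yi                      # rotate quadrant
      y[idx] <- xi
    }
    x <- x + s * rx
    y <- y + s * ry
    t <- t %/% 4L
    s <- s * 2L
  }
  cbind(x = x, y = y)
}

#' Map a signal vector onto a Hilbert-curve image
#'
#' Lays a chromosome-length vector of binned signal onto a `2^k x 2^k`
#' grid along the Hilbert curve, which keeps genomically close bins close
#' in the image. A vector longer than `4^k` is mean-pooled into `4^k`
#' contiguous groups (signal is density-like after normalization, so mean
#' — not sum — pooling); a shorter vector is padded with zeros and the
#' padded cells flagged.
#'
#' @param values numeric vector of binned signal along one chromosome.
#' @param order curve order `k >= 1`.
#' @return An object of class `HilbertImage`: `grid` (matrix indexed
#'   `[x+1, y+1]`), `order`, `mapping` (data.frame index/x/y), `padded`
#'   (logical per cell) and `n_source`.
#' @export
hilbert_map <- function(values, order) {
  if (order < 1 || order != floor(order)) stop("order must be a positive integer (k >= 1)")
  L <- length(values)
  if (!L) stop("empty signal vector")
  n <- 4^order
  if (L >= n) {
    grp <- floor((seq_len(L) - 1) * n / L)
    cells <- as.numeric(rowsum(values, grp)[, 1]) / tabulate(grp + 1L, nbins = n)
    padded <- rep(FALSE, n)
  } else {
    cells <- c(values, rep(0, n - L))
    padded <- c(rep(FALSE, L), rep(TRUE, n - L))
  }
  xy <- hilbert_d2xy(order, 0:(n - 1))
  side <- 2^order
  grid <- matrix(NA_real_, side, side)
  grid[cbind(xy[, "x"] + 1, xy[, "y"] + 1)] <- cells
  structure(list(grid = grid, order = as.integer(order),
                 mapping = data.frame(index = 0:(n - 1),
                                      x = xy[, "x"], y = xy[, "y"]),
                 padded = padded, n_source = L),
            class = "HilbertImage")
}

#' @export
print.HilbertImage <- function(x, ...) {
  cat(sprintf("HilbertImage: order %d (%d x %d), %d source bins%s\n",
              x$order, nrow(x$grid), ncol(x$grid), x$n_source,
              if (any(x$padded)) sprintf(", %d padded cells", sum(x$padded)) else ""))
  invisible(x)
}

#' Plot a Hilbert image
#' @param x a [hilbert_map()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.HilbertImage <- function(x, ...) {
  side <- nrow(x$grid)
  image(seq_len(side) - 0.5, seq_len(side) - 0.5, x$grid,
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "", ylab = "", axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}
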