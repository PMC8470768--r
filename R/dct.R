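#' Orthonormal discrete cosine transform (type II)
#'
#' Computed through a zero-padded length-4n FFT, so full transforms of long
#' flattened layers stay O(n log n). The orthonormal scaling makes the
#' transform an isometry: truncating high-frequency coefficients gives the
#' least-squares reconstruction within the kept basis.
#'
#' @param x numeric vector.
#' @return numeric vector of DCT-II coefficients, zero frequency first.
#' @export
dct_1d <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(as.numeric(x))
  u <- numeric(4L * n)
  u[2L * seq_len(n)] <- x              # odd 0-based slots 1, 3, 5, ...
  c_k <- Re(stats::fft(u))[seq_len(n)]
  c_k * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
}

#' Inverse orthonormal DCT (type III)
#'
#' @param y coefficient vector as produced by [dct_1d()].
#' @return the reconstructed signal.
#' @export
idct_1d <- function(y) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(as.numeric(y))
  a <- y * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
  v <- numeric(4L * n)
  v[seq_len(n)] <- a
  Re(stats::fft(v))[2L * seq_len(n)]
}

#' 2-D orthonormal DCT of an activation map
#'
#' Separable: [dct_1d()] along columns, then along rows.
#'
#' @param m numeric matrix.
#' @param inverse apply the inverse transform instead.
#' @return matrix of the same shape.
#' @export
dct_2d <- function(m, inverse = FALSE) {
  m <- as.matrix(m)
  f <- if (inverse) idct_1d else dct_1d
  res <- m
  if (nrow(res) > 1L) res <- apply(res, 2L, f)
  res <- matrix(res, nrow(m), ncol(m))
  if (ncol(res) > 1L) res <- t(apply(res, 1L, f))
  matrix(res, nrow(m), ncol(m))
}

#' Zig-zag scan order of an h x w coefficient grid
#'
#' Anti-diagonal traversal from the zero-frequency corner (JPEG convention,
#' generalized to rectangles): diagonals of increasing total frequency
#' `i + j`, alternating direction, so low frequencies come first.
#'
#' @param h,w grid dimensions.
#' @return integer vector of column-major linear indices, length `h * w`.
#' @export
zigzag_order <- function(h, w) {
  ord <- integer(h * w)
  pos <- 0L
  for (s in 0:(h + w - 2L)) {
    i <- if (s %% 2L == 0L) seq(min(s, h - 1L), max(0L, s - w + 1L)) else
                            seq(max(0L, s - w + 1L), min(s, h - 1L))
    for (ii in i) {
      pos <- pos + 1L
      ord[pos] <- ii + 1L + (s - ii) * h
    }
  }
  ord
}

#' Keep the k lowest-frequency DCT coefficients of one channel
#'
#' @param map 2-D activation grid.
#' @param k number of coefficients to keep (`<=` grid size).
#' @return numeric vector of length `k`, zig-zag order from DC.
#' @export
dct_reduce_channel <- function(map, k) {
  map <- as.matrix(map)
  if (k > length(map)) stop("coefficient budget exceeds grid size")
  dct_2d(map)[zigzag_order(nrow(map), ncol(map))][seq_len(k)]
}

#' Per-channel (local) DCT reduction of an activation tensor
#'
#' Each channel keeps `channel_budget(D, budget_B)` low-frequency
#' coefficients; channel blocks are concatenated in channel order.
#'
#' @param tensor activation array `h x w x D`.
#' @param budget_B total descriptor budget (default 1000).
#' @return numeric descriptor of length `D * channel_budget(D, budget_B)`.
#' @export
dct_reduce_local <- function(tensor, budget_B = 1000L) {
  a <- as_tensor3(tensor)
  d <- dim(a)
  k <- channel_budget(d[3], budget_B)
  as.vector(vapply(seq_len(d[3]), function(ci) dct_reduce_channel(a[, , ci], k),
                   numeric(k)))
}

#' Global DCT reduction of an activation tensor
#'
#' The whole tensor is flattened channel-major ([flatten_tensor()]) into one
#' sequence, transformed by the 1-D orthonormal DCT, and the first `budget_B`
#' coefficients are kept.
#'
#' @param tensor activation array.
#' @param budget_B descriptor length (default 1000; must not exceed the
#'   flattened size).
#' @return numeric vector of length `budget_B`.
#' @export
gdct_reduce <- function(tensor, budget_B = 1000L) {
  v <- flatten_tensor(as_tensor3(tensor))
  if (length(v) < budget_B) stop("budget exceeds flattened layer size")
  dct_1d(v)[seq_len(budget_B)]
}
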