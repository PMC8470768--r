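# Independent brute-force oracles, written as literal definitions.
# These deliberately use naive loops rather than the package's vectorized or
# FFT-based code paths.

# 1-D orthonormal DCT-II by direct cosine summation
oracle_dct_1d <- function(x) {
  n <- length(x)
  sapply(0:(n - 1), function(k) {
    s <- sum(x * cos(pi * (2 * (0:(n - 1)) + 1) * k / (2 * n)))
    s * if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  })
}

# 2-D orthonormal DCT-II by direct double summation
oracle_dct_2d <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (p in 0:(h - 1)) for (q in 0:(w - 1)) {
    s <- 0
    for (i in 0:(h - 1)) for (j in 0:(w - 1)) {
      s <- s + m[i + 1, j + 1] *
        cos(pi * (2 * i + 1) * p / (2 * h)) * cos(pi * (2 * j + 1) * q / (2 * w))
    }
    out[p + 1, q + 1] <- s * (if (p == 0) sqrt(1 / h) else sqrt(2 / h)) *
      (if (q == 0) sqrt(1 / w) else sqrt(2 / w))
  }
  out
}

# per-pixel, per-neighbor uniform LBP histogram
oracle_lbp_hist <- function(map) {
  h <- nrow(map); w <- ncol(map)
  off <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
              c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  transitions <- function(bits) sum(bits != bits[c(2:8, 1)])
  uni <- which(sapply(0:255, function(cd) {
    transitions(as.integer(intToBits(cd))[1:8]) < 3
  })) - 1L
  hist <- numeric(59)
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    code <- 0
    for (n in 1:8) {
      if (map[i + off[[n]][1], j + off[[n]][2]] - map[i, j] >= 0) {
        code <- code + 2^(n - 1)
      }
    }
    b <- match(code, uni)
    hist[if (is.na(b)) 59 else b] <- hist[if (is.na(b)) 59 else b] + 1
  }
  hist
}

# literal triple-loop co-occurrence pooling
oracle_cooc <- function(a, r = 1, eps = 0) {
  d <- dim(a); h <- d[1]; w <- d[2]; D <- d[3]
  rho <- (a > mean(a)) * 1
  ct <- array(0, d)
  for (i in 1:h) for (j in 1:w) for (k in 1:D) {
    if (rho[i, j, k] == 0) next
    s <- 0
    for (kp in 1:D) {
      wt <- if (kp == k) eps else 1
      for (di in -r:r) for (dj in -r:r) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          s <- s + wt * a[ii, jj, kp] * rho[ii, jj, kp]
        }
      }
    }
    ct[i, j, k] <- s
  }
  apply(ct, 3, mean)
}

# counting definition of entropy pooling (255 equal-width bins on [0, 255])
oracle_gep <- function(a, n_bins = 255) {
  d <- dim(a)
  sapply(seq_len(d[3]), function(ci) {
    m <- a[, , ci]
    if (max(m) == min(m)) return(0)
    v <- (m - min(m)) / (max(m) - min(m)) * 255
    counts <- numeric(n_bins)
    for (x in v) {
      b <- min(floor(x / 255 * n_bins) + 1, n_bins)
      counts[b] <- counts[b] + 1
    }
    p <- counts / sum(counts)
    -sum(p[p > 0] * log(p[p > 0]))
  })
}

# literal counting definition of mean-thresholding pooling
oracle_gmtp <- function(a) {
  d <- dim(a)
  tg <- sum(a) / prod(d)
  sapply(seq_len(d[3]), function(ci) {
    cnt <- 0
    for (x in a[, , ci]) if (x < tg) cnt <- cnt + 1
    cnt / (d[1] * d[2])
  })
}

# rank-all-columns chi-square selection oracle (reuses the statistic under
# test only through its published value; ranking logic is independent)
oracle_chi_rank <- function(X, labels, k, n_bins = 10) {
  sc <- sapply(seq_len(ncol(X)), function(j) {
    chi_square_score(X[, j], labels, n_bins)$statistic
  })
  ord <- seq_len(ncol(X))[order(-sc, seq_len(ncol(X)))]
  ord[seq_len(k)]
}

# sliding-window valid+zero-padded convolution oracle for one conv node
oracle_conv <- function(img, W, b) {
  d <- dim(img); h <- d[1]; w <- d[2]; cin <- d[3]
  kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  p <- (kh - 1) %/% 2
  out <- array(0, c(h, w, cout))
  for (o in 1:cout) for (i in 1:h) for (j in 1:w) {
    s <- b[o]
    for (ki in 1:kh) for (kj in 1:kw) for (ci in 1:cin) {
      ii <- i + ki - 1 - p; jj <- j + kj - 1 - p
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        s <- s + img[ii, jj, ci] * W[ki, kj, ci, o]
      }
    }
    out[i, j, o] <- s
  }
  out
}

# shared expensive fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fixture_backbone <- function() fixture("bb", function() tiny_backbone(1L))

fixture_dataset <- function() {
  fixture("ds", function() gen_texture_dataset(texture_dataset_spec(seed = 101L)))
}
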