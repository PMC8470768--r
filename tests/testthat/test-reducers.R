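test_that("the reduction threshold is strict and the channel budget floors", {
  expect_true(needs_reduction(100352))
  expect_false(needs_reduction(4096))
  expect_false(needs_reduction(5000))                  # strictly "more than"
  expect_equal(channel_budget(100, 1000), 10L)
  expect_equal(channel_budget(512, 1000), 1L)          # floor
  expect_equal(channel_budget(2048, 1000), 1L)         # minimum-one clamp
  expect_equal(channel_budget(3, 1000), 333L)
})

test_that("PCA centers on the training mean and recovers exact subspaces", {
  # points on a 1-D line in 3-D: one component reconstructs exactly
  t_ <- seq(-2, 2, length.out = 10)
  X <- cbind(1 + 2 * t_, -t_, 0.5 + t_)
  fit <- pca_fit(X, 1)
  proj <- pca_apply(fit, X)
  rec <- proj %*% t(fit$rotation) + matrix(fit$center, 10, 3, byrow = TRUE)
  expect_lt(max(abs(rec - X)), 1e-10)
  expect_lt(max(abs(pca_apply(fit, colMeans(X)))), 1e-10)   # mean -> zero
  # seeded matrix against a covariance eigendecomposition oracle
  set.seed(12)
  Y <- matrix(rnorm(200), 20, 10)
  f2 <- pca_fit(Y, 3)
  ev <- eigen(stats::cov(Y), symmetric = TRUE)$vectors[, 1:3]
  P1 <- pca_apply(f2, Y)
  P2 <- sweep(Y, 2, colMeans(Y)) %*% ev
  for (j in 1:3) {
    expect_lt(min(max(abs(P1[, j] - P2[, j])), max(abs(P1[, j] + P2[, j]))), 1e-8)
  }
  # reconstruction error non-increasing in component count
  errs <- sapply(1:8, function(k) {
    fk <- pca_fit(Y, k)
    pk <- pca_apply(fk, Y)
    sum((sweep(Y, 2, fk$center) - pk %*% t(fk$rotation))^2)
  })
  expect_true(all(diff(errs) <= 1e-10))
  expect_warning(pca_fit(X, 5), "clipped")
})

test_that("chi-square statistic follows the contingency definition", {
  # engineered 2-bin x 2-class table: O = [[10,20],[20,10]], all E = 15,
  # so each bin contributes 25/15 + 25/15
  x <- c(rep(0, 30), rep(1, 30))
  y <- c(rep("A", 10), rep("B", 20), rep("A", 20), rep("B", 10))
  r <- chi_square_score(x, y, n_bins = 2)
  expect_equal(r$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(r$dof_c, 1L)
  expect_true(all(r$expected == 15))
  expect_equal(chi_square_score(rep(2, 20), rep(c("A", "B"), 10))$statistic, 0)
  # a feature identical to the label maximizes the statistic
  lab <- rep(c("A", "B", "C"), each = 10)
  best <- chi_square_score(as.integer(factor(lab)), lab, n_bins = 3)$statistic
  set.seed(4)
  for (i in 1:10) {
    r2 <- chi_square_score(rnorm(30), lab, n_bins = 3)$statistic
    expect_lte(r2, best + 1e-9)
  }
})

test_that("chi-square selection ranks columns like the exhaustive oracle", {
  lab <- rep(c("A", "B"), each = 15)
  X <- cbind(rnorm(30), as.integer(factor(lab)) + rnorm(30, sd = 0.01), rnorm(30))
  expect_equal(as.integer(chi_select(X, lab, 1)), 2L)
  expect_setequal(as.integer(chi_select(X, lab, 3)), 1:3)
  expect_error(chi_select(X, lab, 4), "more columns")
  for (s in 1:20) {
    set.seed(s)
    M <- matrix(rnorm(50 * 20), 50, 20)
    lb <- sample(c("A", "B", "C"), 50, replace = TRUE)
    expect_equal(as.integer(chi_select(M, lb, 5)), oracle_chi_rank(M, lb, 5))
  }
})

test_that("uniform LBP histograms match the per-pixel oracle and count 58 patterns", {
  n_uniform <- sum(sapply(0:255, function(cd) {
    b <- as.integer(intToBits(cd))[1:8]
    sum(b != b[c(2:8, 1)]) < 3
  }))
  expect_equal(n_uniform, 58L)
  # constant map: s(0) = 1 everywhere -> code 255, a single uniform bin
  h <- lbp_uniform_hist(matrix(4, 6, 6))
  expect_equal(sum(h), 16L)                            # interior pixel count
  expect_equal(sum(h > 0), 1L)
  expect_lte(which(h > 0), 58L)                        # 255 is uniform
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(runif(42, 0, 255), 6, 7)
    got <- lbp_uniform_hist(m)
    expect_equal(as.numeric(got), oracle_lbp_hist(m))
    expect_equal(sum(got), 4L * 5L)
  }
  expect_error(lbp_uniform_hist(matrix(0, 2, 5)), "too small")
})

test_that("LBP + chi-square reducer selects on training data only", {
  set.seed(3)
  tensors <- lapply(1:12, function(i) {
    array(runif(8 * 8 * 4) + (i > 6) * 0.3, c(8, 8, 4))
  })
  labels <- rep(c("A", "B"), each = 6)
  raw <- t(sapply(tensors, function(a) {
    unlist(lapply(1:4, function(ci) {
      m <- a[, , ci]
      m <- (m - min(m)) / (max(m) - min(m)) * 255
      oracle_lbp_hist(m)
    }))
  }))
  expect_equal(ncol(raw), 4L * 59L)
  fit <- lbpchi_fit(tensors, labels, budget_B = 20)
  expect_length(fit$selected, 20L)
  expect_equal(fit$selected, oracle_chi_rank(raw, labels, 20))
  expect_equal(lbpchi_apply(fit, tensors[[1]]), raw[1, fit$selected])
  # budget at or above the raw length is a no-op selection
  fit_all <- lbpchi_fit(tensors, labels, budget_B = 500)
  expect_equal(fit_all$selected, seq_len(236L))
})

test_that("co-occurrence pooling matches the brute-force window oracle", {
  expect_equal(cooc_pool(array(2, c(4, 4, 3))), rep(0, 3))   # strict threshold
  # one isolated supra-mean spike: CT value = eps * itself
  a <- array(0, c(7, 7, 2)); a[4, 4, 1] <- 10
  expect_equal(cooc_pool(a, radius_r = 1, epsilon = 0), c(0, 0))
  eps <- 0.01
  got <- cooc_pool(a, radius_r = 1, epsilon = eps)
  expect_equal(got[1], eps * 10 / 49, tolerance = 1e-12)
  expect_equal(got[2], 0)
  for (s in 1:20) {
    set.seed(s)
    t3 <- array(runif(5 * 5 * 3), c(5, 5, 3))
    expect_lt(max(abs(cooc_pool(t3, 1, 0) - oracle_cooc(t3, 1, 0))), 1e-6)
  }
  set.seed(500)
  t4 <- array(runif(6 * 6 * 2), c(6, 6, 2))
  expect_lt(max(abs(cooc_pool(t4, 2, 0.05) - oracle_cooc(t4, 2, 0.05))), 1e-6)
})

test_that("entropy pooling matches its histogram oracle and closed forms", {
  expect_equal(gep_pool(array(5, c(4, 4, 1))), 0)
  # every bin equally occupied -> ln(255)
  ch <- array(seq(0, 254.999, length.out = 255), c(255, 1, 1))
  expect_equal(gep_pool(ch), log(255), tolerance = 1e-6)
  for (s in 1:20) {
    set.seed(s)
    a <- array(runif(8 * 8 * 3, -2, 5), c(8, 8, 3))
    expect_lt(max(abs(gep_pool(a) - oracle_gep(a))), 1e-9)
  }
  # invariance to positive affine rescaling
  set.seed(6); a <- array(rnorm(100), c(10, 10, 1))
  expect_equal(gep_pool(a), gep_pool(3 * a + 7), tolerance = 1e-12)
  expect_true(all(gep_pool(a) <= log(255) + 1e-12))
})

test_that("mean-thresholding pooling matches its counting oracle exactly", {
  t1 <- array(c(rep(0, 4), rep(1, 4)), c(2, 2, 2))
  expect_equal(gmtp_pool(t1), c(1, 0))                 # Tg = 0.5
  expect_equal(gmtp_pool(array(3, c(3, 3, 4))), rep(0, 4))  # strict <
  for (s in 1:20) {
    set.seed(s)
    a <- array(runif(4 * 4 * 5), c(4, 4, 5))
    expect_identical(gmtp_pool(a), oracle_gmtp(a))
    expect_true(all(gmtp_pool(a) >= 0 & gmtp_pool(a) <= 1))
  }
  set.seed(60); a <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  expect_equal(gmtp_pool(a), gmtp_pool(0.1 * a + 2))   # affine invariance
})

test_that("reduce_layer dispatches on the flat-size rule with deterministic lengths", {
  set.seed(41)
  layer_big <- data.frame(layer_name = "big", depth_index = 1, channels_D = 24,
                          spatial_h = 16, spatial_w = 16, flat_size = 6144)
  tensors <- lapply(1:8, function(i) array(runif(16 * 16 * 24), c(16, 16, 24)))
  labels <- rep(c("A", "B"), 4)
  for (m in c("DCT", "gDCT", "GEP", "GMTP", "CoOC")) {
    spec <- reducer_spec(method = m)
    res <- reduce_layer(tensors, labels, layer_big, spec)
    want <- switch(m, DCT = 24 * 41, gDCT = 1000, 24)
    expect_equal(res$fit$out_length, want)
    expect_equal(dim(res$features), c(8L, want))
  }
  # a small final layer passes through RAW whatever the method
  layer_small <- data.frame(layer_name = "logits", depth_index = 2,
                            channels_D = 10, spatial_h = 1, spatial_w = 1,
                            flat_size = 10)
  vecs <- lapply(1:6, function(i) array(rnorm(10), c(1, 1, 10)))
  res <- reduce_layer(vecs, rep(c("A", "B"), 3), layer_small, reducer_spec("GMTP"))
  expect_equal(res$fit$method, "RAW")
  expect_equal(res$fit$out_length, 10L)
  expect_equal(res$features[1, ], as.vector(vecs[[1]]))
  # pooling on a large 1-D layer is a configuration error
  big1d <- lapply(1:6, function(i) array(rnorm(6000), c(1, 1, 6000)))
  expect_error(reducer_fit(big1d, rep(c("A", "B"), 3), "x", reducer_spec("GMTP")),
               "1-D layer")
})

test_that("fitted reducers are idempotent on the training fold", {
  set.seed(17)
  tensors <- lapply(1:10, function(i) array(runif(12 * 12 * 40), c(12, 12, 40)))
  labels <- rep(c("A", "B"), 5)
  layer <- data.frame(layer_name = "L", depth_index = 1, channels_D = 40,
                      spatial_h = 12, spatial_w = 12, flat_size = 5760)
  for (m in c("PCA", "CHI", "LBPCHI")) {
    spec <- reducer_spec(method = m, budget_B = 40)
    fit <- reducer_fit(tensors, labels, layer, spec)
    f1 <- reducer_apply(fit, tensors)
    f2 <- reducer_apply(fit, tensors)
    expect_identical(f1, f2)
    expect_equal(nrow(f1), 10L)
  }
})
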