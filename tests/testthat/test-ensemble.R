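# small seeded Gaussian-blob feature sets for unit tests
make_blobs <- function(n_per = 12, k = 3, d = 6, sep = 4, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(ci) {
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[ci, ], n_per, d, byrow = TRUE)
  }))
  list(X = X, y = factor(rep(paste0("c", seq_len(k)), each = n_per)))
}

test_that("SVM units separate blobs and score deterministically", {
  b <- make_blobs(k = 2, sep = 6, sd = 0.5, seed = 2)
  u <- train_unit(b$X, b$y)
  sc <- score_unit(u, b$X)
  expect_equal(colnames(sc), levels(b$y))
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-12)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(colnames(sc)[max.col(sc)], as.character(b$y))   # separable
  u2 <- train_unit(b$X, b$y)
  expect_identical(score_unit(u2, b$X), sc)                    # determinism
  expect_error(train_unit(b$X, rep("a", nrow(b$X))), "2 classes")
  expect_error(score_unit(u, b$X[, 1:3]), "match")
})

test_that("unit training accuracy agrees with an independent kernel machine", {
  skip_if_not_installed("kernlab")
  b <- make_blobs(n_per = 15, k = 3, d = 5, sep = 2, sd = 1, seed = 7)
  Xn <- b$X / sqrt(rowSums(b$X^2))
  u <- train_unit(b$X, b$y)
  pred_pkg <- colnames(score_unit(u, b$X))[max.col(score_unit(u, b$X))]
  ref <- kernlab::ksvm(Xn, b$y, type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = 0.1), C = 1000, scaled = FALSE)
  pred_ref <- as.character(kernlab::predict(ref, Xn))
  n_ok_pkg <- sum(pred_pkg == as.character(b$y))
  n_ok_ref <- sum(pred_ref == as.character(b$y))
  expect_lte(abs(n_ok_pkg - n_ok_ref), 1L)
})

test_that("sum-rule fusion is the normalized, permutation-invariant mean", {
  m1 <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("A", "B")))
  m2 <- matrix(c(0, 1), 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_identical(sum_rule_fuse(list(m1)), m1)                # identity
  expect_equal(sum_rule_fuse(list(m1, m2)),
               matrix(0.5, 1, 2, dimnames = list(NULL, c("A", "B"))))
  set.seed(9)
  mats <- lapply(1:4, function(i) {
    m <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
    m / rowSums(m)
  })
  f1 <- sum_rule_fuse(mats)
  f2 <- sum_rule_fuse(rev(mats))
  expect_equal(f1, f2)                                         # commutative
  expect_equal(sum_rule_fuse(mats[c(1, 1, 1)]), mats[[1]])     # idempotent
  lo <- Reduce(pmin, mats); hi <- Reduce(pmax, mats)
  expect_true(all(f1 >= lo - 1e-12 & f1 <= hi + 1e-12))        # bounded
  bad <- mats[[1]]; colnames(bad) <- c("A", "C", "B")
  expect_error(sum_rule_fuse(list(mats[[1]], bad)), "class order")
})

test_that("stratified folds are seeded, disjoint and balanced", {
  y <- rep(c("a", "b"), each = 50)
  f <- kfold_protocol(y, 5, seed = 3)
  expect_equal(as.vector(table(f)), rep(20L, 5))
  expect_identical(f, kfold_protocol(y, 5, seed = 3))
  expect_false(identical(f, kfold_protocol(y, 5, seed = 4)))
  # class proportions within one sample of global per fold
  y2 <- factor(rep(c("a", "b", "c"), times = c(21, 34, 45)))
  f2 <- kfold_protocol(y2, 5, seed = 1)
  tab <- table(y2, f2)
  for (cl in rownames(tab)) {
    expect_lte(max(tab[cl, ]) - min(tab[cl, ]), 1L)
  }
  expect_error(kfold_protocol(rep(c("a", "b"), c(3, 50)), 5), "at least k")
})

test_that("recipe parsing covers named ensembles and -2 variants", {
  r <- parse_recipe("DCT")
  expect_equal(r$methods, "DCT"); expect_false(r$drop_last_two)
  expect_equal(parse_recipe("g-DCT")$methods, "gDCT")
  r2 <- parse_recipe("(DCT+GMTP)-2")
  expect_equal(r2$methods, c("DCT", "GMTP"))
  expect_true(r2$drop_last_two)
  expect_equal(r2$independent_trainings, 2L)
  r3 <- parse_recipe("DCT+PCA+GMTP")
  expect_equal(r3$methods, c("DCT", "PCA", "GMTP"))
  expect_equal(parse_recipe("TunLayer-3")$tun_layer, 3L)
  expect_equal(parse_recipe("TunFusLayer")$tun_layer, 0L)
  expect_error(parse_recipe("FOO+BAR"), "unknown recipe")
})

test_that("-2 recipes drop the two deepest units and TunFusLayer composes", {
  bb <- tiny_backbone(3L, input_size = 16L)         # cheap: everything RAW
  set.seed(23)
  imgs <- lapply(1:12, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  labels <- factor(rep(c("A", "B"), 6))
  selected <- select_layers(bb$layers)
  tensors <- extract_layerset(bb, imgs, selected$layer_name)
  n_sel <- nrow(selected)
  units_full <- fit_ensemble(list(tensors), labels, parse_recipe("DCT"),
                             selected)
  units_m2 <- fit_ensemble(list(tensors), labels, parse_recipe("DCT-2"),
                           selected)
  expect_equal(length(units_m2), n_sel - 2L)
  expect_equal(vapply(units_m2, `[[`, character(1), "layer_name"),
               selected$layer_name[seq_len(n_sel - 2L)])
  # TunFusLayer equals fusing the four TunLayer-x unit matrices directly
  tfl <- fit_ensemble(list(tensors), labels, parse_recipe("TunFusLayer"),
                      selected)
  expect_equal(length(tfl), 4L)
  fused <- predict_ensemble(tfl, list(tensors))$fused
  mats <- lapply(1:4, function(x) {
    u <- fit_ensemble(list(tensors), labels,
                      parse_recipe(sprintf("TunLayer-%d", x)), selected)
    predict_ensemble(u, list(tensors))$per_unit[[1]]
  })
  expect_equal(fused, sum_rule_fuse(mats), tolerance = 1e-12)
})

test_that("no test-fold sample influences fitting (leakage audit)", {
  ds <- gen_texture_dataset(texture_dataset_spec(per_class = 8, seed = 55))
  bb <- fixture_backbone()
  folds <- kfold_protocol(ds$labels, 4, seed = 2)
  tr <- which(folds != 1L)
  recipe <- parse_recipe("DCT+GMTP")
  selected <- select_layers(bb$layers)
  lnames <- selected$layer_name
  tens_all <- extract_layerset(bb, ds$images, lnames)
  tens_tr_withheld <- lapply(tens_all, function(x) x[tr])        # test rows exist but withheld
  tens_tr_absent <- extract_layerset(bb, ds$images[tr], lnames)  # test rows never extracted
  u1 <- fit_ensemble(list(tens_tr_withheld), ds$labels[tr], recipe, selected)
  u2 <- fit_ensemble(list(tens_tr_absent), ds$labels[tr], recipe, selected)
  expect_equal(length(u1), length(u2))
  for (i in seq_along(u1)) {
    expect_equal(u1[[i]]$reducer$state, u2[[i]]$reducer$state)
    expect_equal(u1[[i]]$unit$model$SV, u2[[i]]$unit$model$SV)
    expect_equal(u1[[i]]$unit$model$coefs, u2[[i]]$unit$model$coefs)
    expect_equal(u1[[i]]$unit$model$rho, u2[[i]]$unit$model$rho)
  }
})

test_that("fused ensembles are at least as accurate as their worst unit", {
  ds <- fixture_dataset()
  bb <- fixture_backbone()
  folds <- kfold_protocol(ds$labels, 5, seed = 7)
  tr <- which(folds != 1L); te <- which(folds == 1L)
  selected <- select_layers(bb$layers)
  tensors <- extract_layerset(bb, ds$images, selected$layer_name)
  sub <- function(idx) lapply(tensors, function(x) x[idx])
  units <- fit_ensemble(list(sub(tr)), ds$labels[tr], parse_recipe("DCT"),
                        selected)
  pr <- predict_ensemble(units, list(sub(te)))
  truth <- as.character(ds$labels[te])
  acc_of <- function(m) mean(colnames(m)[max.col(m, ties.method = "first")] == truth)
  fused_acc <- acc_of(pr$fused)
  unit_accs <- vapply(pr$per_unit, acc_of, numeric(1))
  expect_gte(fused_acc, min(unit_accs))
})
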