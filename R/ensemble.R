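#' SVM units and score-level fusion
#'
#' One radial-basis SVM is trained per (layer, reducer) pair with the generic
#' hyperparameters C = 1000 and gamma = 0.1; no per-dataset tuning is done.
#' Feature rows are L2-normalized before fitting and scoring, which keeps the
#' fixed kernel width meaningful across layers whose descriptor length spans
#' three orders of magnitude. Unit scores are per-class probabilities in
#' `[0, 1]` summing to 1 per row, obtained deterministically from the
#' one-vs-one decision values through a logistic link, so score matrices from
#' different layers are commensurable under the sum rule.
#'
#' @name svm-units
NULL

l2_normalize_rows <- function(X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

#' Train one RBF-SVM unit
#'
#' @param features numeric matrix, one row per training sample.
#' @param labels class labels (factor or coercible), >= 2 classes.
#' @param C,gamma RBF-SVM hyperparameters (defaults 1000 and 0.1).
#' @param layer_name optional provenance tag.
#' @return an `svm_unit` holding the fitted machine, the ordered class list
#'   and the expected feature length.
#' @export
train_unit <- function(features, labels, C = 1000, gamma = 0.1,
                       layer_name = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("SVM training needs at least 2 classes")
  X <- l2_normalize_rows(features)
  fit <- e1071::svm(X, labels, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  structure(list(model = fit, class_labels = levels(labels),
                 n_features = ncol(X), C = C, gamma = gamma,
                 layer_name = layer_name),
            class = "svm_unit")
}

#' Score samples with a trained unit
#'
#' One-vs-one decision values `f_ij` are mapped to pairwise preferences
#' `r_ij = 1 / (1 + exp(-f_ij))`, averaged per class over its `K - 1`
#' pairings, and row-normalized, giving a deterministic per-class probability
#' row for every sample.
#'
#' @param unit an `svm_unit`.
#' @param features numeric matrix (or single row) of descriptors.
#' @return a `samples x classes` score matrix with class labels as column
#'   names; every row sums to 1.
#' @export
score_unit <- function(unit, features) {
  X <- l2_normalize_rows(features)
  if (ncol(X) != unit$n_features) {
    stop(sprintf("feature length %d does not match unit's %d",
                 ncol(X), unit$n_features))
  }
  pr <- stats::predict(unit$model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cls <- unit$class_labels
  k <- length(cls)
  scores <- matrix(0, nrow(X), k, dimnames = list(NULL, cls))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (p in seq_along(pairs)) {
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    r <- stats::plogis(dv[, p])
    scores[, a] <- scores[, a] + r
    scores[, b] <- scores[, b] + (1 - r)
  }
  scores <- scores / (k - 1)
  scores / rowSums(scores)
}

#' Fuse score matrices by the normalized sum rule
#'
#' Elementwise sum divided by the number of contributing units; a single
#' input is returned unchanged. All matrices must share shape and class
#' (column) order.
#'
#' @param matrices list of `samples x classes` score matrices.
#' @return the fused score matrix.
#' @export
sum_rule_fuse <- function(matrices) {
  if (!length(matrices)) stop("nothing to fuse")
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!all(dim(m) == dim(ref)) || !identical(colnames(m), colnames(ref))) {
      stop("score matrices must share shape and class order")
    }
  }
  Reduce(`+`, matrices) / length(matrices)
}

#' Stratified, seeded k-fold assignment
#'
#' Each class's samples are shuffled under the seed and dealt round-robin
#' into the k folds (with a rotating starting fold across classes), so every
#' fold's class proportions match the global ones within one sample.
#'
#' @param labels class labels (factor or coercible).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
kfold_protocol <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (k < 2L) stop("k must be at least 2")
  if (min(table(labels)) < k) stop("every class needs at least k samples")
  folds <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx) %% k
    }
  })
  folds
}

# ---- recipes -----------------------------------------------------------------

#' Parse a named ensemble recipe
#'
#' Recognized names: the single-method recipes `DCT`, `g-DCT`, `PCA`, `CHI`,
#' `LBPCHI`, `CoOC`, `GEP`, `GMTP`; sums such as `DCT+GMTP` or
#' `DCT+PCA+GMTP`; their `(...)-2` variants, which drop the two deepest
#' selected layers from every method; `TunLayer-x` (one SVM on the x-to-last
#' selected layer's RAW-or-reduced features); and `TunFusLayer` (sum rule of
#' TunLayer-1..4). A `-2` recipe with exactly two methods is marked for two
#' independently trained backbones (one per method) when two are supplied.
#'
#' @param name recipe string, e.g. `"(DCT+GMTP)-2"`.
#' @return an `ensemble_recipe` list: `name`, `methods`, `drop_last_two`,
#'   `independent_trainings`, `tun_layer`.
#' @export
parse_recipe <- function(name) {
  raw <- gsub(" ", "", name)
  drop2 <- FALSE
  tun <- NA_integer_
  body <- raw
  if (grepl("^\\(.*\\)-2$", raw)) {
    drop2 <- TRUE
    body <- sub("^\\((.*)\\)-2$", "\\1", raw)
  } else if (grepl("-2$", raw) && !grepl("^TunLayer", raw)) {
    drop2 <- TRUE
    body <- sub("-2$", "", raw)
  }
  if (grepl("^TunLayer-[0-9]+$", body)) {
    tun <- as.integer(sub("^TunLayer-", "", body))
    methods <- "RAW"
  } else if (body == "TunFusLayer") {
    tun <- 0L                      # all of the last four layers
    methods <- "RAW"
  } else {
    methods <- strsplit(body, "+", fixed = TRUE)[[1]]
    canon <- c(DCT = "DCT", `g-DCT` = "gDCT", gDCT = "gDCT", PCA = "PCA",
               CHI = "CHI", LBPCHI = "LBPCHI", CoOC = "CoOC", GEP = "GEP",
               GMTP = "GMTP", RAW = "RAW")
    if (!all(methods %in% names(canon))) {
      stop(sprintf("unknown recipe '%s'", name))
    }
    methods <- unname(canon[methods])
  }
  structure(list(name = name, methods = methods, drop_last_two = drop2,
                 independent_trainings = if (drop2 && length(methods) == 2L) 2L else 1L,
                 tun_layer = tun),
            class = "ensemble_recipe")
}

# layers feeding SVMs for one method under a recipe
recipe_layers <- function(recipe, selected) {
  n <- nrow(selected)
  if (!is.na(recipe$tun_layer)) {
    if (recipe$tun_layer == 0L) {
      return(selected[max(1L, n - 3L):n, , drop = FALSE])
    }
    return(selected[n - recipe$tun_layer + 1L, , drop = FALSE])
  }
  if (recipe$drop_last_two) selected[seq_len(n - 2L), , drop = FALSE] else selected
}

#' Fit every unit of a recipe on a training fold
#'
#' For each method of the recipe and each of its layers, a reducer is fitted
#' on the training tensors, training descriptors computed, and an RBF-SVM
#' unit trained. Only the supplied training tensors ever reach a fitting
#' routine.
#'
#' @param tensors_by_backbone list (one per backbone) of layer-name-indexed
#'   lists of training tensors, as produced by [extract_layerset()].
#' @param labels training labels.
#' @param recipe an `ensemble_recipe`.
#' @param selected data.frame of selected layers ([select_layers()]).
#' @param spec_base a [reducer_spec()] carrying budgets and thresholds.
#' @param svm_C,svm_gamma SVM hyperparameters.
#' @return list of fitted pairs, each `list(backbone_index, layer_name,
#'   method, reducer, unit)`.
#' @export
fit_ensemble <- function(tensors_by_backbone, labels, recipe, selected,
                         spec_base = reducer_spec(), svm_C = 1000,
                         svm_gamma = 0.1) {
  layers <- recipe_layers(recipe, selected)
  units <- list()
  n_bb <- length(tensors_by_backbone)
  for (mi in seq_along(recipe$methods)) {
    method <- recipe$methods[mi]
    bb_idx <- if (recipe$independent_trainings > 1L && n_bb > 1L) {
      ((mi - 1L) %% n_bb) + 1L
    } else 1L
    tensors <- tensors_by_backbone[[bb_idx]]
    for (li in seq_len(nrow(layers))) {
      lname <- layers$layer_name[li]
      spec <- spec_base
      spec$method <- method
      fit <- reducer_fit(tensors[[lname]], labels, layers[li, , drop = FALSE], spec)
      feats <- reducer_apply(fit, tensors[[lname]])
      unit <- train_unit(feats, labels, C = svm_C, gamma = svm_gamma,
                         layer_name = lname)
      units[[length(units) + 1L]] <- list(backbone_index = bb_idx,
                                          layer_name = lname, method = method,
                                          reducer = fit, unit = unit)
    }
  }
  units
}

#' Score tensors with a fitted ensemble and fuse
#'
#' @param units result of [fit_ensemble()].
#' @param tensors_by_backbone layer-name-indexed tensor lists, one per
#'   backbone, for the samples to score.
#' @return list with the fused score matrix (`fused`) and the per-unit
#'   matrices (`per_unit`).
#' @export
predict_ensemble <- function(units, tensors_by_backbone) {
  mats <- lapply(units, function(u) {
    feats <- reducer_apply(u$reducer,
                           tensors_by_backbone[[u$backbone_index]][[u$layer_name]])
    score_unit(u$unit, feats)
  })
  list(fused = sum_rule_fuse(mats), per_unit = mats)
}

score_to_pred <- function(scores) {
  colnames(scores)[max.col(scores, ties.method = "first")]
}

#' Run a named recipe under cross-validation
#'
#' For every fold: activations of the selected layers are extracted for all
#' images, reducers and SVM units are fitted on the training fold only, the
#' test fold is scored, and per-unit matrices are fused by the normalized sum
#' rule. With several backbones, each backbone's ensemble is normalized and
#' the per-backbone fused scores are summed (cross-backbone fusion).
#'
#' @param recipe recipe name or `ensemble_recipe`.
#' @param backbones an `lf_backbone` or list of them.
#' @param images list of image arrays.
#' @param labels class labels, one per image.
#' @param folds integer fold assignment (see [kfold_protocol()]), or `k` to
#'   build one with `seed`.
#' @param spec_base a [reducer_spec()].
#' @param svm_C,svm_gamma SVM hyperparameters.
#' @param seed seed for fold construction when `folds` is a single number.
#' @return list: `fold_accuracy`, `mean_accuracy`, `predictions` data.frame
#'   (`sample`, `fold`, `truth`, `pred`, per-class fused scores), `confusion`.
#' @export
build_recipe <- function(recipe, backbones, images, labels, folds = 5L,
                         spec_base = reducer_spec(), svm_C = 1000,
                         svm_gamma = 0.1, seed = 1L) {
  if (is.character(recipe)) recipe <- parse_recipe(recipe)
  if (inherits(backbones, "lf_backbone")) backbones <- list(backbones)
  labels <- as.factor(labels)
  if (length(folds) == 1L) folds <- kfold_protocol(labels, k = folds, seed = seed)
  stopifnot(length(folds) == length(images), length(labels) == length(images))
  selected <- select_layers(backbones[[1]]$layers)
  lnames <- recipe_layers(recipe, selected)$layer_name
  tensors_all <- lapply(backbones, function(bb) {
    sel <- select_layers(bb$layers)
    extract_layerset(bb, images, recipe_layers(recipe, sel)$layer_name)
  })
  nk <- max(folds)
  acc <- numeric(nk)
  pred_rows <- list()
  for (f in seq_len(nk)) {
    tr <- which(folds != f); te <- which(folds == f)
    sub <- function(tl, idx) lapply(tl, function(x) x[idx])
    per_bb <- lapply(tensors_all, sub, idx = tr)
    if (length(backbones) > 1L && recipe$independent_trainings == 1L) {
      # cross-backbone fusion: full recipe per backbone, then sum
      fused <- NULL
      for (bi in seq_along(backbones)) {
        units <- fit_ensemble(list(sub(tensors_all[[bi]], tr)), labels[tr],
                              recipe, select_layers(backbones[[bi]]$layers),
                              spec_base, svm_C, svm_gamma)
        sc <- predict_ensemble(units, list(sub(tensors_all[[bi]], te)))
        fused <- if (is.null(fused)) sc$fused else fused + sc$fused
      }
      fused <- fused / length(backbones)
    } else {
      units <- fit_ensemble(per_bb, labels[tr], recipe, selected,
                            spec_base, svm_C, svm_gamma)
      fused <- predict_ensemble(units, lapply(tensors_all, sub, idx = te))$fused
    }
    pred <- score_to_pred(fused)
    acc[f] <- mean(pred == as.character(labels[te]))
    pred_rows[[f]] <- data.frame(sample = te, fold = f,
                                 truth = as.character(labels[te]), pred = pred,
                                 fused, check.names = FALSE,
                                 stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, pred_rows)
  predictions <- predictions[order(predictions$sample), , drop = FALSE]
  list(recipe = recipe$name, fold_accuracy = acc, mean_accuracy = mean(acc),
       predictions = predictions,
       confusion = table(truth = predictions$truth, pred = predictions$pred),
       layers = lnames)
}
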