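#' Reducer specification
#'
#' @param method one of `"DCT"`, `"gDCT"`, `"PCA"`, `"CHI"`, `"LBPCHI"`,
#'   `"CoOC"`, `"GEP"`, `"GMTP"`, `"RAW"`.
#' @param scope `"local"` (per channel) or `"global"` (whole layer). Pooling
#'   operators (`CoOC`, `GEP`, `GMTP`) are intrinsically per-channel.
#' @param budget_B target descriptor length (default 1000); ignored by the
#'   pooling operators, which emit one value per channel.
#' @param threshold_T flat-size threshold above which reduction applies
#'   (default 5000); at or below it the layer passes through RAW.
#' @param n_bins_chi quantile bins used to discretize continuous features for
#'   the chi-square statistic.
#' @param cooc_radius,cooc_epsilon co-occurrence window radius and
#'   self-channel filter value.
#' @return a `reducer_spec` list.
#' @export
reducer_spec <- function(method = "DCT", scope = c("local", "global"),
                         budget_B = 1000L, threshold_T = 5000L,
                         n_bins_chi = 10L, cooc_radius = 1L, cooc_epsilon = 0) {
  method <- match.arg(method, c("DCT", "gDCT", "PCA", "CHI", "LBPCHI",
                                "CoOC", "GEP", "GMTP", "RAW"))
  scope <- match.arg(scope)
  if (method == "gDCT") scope <- "global"
  stopifnot(budget_B > 0, threshold_T >= 0)
  structure(list(method = method, scope = scope,
                 budget_B = as.integer(budget_B),
                 threshold_T = as.integer(threshold_T),
                 n_bins_chi = as.integer(n_bins_chi),
                 cooc_radius = as.integer(cooc_radius),
                 cooc_epsilon = cooc_epsilon),
            class = "reducer_spec")
}

#' Does a layer need dimensionality reduction?
#'
#' Reduction applies only when a layer emits strictly more than
#' `threshold_T` features (default 5000).
#'
#' @param layer one row of [enumerate_layers()], or a flat size.
#' @param spec a [reducer_spec()].
#' @return logical.
#' @export
needs_reduction <- function(layer, spec = reducer_spec()) {
  flat <- if (is.data.frame(layer)) layer$flat_size[1] else as.integer(layer)
  flat > spec$threshold_T
}

#' Per-channel coefficient budget
#'
#' `floor(budget_B / channels_D)`, clamped to at least one coefficient per
#' channel, so the total descriptor length is `channels_D * result` (which can
#' deviate from `budget_B` when `channels_D` does not divide it, or exceed it
#' when there are more channels than budget).
#'
#' @param channels_D channel count.
#' @param budget_B total budget (default 1000).
#' @return integer coefficients per channel.
#' @export
channel_budget <- function(channels_D, budget_B = 1000L) {
  stopifnot(channels_D >= 1)
  max(1L, as.integer(budget_B) %/% as.integer(channels_D))
}

# ---- PCA --------------------------------------------------------------------

#' Fit / apply a PCA projection
#'
#' `pca_fit` learns an orthonormal basis ordered by decreasing explained
#' variance from training rows only; `pca_apply` centers by the training mean
#' and projects. A budget exceeding the data rank is clipped with a warning.
#'
#' @param X numeric matrix, rows = training samples.
#' @param budget number of components.
#' @return `pca_fit`: list with `rotation` (columns = components), `center`,
#'   `sdev`; `pca_apply`: projected rows.
#' @export
pca_fit <- function(X, budget) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA needs at least 2 training rows")
  rank_max <- min(ncol(X), nrow(X) - 1L)
  if (budget > rank_max) {
    warning(sprintf("PCA budget %d exceeds rank %d; clipped", budget, rank_max))
    budget <- rank_max
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = budget)
  list(rotation = p$rotation[, seq_len(budget), drop = FALSE],
       center = p$center, sdev = p$sdev[seq_len(budget)])
}

#' @rdname pca_fit
#' @param basis result of `pca_fit`.
#' @param rows numeric vector or matrix of rows to project.
#' @export
pca_apply <- function(basis, rows) {
  rows <- if (is.null(dim(rows))) matrix(rows, nrow = 1L) else as.matrix(rows)
  out <- sweep(rows, 2L, basis$center) %*% basis$rotation
  if (nrow(out) == 1L) as.vector(out) else out
}

# ---- chi-square feature selection -------------------------------------------

#' Chi-square dependence statistic between one feature and the class labels
#'
#' The continuous feature is discretized into quantile bins (computed on the
#' given values, i.e. the training fold), a bin-by-class contingency table of
#' observed counts O is formed, expected counts E come from the product of the
#' marginals, and the statistic is `sum((O - E)^2 / E)` over cells with
#' `E > 0`. A constant feature occupies a single bin and scores 0.
#'
#' @param x numeric feature column.
#' @param labels class labels (factor or coercible), >= 2 classes.
#' @param n_bins number of quantile bins (default 10).
#' @return a `chi_square_result` list: `statistic`, `dof_c`, `observed`,
#'   `expected`, `breaks`.
#' @export
chi_square_score <- function(x, labels, n_bins = 10L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("chi-square scoring needs at least 2 classes")
  if (!all(is.finite(x))) stop("feature column must be finite")
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 7))
  bins <- if (length(br) < 2L) rep(1L, length(x)) else {
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  O <- table(bin = bins, class = labels)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  use <- E > 0
  stat <- sum((O[use] - E[use])^2 / E[use])
  structure(list(statistic = stat,
                 dof_c = (nrow(O) - 1L) * (ncol(O) - 1L),
                 observed = unclass(O), expected = E, breaks = br),
            class = "chi_square_result")
}

#' Select the k most class-dependent feature columns
#'
#' Ranks every column by its [chi_square_score()] statistic; ties are broken
#' by the lower column index, so selection is deterministic.
#'
#' @param X numeric matrix, rows = training samples.
#' @param labels class labels.
#' @param k number of columns to keep (`<= ncol(X)`).
#' @param n_bins quantile bins for discretization.
#' @return integer vector of selected column indices with the score vector in
#'   attribute `"scores"`.
#' @export
chi_select <- function(X, labels, k, n_bins = 10L) {
  X <- as.matrix(X)
  if (k > ncol(X)) stop("cannot select more columns than exist")
  sc <- vapply(seq_len(ncol(X)),
               function(j) chi_square_score(X[, j], labels, n_bins)$statistic,
               numeric(1))
  idx <- order(-sc, seq_along(sc))[seq_len(k)]
  structure(idx, scores = sc)
}

# ---- uniform local binary patterns ------------------------------------------

#' LBP configuration (8 neighbors, radius 1, uniform patterns)
#'
#' @param neighbors_N,radius_R neighborhood definition (fixed defaults 8, 1).
#' @param uniform_only collapse non-uniform codes into one bin.
#' @return an `lbp_config` list.
#' @export
lbp_config <- function(neighbors_N = 8L, radius_R = 1L, uniform_only = TRUE) {
  if (neighbors_N != 8L || radius_R != 1L) {
    stop("only the 8-neighbor, radius-1 configuration is supported")
  }
  structure(list(neighbors_N = 8L, radius_R = 1L, uniform_only = uniform_only),
            class = "lbp_config")
}

# circular 0/1 transition count of an 8-bit code
lbp_transitions <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits != bits[c(2:8, 1)])
}

# bin lookup: uniform codes (ascending) -> bins 1..58, non-uniform -> bin 59
uniform_lbp_table <- function() {
  tr <- vapply(0:255, lbp_transitions, integer(1))
  tab <- integer(256)
  tab[tr < 3L] <- seq_len(sum(tr < 3L))
  tab[tr >= 3L] <- sum(tr < 3L) + 1L
  tab
}

.lbp_tab <- NULL

#' 59-bin uniform LBP histogram of a 2-D map
#'
#' For every interior pixel the 8 radius-1 neighbors are compared to the
#' center with `s(x) = 1` for `x >= 0`; bit n (weight `2^n`) corresponds to
#' the n-th neighbor counterclockwise from east. Codes with fewer than three
#' circular 0/1 transitions (the 58 uniform patterns) get one bin each; all
#' non-uniform codes share the 59th bin. Counts sum to the number of interior
#' pixels.
#'
#' @param map numeric matrix, at least 3 x 3.
#' @param cfg an [lbp_config()].
#' @return integer vector of 59 bin counts.
#' @export
lbp_uniform_hist <- function(map, cfg = lbp_config()) {
  map <- as.matrix(map)
  h <- nrow(map); w <- ncol(map)
  if (h < 3L || w < 3L) stop("map too small for radius-1 LBP")
  if (is.null(.lbp_tab)) {
    utils::assignInMyNamespace(".lbp_tab", uniform_lbp_table())
  }
  ctr <- map[2:(h - 1L), 2:(w - 1L)]
  # neighbor offsets counterclockwise from east: E, NE, N, NW, W, SW, S, SE
  # (row index grows downward, so "north" is row - 1)
  off <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
              c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  code <- matrix(0L, h - 2L, w - 2L)
  for (n in seq_along(off)) {
    nb <- map[2:(h - 1L) + off[[n]][1], 2:(w - 1L) + off[[n]][2]]
    code <- code + as.integer(nb - ctr >= 0) * 2L^(n - 1L)
  }
  tabulate(.lbp_tab[code + 1L], nbins = 59L)
}

#' Fit / apply the LBP + chi-square reducer
#'
#' Each channel is min-max normalized to `[0, 255]`, its 59-bin uniform LBP
#' histogram extracted, and histograms concatenated over channels
#' (`59 * D` raw features). A chi-square selector fitted on the training
#' tensors retains `budget_B` columns (a no-op when the raw length is
#' already within budget).
#'
#' @param tensors list of training activation arrays (same shape).
#' @param labels class labels, one per tensor.
#' @param budget_B number of histogram columns to keep.
#' @param n_bins_chi quantile bins for the chi-square statistic.
#' @return `lbpchi_fit`: list with `selected` column indices and `raw_length`;
#'   `lbpchi_apply`: selected descriptor for one tensor.
#' @export
lbpchi_fit <- function(tensors, labels, budget_B = 1000L, n_bins_chi = 10L) {
  raw <- t(vapply(tensors, lbp_raw_descriptor, numeric(lbp_raw_length(tensors[[1]]))))
  k <- min(as.integer(budget_B), ncol(raw))
  selected <- if (k == ncol(raw)) seq_len(ncol(raw)) else
    as.integer(chi_select(raw, labels, k, n_bins_chi))
  list(selected = selected, raw_length = ncol(raw))
}

#' @rdname lbpchi_fit
#' @param fit result of `lbpchi_fit`.
#' @param tensor one activation array.
#' @export
lbpchi_apply <- function(fit, tensor) {
  lbp_raw_descriptor(tensor)[fit$selected]
}

lbp_raw_length <- function(tensor) 59L * dim(as_tensor3(tensor))[3]

lbp_raw_descriptor <- function(tensor) {
  a <- as_tensor3(tensor)
  as.vector(vapply(seq_len(dim(a)[3]), function(ci) {
    m <- a[, , ci]
    rng <- range(m)
    m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) * 255 else m * 0
    as.numeric(lbp_uniform_hist(m))
  }, numeric(59L)))
}

# ---- co-occurrence pooling ---------------------------------------------------

#' Co-occurrence pooling of an activation tensor
#'
#' Supra-mean activations (strictly above the mean of the whole tensor) are
#' masked, and for every position the masked activations inside a
#' `(2r+1) x (2r+1)` window are summed over all channels, weighting the
#' position's own channel by `epsilon` (default 0) and every other channel
#' by 1; the sum only counts at positions that are themselves supra-mean
#' (zero-padded at the borders). The co-occurrence tensor is summarized as
#' one value per channel: the mean over its spatial grid.
#'
#' @param tensor activation array `h x w x D`.
#' @param radius_r window radius (window size `2r + 1`).
#' @param epsilon self-channel filter weight.
#' @return numeric vector of length `D`.
#' @export
cooc_pool <- function(tensor, radius_r = 1L, epsilon = 0) {
  a <- as_tensor3(tensor)
  d <- dim(a); h <- d[1]; w <- d[2]; D <- d[3]
  rho <- (a > mean(a)) * 1
  am <- a * rho
  amp <- pad_tensor(am, radius_r)
  # per-channel (2r+1)^2 window sums, zero-padded borders
  win <- array(0, d)
  for (di in -radius_r:radius_r) for (dj in -radius_r:radius_r) {
    win <- win + amp[(1 + radius_r + di):(h + radius_r + di),
                     (1 + radius_r + dj):(w + radius_r + dj), , drop = FALSE]
  }
  tot <- apply(win, c(1, 2), sum)               # sum over all channels
  ct <- array(0, d)
  for (k in seq_len(D)) {
    ct[, , k] <- (tot - (1 - epsilon) * win[, , k]) * rho[, , k]
  }
  apply(ct, 3L, mean)
}

# ---- global pooling measurements --------------------------------------------

#' Global entropy pooling
#'
#' Per channel: min-max normalize to `[0, 255]`, histogram the values into 255
#' equal-width bins, convert to probabilities, and return the Shannon entropy
#' `-sum(p * log(p))` (natural log, `0 log 0 := 0`). A constant channel
#' occupies a single bin and has entropy 0; the output is invariant to
#' positive affine rescaling of the tensor and bounded by `log(255)`.
#'
#' @param tensor activation array `h x w x D`.
#' @param n_bins histogram bins (default 255).
#' @return numeric vector of length `D`.
#' @export
gep_pool <- function(tensor, n_bins = 255L) {
  a <- as_tensor3(tensor)
  vapply(seq_len(dim(a)[3]), function(ci) {
    m <- a[, , ci]
    rng <- range(m)
    if (rng[2] <= rng[1]) return(0)
    v <- (m - rng[1]) / (rng[2] - rng[1]) * n_bins     # values in [0, n_bins]
    idx <- pmin(floor(v) + 1L, n_bins)                 # equal-width unit bins
    p <- tabulate(idx, nbins = n_bins)
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
}

#' Global mean-thresholding pooling
#'
#' The threshold is the mean over all channels and positions of the tensor;
#' each channel reports the proportion of its elements strictly below it.
#' Outputs lie in `[0, 1]` and are invariant to positive affine rescaling.
#'
#' @param tensor activation array `h x w x D`.
#' @return numeric vector of length `D`.
#' @export
gmtp_pool <- function(tensor) {
  a <- as_tensor3(tensor)
  tg <- mean(a)
  apply(a, 3L, function(m) mean(m < tg))
}

# ---- dispatch ----------------------------------------------------------------

#' Fit a reducer on training tensors
#'
#' Dispatch follows the layer-size rule: a layer at or below the flat-size
#' threshold passes through RAW untouched; above it the configured operator
#' applies. Fitted state (PCA basis, chi-square column indices) is learned
#' from the supplied training tensors only. 1-D layers (spatial size 1 x 1)
#' support only DCT (as a 1-D transform), gDCT, PCA, CHI and RAW.
#'
#' @param tensors list of training activation arrays, all of one layer.
#' @param labels class labels, one per tensor (used by CHI / LBPCHI).
#' @param layer one row of [enumerate_layers()] describing the layer.
#' @param spec a [reducer_spec()].
#' @return a `fitted_reducer` with a `$transform(tensor)` closure, the
#'   resolved `$method`, `$out_length` and the fitted `$state`.
#' @export
reducer_fit <- function(tensors, labels, layer, spec = reducer_spec()) {
  stopifnot(inherits(spec, "reducer_spec"))
  d <- dim(as_tensor3(tensors[[1]]))
  flat <- prod(d)
  is_1d <- d[1] == 1L && d[2] == 1L
  method <- if (!needs_reduction(flat, spec)) "RAW" else spec$method
  if (is_1d && method %in% c("LBPCHI", "CoOC", "GEP", "GMTP")) {
    stop(sprintf("method %s is undefined for a 1-D layer", spec$method))
  }
  if (is_1d && method == "DCT") method <- "gDCT"   # per-channel DCT of 1x1 maps
  state <- NULL
  transform <- switch(method,
    RAW = function(tensor) flatten_tensor(as_tensor3(tensor)),
    DCT = function(tensor) dct_reduce_local(tensor, spec$budget_B),
    gDCT = function(tensor) gdct_reduce(tensor, min(spec$budget_B, flat)),
    GEP = function(tensor) gep_pool(tensor),
    GMTP = function(tensor) gmtp_pool(tensor),
    CoOC = function(tensor) cooc_pool(tensor, spec$cooc_radius, spec$cooc_epsilon),
    PCA = {
      if (spec$scope == "local" && !is_1d) {
        k <- channel_budget(d[3], spec$budget_B)
        state <- lapply(seq_len(d[3]), function(ci) {
          rows <- t(vapply(tensors, function(a) as.vector(as_tensor3(a)[, , ci]),
                           numeric(d[1] * d[2])))
          pca_fit(rows, min(k, min(ncol(rows), nrow(rows) - 1L)))
        })
        function(tensor) {
          a <- as_tensor3(tensor)
          unlist(lapply(seq_len(d[3]), function(ci) {
            pca_apply(state[[ci]], as.vector(a[, , ci]))
          }))
        }
      } else {
        rows <- t(vapply(tensors, function(a) flatten_tensor(as_tensor3(a)),
                         numeric(flat)))
        state <- pca_fit(rows, min(spec$budget_B, min(ncol(rows), nrow(rows) - 1L)))
        function(tensor) pca_apply(state, flatten_tensor(as_tensor3(tensor)))
      }
    },
    CHI = {
      rows <- t(vapply(tensors, function(a) flatten_tensor(as_tensor3(a)),
                       numeric(flat)))
      k <- min(spec$budget_B, ncol(rows))
      state <- as.integer(chi_select(rows, labels, k, spec$n_bins_chi))
      function(tensor) flatten_tensor(as_tensor3(tensor))[state]
    },
    LBPCHI = {
      state <- lbpchi_fit(tensors, labels, spec$budget_B, spec$n_bins_chi)
      function(tensor) lbpchi_apply(state, tensor)
    })
  out_length <- length(transform(tensors[[1]]))
  structure(list(method = method, spec = spec, state = state,
                 layer_name = if (is.data.frame(layer)) layer$layer_name[1] else layer,
                 out_length = out_length, transform = transform),
            class = "fitted_reducer")
}

#' Reduce a set of tensors with a fitted reducer
#'
#' @param fit a `fitted_reducer` from [reducer_fit()].
#' @param tensors a single activation array or a list of them.
#' @return a numeric vector (single tensor) or matrix with one row per tensor.
#' @export
reducer_apply <- function(fit, tensors) {
  if (!is.list(tensors)) return(fit$transform(tensors))
  t(vapply(tensors, fit$transform, numeric(fit$out_length)))
}

#' Fit a reducer and produce descriptors for one layer
#'
#' Convenience wrapper combining [reducer_fit()] on the training tensors with
#' [reducer_apply()] on all tensors.
#'
#' @inheritParams reducer_fit
#' @param apply_tensors tensors to transform (defaults to the training set).
#' @return list with `fit` and `features` (rows in `apply_tensors` order).
#' @export
reduce_layer <- function(tensors, labels, layer, spec = reducer_spec(),
                         apply_tensors = tensors) {
  fit <- reducer_fit(tensors, labels, layer, spec)
  list(fit = fit, features = reducer_apply(fit, apply_tensors))
}
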