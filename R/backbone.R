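#' Convolutional backbones
#'
#' A backbone is a plain sequential stack of named nodes
#' (`conv` / `relu` / `maxpool` / `fc`), each producing an activation that can
#' be tapped for feature extraction. Weights are stored explicitly, forward
#' passes are pure R (im2col convolution), and a full analytic backward pass
#' supports fine-tuning. Pretrained ImageNet-scale topologies are outside the
#' scope of the package; the supported registry is the seeded `tinycnn`
#' fixture family (see [tiny_backbone()]), plus any custom stack built with
#' [new_backbone()].
#'
#' @name backbone
NULL

#' Build a backbone from an explicit node list
#'
#' Node types: `conv` (fields `W` = kh x kw x Cin x Cout array with odd kernel
#' size, `b` length-Cout; stride 1, zero "same" padding), `relu`,
#' `maxpool` (2x2, stride 2), `fc` (fields `W` = out x in matrix, `b`;
#' flattens its input channel-major). Every node is an enumerable,
#' activation-producing layer.
#'
#' @param architecture_id name of the topology.
#' @param input_size integer length-2, input height and width in pixels.
#' @param nodes list of node lists, each with `name` and `type` plus weights.
#' @param pretrained logical flag: weights come from a generic corpus.
#' @param tuned logical flag: weights were fine-tuned on a task split.
#' @param in_channels input channel count (default 3, RGB).
#' @return an object of class `lf_backbone`.
#' @export
new_backbone <- function(architecture_id, input_size, nodes,
                         pretrained = FALSE, tuned = FALSE, in_channels = 3L) {
  stopifnot(length(input_size) == 2L, all(input_size > 0))
  nm <- vapply(nodes, function(n) n$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate node names in backbone")
  bb <- structure(
    list(architecture_id = architecture_id,
         input_size = as.integer(input_size),
         in_channels = as.integer(in_channels),
         nodes = nodes, pretrained = pretrained, tuned = tuned,
         tuned_on = NULL),
    class = "lf_backbone")
  bb$layers <- enumerate_layers(bb)
  bb
}

#' @export
print.lf_backbone <- function(x, ...) {
  cat(sprintf("<lf_backbone %s: %d nodes, input %dx%dx%d, %s>\n",
              x$architecture_id, length(x$nodes),
              x$input_size[1], x$input_size[2], x$in_channels,
              if (isTRUE(x$tuned)) "tuned" else "untuned"))
  invisible(x)
}

#' Enumerate the extractable layers of a backbone
#'
#' Walks the node list in forward order, propagating activation shapes from
#' the input size. The enumeration is deterministic for a given
#' `architecture_id` and is the index space used by [select_layers()].
#'
#' @param backbone an `lf_backbone`.
#' @return a data.frame with one row per node: `layer_name`, `depth_index`,
#'   `channels_D`, `spatial_h`, `spatial_w`, `flat_size`.
#' @export
enumerate_layers <- function(backbone) {
  if (!inherits(backbone, "lf_backbone")) stop("unsupported backbone")
  h <- backbone$input_size[1]; w <- backbone$input_size[2]
  d <- backbone$in_channels
  out <- vector("list", length(backbone$nodes))
  for (i in seq_along(backbone$nodes)) {
    nd <- backbone$nodes[[i]]
    switch(nd$type,
      conv = { d <- dim(nd$W)[4] },
      relu = { },
      maxpool = { h <- h %/% 2L; w <- w %/% 2L },
      fc = { h <- 1L; w <- 1L; d <- nrow(nd$W) },
      stop(sprintf("unknown node type '%s'", nd$type)))
    out[[i]] <- data.frame(layer_name = nd$name, depth_index = i,
                           channels_D = as.integer(d),
                           spatial_h = as.integer(h), spatial_w = as.integer(w),
                           flat_size = as.integer(d * h * w),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Select the layers that feed SVM units
#'
#' Starting from the middle layer (index `ceiling(L/2)`), one layer is taken
#' after every 10 toward the output, and the last four layers are always
#' included; duplicates are removed and forward order preserved.
#'
#' @param layers data.frame from [enumerate_layers()] (needs >= 5 rows).
#' @return the selected subset of `layers`, order preserved.
#' @export
select_layers <- function(layers) {
  n <- nrow(layers)
  if (is.null(n) || n < 5L) stop("layer selection needs at least 5 enumerated layers")
  idx <- sort(unique(c(seq(ceiling(n / 2), n, by = 10L), (n - 3L):n)))
  layers[idx, , drop = FALSE]
}

# ---- forward / backward engine ----------------------------------------------

pad_tensor <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  xp
}

# im2col: rows index output pixels (column-major), columns index (ki, kj, ci)
im2col <- function(xp, h, w, kh, kw, cin) {
  cols <- matrix(0, h * w, kh * kw * cin)
  pos <- 0L
  for (ci in seq_len(cin)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    pos <- pos + 1L
    cols[, pos] <- as.vector(xp[ki:(ki + h - 1L), kj:(kj + w - 1L), ci])
  }
  cols
}

conv_forward <- function(x, W, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  p <- (kh - 1L) %/% 2L
  cols <- im2col(pad_tensor(x, p), h, w, kh, kw, cin)
  outm <- cols %*% matrix(W, ncol = cout)
  outm <- outm + matrix(b, h * w, cout, byrow = TRUE)
  list(out = array(outm, c(h, w, cout)), cols = cols)
}

conv_backward <- function(dout, x, W, cols) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  p <- (kh - 1L) %/% 2L
  dom <- matrix(dout, h * w, cout)
  db <- colSums(dom)
  dW <- array(crossprod(cols, dom), dim(W))
  dcols <- dom %*% t(matrix(W, ncol = cout))
  dxp <- array(0, c(h + 2L * p, w + 2L * p, cin))
  pos <- 0L
  for (ci in seq_len(cin)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    pos <- pos + 1L
    dxp[ki:(ki + h - 1L), kj:(kj + w - 1L), ci] <-
      dxp[ki:(ki + h - 1L), kj:(kj + w - 1L), ci] + matrix(dcols[, pos], h, w)
  }
  dx <- if (p > 0L) dxp[(p + 1L):(p + h), (p + 1L):(p + w), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

maxpool_forward <- function(x) {
  d <- dim(x); ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  parts <- list(x[ro, co, , drop = FALSE], x[ro + 1L, co, , drop = FALSE],
                x[ro, co + 1L, , drop = FALSE], x[ro + 1L, co + 1L, , drop = FALSE])
  out <- pmax(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
  list(out = out, parts = parts)
}

maxpool_backward <- function(dout, x, fw) {
  d <- dim(x); ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  dx <- array(0, d)
  taken <- array(FALSE, dim(fw$out))
  idx <- list(cbind(0L, 0L), cbind(1L, 0L), cbind(0L, 1L), cbind(1L, 1L))
  for (q in 1:4) {
    m <- (fw$parts[[q]] == fw$out) & !taken   # ties routed to first position
    taken <- taken | m
    dr <- ro + idx[[q]][1]; dc <- co + idx[[q]][2]
    dx[dr, dc, ] <- dx[dr, dc, ] + dout * m
  }
  dx
}

forward_nodes <- function(backbone, x, keep_cache = FALSE) {
  acts <- vector("list", length(backbone$nodes))
  caches <- if (keep_cache) vector("list", length(backbone$nodes)) else NULL
  names(acts) <- vapply(backbone$nodes, `[[`, character(1), "name")
  cur <- x
  for (i in seq_along(backbone$nodes)) {
    nd <- backbone$nodes[[i]]
    cur <- switch(nd$type,
      conv = {
        fw <- conv_forward(cur, nd$W, nd$b)
        if (keep_cache) caches[[i]] <- list(x = cur, cols = fw$cols)
        fw$out
      },
      relu = {
        if (keep_cache) caches[[i]] <- list(x = cur)
        pmax(cur, 0)
      },
      maxpool = {
        fw <- maxpool_forward(cur)
        if (keep_cache) caches[[i]] <- list(x = cur, fw = fw)
        fw$out
      },
      fc = {
        v <- flatten_tensor(cur)
        if (keep_cache) caches[[i]] <- list(x = cur, v = v)
        array(as.vector(nd$W %*% v + nd$b), c(1L, 1L, nrow(nd$W)))
      })
    acts[[i]] <- cur
  }
  list(acts = acts, caches = caches)
}

#' Run an image through a backbone
#'
#' @param backbone an `lf_backbone`.
#' @param image numeric `h x w x C` array matching the backbone's input size
#'   and channel count, values typically in `[0, 1]`.
#' @return named list of activation arrays, one per node, in forward order.
#' @export
forward_pass <- function(backbone, image) {
  image <- as_tensor3(image)
  d <- dim(image)
  if (d[1] != backbone$input_size[1] || d[2] != backbone$input_size[2] ||
      d[3] != backbone$in_channels) {
    stop(sprintf("input must be %d x %d x %d for this backbone",
                 backbone$input_size[1], backbone$input_size[2], backbone$in_channels))
  }
  forward_nodes(backbone, image)$acts
}

#' Extract the activation tensor of one layer for one image
#'
#' The image is resized to the backbone's input size if needed (bilinear,
#' grayscale replicated to the expected channel count); extraction is fully
#' deterministic for a frozen backbone.
#'
#' @param backbone an `lf_backbone`.
#' @param image numeric image array (`h x w` or `h x w x C`, values in `[0,1]`).
#' @param layer a layer name, or one row of [enumerate_layers()].
#' @return an [activation_tensor()] whose shape matches the layer descriptor.
#' @export
extract_activations <- function(backbone, image, layer) {
  lname <- if (is.data.frame(layer)) layer$layer_name[1] else as.character(layer)
  if (!lname %in% backbone$layers$layer_name) {
    stop(sprintf("unknown layer '%s' for backbone %s", lname, backbone$architecture_id))
  }
  img <- prepare_input(backbone, image)
  acts <- forward_pass(backbone, img)
  activation_tensor(as_tensor3(acts[[lname]]), layer_name = lname)
}

#' Extract several layers for a set of images in one pass each
#'
#' @param backbone an `lf_backbone`.
#' @param images list of image arrays.
#' @param layer_names character vector of layer names to tap.
#' @return named list (per layer) of lists of activation arrays (per image).
#' @export
extract_layerset <- function(backbone, images, layer_names) {
  bad <- setdiff(layer_names, backbone$layers$layer_name)
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  res <- lapply(layer_names, function(l) vector("list", length(images)))
  names(res) <- layer_names
  for (i in seq_along(images)) {
    acts <- forward_pass(backbone, prepare_input(backbone, images[[i]]))
    for (l in layer_names) res[[l]][[i]] <- as_tensor3(acts[[l]])
  }
  res
}

# resize to input size and replicate / trim channels as needed
prepare_input <- function(backbone, image) {
  img <- as_tensor3(image)
  d <- dim(img)
  if (d[3] == 1L && backbone$in_channels == 3L) {
    img <- array(rep(img, 3L), c(d[1], d[2], 3L))
    d <- dim(img)
  }
  if (d[3] != backbone$in_channels) stop("image channel count does not match backbone")
  if (d[1] != backbone$input_size[1] || d[2] != backbone$input_size[2]) {
    img <- EBImage::resize(EBImage::Image(img, colormode = "Color"),
                           w = backbone$input_size[1], h = backbone$input_size[2])
    img <- as_tensor3(EBImage::imageData(img))
  }
  img
}

# ---- fine-tuning -------------------------------------------------------------

#' Fine-tuning configuration
#'
#' Defaults follow the generic transfer-learning protocol the pipeline was
#' designed around: batch size 30, learning rate 3e-4 for 20 epochs with the
#' last fully connected layer trained at a 20x larger rate, and augmentation
#' by random reflections on both axes plus two independent per-axis rescales
#' drawn uniformly from `[1, 2]`.
#'
#' @param batch_size images per gradient step.
#' @param learning_rate base learning rate.
#' @param epochs training epochs (50 is used for small TEM-style protocols).
#' @param final_layer_lr_multiplier factor applied to the last fc layer's rate.
#' @param augment logical: apply reflection + rescale augmentation.
#' @param rescale_range range of the per-axis rescale factor.
#' @param momentum SGD momentum.
#' @param seed integer; fixes augmentation draws and batch order.
#' @return a `fine_tune_config` list.
#' @export
fine_tune_config <- function(batch_size = 30L, learning_rate = 3e-4,
                             epochs = 20L, final_layer_lr_multiplier = 20,
                             augment = TRUE, rescale_range = c(1, 2),
                             momentum = 0.9, seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate >= 0, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 final_layer_lr_multiplier = final_layer_lr_multiplier,
                 augment = augment, rescale_range = rescale_range,
                 momentum = momentum, seed = as.integer(seed)),
            class = "fine_tune_config")
}

augment_image <- function(img, rescale_range) {
  d <- dim(img)
  if (runif(1) < 0.5) img <- img[d[1]:1, , , drop = FALSE]
  if (runif(1) < 0.5) img <- img[, d[2]:1, , drop = FALSE]
  sy <- runif(1, rescale_range[1], rescale_range[2])
  sx <- runif(1, rescale_range[1], rescale_range[2])
  # zoom-in: sample the central 1/s window back to full size (nearest neighbor)
  ri <- pmin(d[1], pmax(1L, round((seq_len(d[1]) - 0.5) / sy + d[1] * (1 - 1 / sy) / 2 + 0.5)))
  ci <- pmin(d[2], pmax(1L, round((seq_len(d[2]) - 0.5) / sx + d[2] * (1 - 1 / sx) / 2 + 0.5)))
  img[ri, ci, , drop = FALSE]
}

backward_nodes <- function(backbone, caches, dout, lr_scale) {
  n <- length(backbone$nodes)
  grads <- vector("list", n)
  for (i in n:1) {
    nd <- backbone$nodes[[i]]
    ca <- caches[[i]]
    dout <- switch(nd$type,
      conv = {
        bw <- conv_backward(dout, ca$x, nd$W, ca$cols)
        grads[[i]] <- list(dW = bw$dW, db = bw$db)
        bw$dx
      },
      relu = dout * (ca$x > 0),
      maxpool = maxpool_backward(dout, ca$x, ca$fw),
      fc = {
        dv <- as.vector(dout)
        grads[[i]] <- list(dW = outer(dv, ca$v), db = dv)
        array(as.vector(crossprod(nd$W, dv)), dim(ca$x))
      })
  }
  grads
}

#' Fine-tune a backbone on a labeled training set
#'
#' Minimizes softmax cross-entropy with momentum SGD. The last `fc` node is
#' updated with `final_layer_lr_multiplier` times the base learning rate.
#' When the final layer's width does not match the number of classes it is
#' reinitialized (seeded) to the right width.
#'
#' @param backbone an `lf_backbone` ending in an `fc` node.
#' @param images list of image arrays.
#' @param labels factor (or coercible) of class labels, one per image.
#' @param cfg a [fine_tune_config()].
#' @return the tuned backbone; `$tuned` is `TRUE`, `$loss_history` holds the
#'   mean training loss per epoch, `$tuned_on` records seed and sample count.
#' @export
fine_tune <- function(backbone, images, labels, cfg = fine_tune_config()) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("fine-tuning needs at least two classes")
  if (length(images) != length(labels)) stop("images/labels length mismatch")
  n <- length(images)
  last <- length(backbone$nodes)
  if (backbone$nodes[[last]]$type != "fc") stop("backbone must end in an fc node")
  with_seed(cfg$seed, {
    k <- nlevels(labels)
    if (nrow(backbone$nodes[[last]]$W) != k) {
      fanin <- ncol(backbone$nodes[[last]]$W)
      backbone$nodes[[last]]$W <- matrix(rnorm(k * fanin, sd = sqrt(2 / fanin)), k, fanin)
      backbone$nodes[[last]]$b <- numeric(k)
      backbone$layers <- enumerate_layers(backbone)
    }
    y <- as.integer(labels)
    imgs <- lapply(images, function(im) prepare_input(backbone, im))
    vel <- lapply(backbone$nodes, function(nd) {
      if (nd$type %in% c("conv", "fc")) list(W = nd$W * 0, b = nd$b * 0) else NULL
    })
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      eploss <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        gacc <- NULL; bloss <- 0
        for (j in bidx) {
          img <- imgs[[j]]
          if (cfg$augment) img <- augment_image(img, cfg$rescale_range)
          fw <- forward_nodes(backbone, img, keep_cache = TRUE)
          logits <- as.vector(fw$acts[[last]])
          p <- exp(logits - max(logits)); p <- p / sum(p)
          bloss <- bloss - log(max(p[y[j]], 1e-12))
          dlog <- p; dlog[y[j]] <- dlog[y[j]] - 1
          g <- backward_nodes(backbone, fw$caches, array(dlog, c(1L, 1L, k)), NULL)
          if (is.null(gacc)) gacc <- g else {
            for (i in seq_along(g)) if (!is.null(g[[i]])) {
              gacc[[i]]$dW <- gacc[[i]]$dW + g[[i]]$dW
              gacc[[i]]$db <- gacc[[i]]$db + g[[i]]$db
            }
          }
        }
        m <- length(bidx)
        for (i in seq_along(backbone$nodes)) {
          if (is.null(gacc[[i]])) next
          lr <- cfg$learning_rate * if (i == last) cfg$final_layer_lr_multiplier else 1
          vel[[i]]$W <- cfg$momentum * vel[[i]]$W - lr * gacc[[i]]$dW / m
          vel[[i]]$b <- cfg$momentum * vel[[i]]$b - lr * gacc[[i]]$db / m
          backbone$nodes[[i]]$W <- backbone$nodes[[i]]$W + vel[[i]]$W
          backbone$nodes[[i]]$b <- backbone$nodes[[i]]$b + vel[[i]]$b
        }
        eploss <- eploss + bloss / m; nb <- nb + 1L
      }
      losses[ep] <- eploss / max(nb, 1L)
    }
    backbone$tuned <- TRUE
    backbone$loss_history <- losses
    backbone$tuned_on <- list(seed = cfg$seed, n_samples = n,
                              classes = levels(labels), epochs = cfg$epochs,
                              config = unclass(cfg))
    backbone
  })
}

#' Classify images with the backbone's own softmax head
#'
#' @param backbone an `lf_backbone` ending in an `fc` node.
#' @param images list of image arrays.
#' @return integer class indices (argmax of the final layer).
#' @export
backbone_predict <- function(backbone, images) {
  last <- backbone$layers$layer_name[nrow(backbone$layers)]
  vapply(images, function(im) {
    which.max(as.vector(extract_activations(backbone, im, last)))
  }, integer(1))
}
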