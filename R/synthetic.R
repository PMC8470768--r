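#' Synthetic texture dataset specification
#'
#' Stands in for the fluorescence-microscopy and TEM collections the pipeline
#' targets: each class is an oriented sinusoidal grating (a distinct
#' orientation-frequency pair) corrupted by seeded additive Gaussian noise.
#' Texture-like signal is what the inner convolutional layers respond to, so
#' these images exercise the same layers the real datasets do.
#'
#' @param n_classes number of classes (>= 2; default 3).
#' @param per_class images per class (default 30).
#' @param image_size square image side in pixels (default 64).
#' @param orientations grating orientation per class, radians (defaults
#'   evenly spaced over half a turn).
#' @param frequencies grating frequency per class, cycles per image
#'   (defaults 4, 6, 8, ...).
#' @param amplitude grating amplitude around mid-gray (default 0.25).
#' @param noise_sd additive Gaussian noise sd on the `[0, 1]` intensity scale
#'   (default 0.1).
#' @param seed integer seed; same spec + seed regenerates byte-identical data.
#' @return a `texture_dataset_spec` list.
#' @export
texture_dataset_spec <- function(n_classes = 3L, per_class = 30L,
                                 image_size = 64L,
                                 orientations = seq(0, pi, length.out = n_classes + 1L)[seq_len(n_classes)],
                                 frequencies = 4 + 2 * (seq_len(n_classes) - 1L),
                                 amplitude = 0.25, noise_sd = 0.1, seed = 1L) {
  if (n_classes < 2L) stop("a dataset needs at least 2 classes")
  stopifnot(per_class >= 1, image_size >= 8,
            length(orientations) == n_classes, length(frequencies) == n_classes)
  if (anyDuplicated(paste(round(orientations, 6), round(frequencies, 6)))) {
    stop("classes must have distinct orientation-frequency pairs")
  }
  structure(list(n_classes = as.integer(n_classes),
                 per_class = as.integer(per_class),
                 image_size = as.integer(image_size),
                 orientations = orientations, frequencies = frequencies,
                 amplitude = amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "texture_dataset_spec")
}

grating_image <- function(size, theta, freq, amplitude) {
  xy <- (seq_len(size) - 0.5) / size
  phase <- outer(xy * cos(theta), xy * sin(theta), `+`)
  0.5 + amplitude * sin(2 * pi * freq * phase)
}

#' Generate a labeled synthetic texture dataset
#'
#' Images are 8-bit grayscale gratings plus seeded Gaussian noise, clipped to
#' `[0, 1]` and quantized to 256 levels. With `dir = NULL` the dataset is
#' returned in memory; otherwise it is also written as PNG files in the
#' standard `root/<class>/*.png` layout and the directory path returned in
#' `$dir`. Regeneration from the same spec is byte-identical.
#'
#' @param spec a [texture_dataset_spec()].
#' @param dir optional output directory.
#' @return list: `images` (list of `size x size` matrices in `[0, 1]`),
#'   `labels` (factor `class1`, `class2`, ...), `spec`, `dir`, `files`.
#' @export
gen_texture_dataset <- function(spec = texture_dataset_spec(), dir = NULL) {
  stopifnot(inherits(spec, "texture_dataset_spec"))
  imgs <- vector("list", spec$n_classes * spec$per_class)
  labels <- character(length(imgs))
  files <- character(length(imgs))
  with_seed(spec$seed, {
    i <- 0L
    for (ci in seq_len(spec$n_classes)) {
      base <- grating_image(spec$image_size, spec$orientations[ci],
                            spec$frequencies[ci], spec$amplitude)
      for (r in seq_len(spec$per_class)) {
        i <- i + 1L
        img <- base
        if (spec$noise_sd > 0) {
          img <- img + matrix(stats::rnorm(length(base), sd = spec$noise_sd),
                              nrow(base))
        }
        img <- round(pmin(pmax(img, 0), 1) * 255) / 255
        imgs[[i]] <- img
        labels[i] <- sprintf("class%d", ci)
        files[i] <- sprintf("class%d/img_%03d.png", ci, r)
      }
    }
  })
  if (!is.null(dir)) {
    for (ci in seq_len(spec$n_classes)) {
      dir.create(file.path(dir, sprintf("class%d", ci)),
                 recursive = TRUE, showWarnings = FALSE)
    }
    for (i in seq_along(imgs)) {
      png::writePNG(imgs[[i]], file.path(dir, files[i]))
    }
  }
  list(images = imgs, labels = factor(labels), spec = spec, dir = dir,
       files = if (is.null(dir)) NULL else files)
}

#' Load a labeled image dataset from a class-subdirectory tree
#'
#' Expects `root/<class_name>/*.{png,tif,tiff,jpg,jpeg}`. Images are decoded
#' to arrays in `[0, 1]` (grayscale kept as a single channel; replication to
#' RGB happens at backbone input).
#'
#' @param root dataset root directory.
#' @return list with `images`, `labels` (factor of subdirectory names) and
#'   `files`.
#' @export
load_image_dataset <- function(root) {
  if (!dir.exists(root)) stop(sprintf("dataset directory '%s' not found", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) < 2L) stop("dataset needs at least 2 class subdirectories")
  images <- list(); labels <- character(); files <- character()
  for (cl in classes) {
    fl <- sort(list.files(file.path(root, cl),
                          pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                          ignore.case = TRUE, full.names = TRUE))
    for (f in fl) {
      img <- EBImage::imageData(EBImage::readImage(f))
      # EBImage stores (x, y[, channel]); convert to row-major (h, w[, c])
      img <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2L, 1L, 3L))
      if (length(dim(img)) == 3L && dim(img)[3] > 3L) {
        img <- img[, , 1:3, drop = FALSE]                # drop alpha
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
      files <- c(files, f)
    }
  }
  if (!length(images)) stop("no decodable images found")
  list(images = images, labels = factor(labels), files = files)
}

#' Generate a seeded activation tensor with controlled statistics
#'
#' Families: `"uniform"` (iid `U(0, max)`), `"half-normal"` (`|N(0, sd)|`),
#' `"sparse-spikes"` (zeros plus `n_spikes` seeded unit spikes of amplitude
#' `amplitude`).
#'
#' @param h,w,D tensor dimensions.
#' @param family distribution family name.
#' @param seed integer seed.
#' @param max,sd,n_spikes,amplitude family parameters.
#' @return an [activation_tensor()].
#' @export
gen_activation_tensor <- function(h, w, D, family = c("uniform", "half-normal",
                                                      "sparse-spikes"),
                                  seed = 1L, max = 1, sd = 1, n_spikes = 1L,
                                  amplitude = 1) {
  stopifnot(h >= 1, w >= 1, D >= 1)
  family <- match.arg(family)
  vals <- with_seed(seed, switch(family,
    uniform = array(stats::runif(h * w * D, 0, max), c(h, w, D)),
    `half-normal` = array(abs(stats::rnorm(h * w * D, sd = sd)), c(h, w, D)),
    `sparse-spikes` = {
      a <- array(0, c(h, w, D))
      pos <- sample.int(h * w * D, n_spikes)
      a[pos] <- amplitude
      a
    }))
  activation_tensor(vals, sample_id = sprintf("%s-seed%d", family, seed))
}

#' The fixture backbone: a seeded 3-block convolution-pool stack
#'
#' Twelve enumerable nodes (`conv`/`relu`/`pool` per block, then two fully
#' connected stages): channel widths 8 / 24 / 40 on a 64 x 64 RGB input, so
#' the middle selected layer (`pool2`, 16 x 16 x 24 = 6144 features) exceeds
#' the 5000-feature reduction threshold and the reduction path is exercised,
#' while `conv1` (32768 features) is the largest layer. Weights are seeded
#' He-normal draws, so the backbone is a frozen, fully deterministic fixture.
#'
#' @param seed integer seed for the weight draws.
#' @param n_classes width of the final fc node (default 3).
#' @param input_size input side in pixels (default 64).
#' @return an `lf_backbone`.
#' @export
tiny_backbone <- function(seed = 1L, n_classes = 3L, input_size = 64L) {
  widths <- c(8L, 24L, 40L)
  fc_width <- 64L
  with_seed(seed, {
    he_conv <- function(cin, cout) {
      array(stats::rnorm(3 * 3 * cin * cout, sd = sqrt(2 / (9 * cin))),
            c(3L, 3L, cin, cout))
    }
    he_fc <- function(cin, cout) {
      matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cout, cin)
    }
    flat3 <- (input_size %/% 8L)^2 * widths[3]
    nodes <- list(
      list(name = "conv1", type = "conv", W = he_conv(3L, widths[1]),
           b = numeric(widths[1])),
      list(name = "relu1", type = "relu"),
      list(name = "pool1", type = "maxpool"),
      list(name = "conv2", type = "conv", W = he_conv(widths[1], widths[2]),
           b = numeric(widths[2])),
      list(name = "relu2", type = "relu"),
      list(name = "pool2", type = "maxpool"),
      list(name = "conv3", type = "conv", W = he_conv(widths[2], widths[3]),
           b = numeric(widths[3])),
      list(name = "relu3", type = "relu"),
      list(name = "pool3", type = "maxpool"),
      list(name = "fc1", type = "fc", W = he_fc(flat3, fc_width),
           b = numeric(fc_width)),
      list(name = "relu4", type = "relu"),
      list(name = "fc2", type = "fc", W = he_fc(fc_width, n_classes),
           b = numeric(n_classes)))
    new_backbone(sprintf("tinycnn-%d", seed), c(input_size, input_size), nodes)
  })
}
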