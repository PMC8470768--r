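#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' All seeded generators in the package go through this helper so that they
#' are pure functions of their arguments and never disturb the caller's RNG
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Flatten an activation tensor to a vector
#'
#' Channel-major order: channels are concatenated in order, each channel's
#' spatial map unrolled column-major. This is the flattening used for RAW
#' descriptors and for the global DCT.
#'
#' @param a numeric array `h x w x D` (or a plain vector, returned as is).
#' @return numeric vector of length `h * w * D`.
#' @export
flatten_tensor <- function(a) {
  as.vector(a)
}

#' Construct an activation tensor
#'
#' A thin wrapper around a numeric `h x w x D` array carrying provenance
#' (layer name and sample id). All reducers accept either this class or a
#' plain array.
#'
#' @param values numeric array `h x w x D`; all entries must be finite.
#' @param layer_name name of the producing layer (optional).
#' @param sample_id provenance key (optional).
#' @return an `activation_tensor` (numeric array with attributes).
#' @export
activation_tensor <- function(values, layer_name = NULL, sample_id = NULL) {
  values <- as_tensor3(values)
  if (!all(is.finite(values))) stop("activation tensor contains non-finite values")
  attr(values, "layer_name") <- layer_name
  attr(values, "sample_id") <- sample_id
  class(values) <- c("activation_tensor", class(values))
  values
}

# coerce vector / matrix / array to a 3-D h x w x D array
as_tensor3 <- function(a) {
  if (is.null(dim(a))) {
    array(as.numeric(a), dim = c(1L, 1L, length(a)))
  } else if (length(dim(a)) == 2L) {
    array(as.numeric(a), dim = c(dim(a), 1L))
  } else if (length(dim(a)) == 3L) {
    storage.mode(a) <- "double"
    a
  } else {
    stop("expected a vector, matrix or 3-D array")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
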