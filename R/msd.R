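#' Mixed-scale dense network specification
#'
#' A width-1 mixed-scale dense (MS-D) 2D network: `depth` dilated 3x3
#' convolutional layers, each consuming the channel-concatenation of the
#' network input and every previous layer output, followed by a ReLU; a
#' final 1x1 linear layer maps all channels to `c_out`.  Dilations cycle
#' through 1..10 by default (layer i uses `(i - 1) %% 10 + 1`); spatial size
#' is preserved via reflection padding.
#'
#' @param c_in Input channels (>= 1).
#' @param depth Number of dense 3x3 layers (>= 0).
#' @param c_out Output channels (only 1 is instantiable; the parameter-count
#'   formula accepts any value).
#' @param dilations Optional integer vector of per-layer dilations (length
#'   `depth`); defaults to the cyclic 1..10 schedule.
#' @param seed Initialization seed.
#' @return An object of class `msd_spec`.
#' @export
msd_spec <- function(c_in = 1L, depth = 100L, c_out = 1L, dilations = NULL,
                     seed = 1L) {
  if (!is_count(c_in)) stopf("c_in must be >= 1")
  if (!is_count(depth, min = 0)) stopf("depth must be >= 0")
  if (!is_count(c_out)) stopf("c_out must be >= 1")
  if (is.null(dilations)) dilations <- (seq_len(depth) - 1L) %% 10L + 1L
  dilations <- as.integer(dilations)
  if (length(dilations) != depth || any(dilations < 1L))
    stopf("dilations must be %d positive integers", depth)
  structure(list(c_in = as.integer(c_in), depth = as.integer(depth),
                 c_out = as.integer(c_out), dilations = dilations,
                 seed = as.integer(seed)),
            class = "msd_spec")
}

#' Count trainable parameters of an MS-D network
#'
#' Each dense layer i has one 3x3 convolution over its `c_in + i - 1`
#' preceding channels plus one bias; the final 1x1 layer has one weight per
#' channel per output plus one bias per output:
#' `sum_i (9 * (c_in + i - 1) + 1) + (c_in + depth) * c_out + c_out`.
#'
#' @param spec An [msd_spec()].
#' @return Integer parameter count, equal to the length of the instantiated
#'   parameter vector of [msd_init()].
#' @export
msd_count_params <- function(spec) {
  stopifnot(inherits(spec, "msd_spec"))
  d <- spec$depth
  dense <- if (d > 0) sum(9L * (spec$c_in + seq_len(d) - 1L) + 1L) else 0L
  as.integer(dense + (spec$c_in + d) * spec$c_out + spec$c_out)
}

# Shapes of every parameter tensor, in packing order (used by the
# initializer; kept separate from the closed-form count).
msd_param_shapes <- function(spec) {
  shapes <- list()
  for (i in seq_len(spec$depth)) {
    c_prev <- spec$c_in + i - 1L
    shapes[[length(shapes) + 1L]] <- c(3L, 3L, c_prev)  # conv weights
    shapes[[length(shapes) + 1L]] <- 1L                 # bias
  }
  shapes[[length(shapes) + 1L]] <- c(spec$c_in + spec$depth, spec$c_out)
  shapes[[length(shapes) + 1L]] <- spec$c_out
  shapes
}

#' Construct a stage model
#'
#' Bundles an architecture spec, a flat parameter vector and the input /
#' output normalization constants applied around the network.
#'
#' @param spec An [msd_spec()].
#' @param params Numeric vector of length [msd_count_params()].
#' @param norm_in 2 x `c_in` matrix, rows = (mean, sd) per input channel.
#' @param norm_out Length-2 numeric (mean, sd) of the target.
#' @param history Optional training history.
#' @return An object of class `stage_model`.
#' @export
stage_model <- function(spec, params, norm_in = NULL, norm_out = c(0, 1),
                        history = NULL) {
  stopifnot(inherits(spec, "msd_spec"))
  if (length(params) != msd_count_params(spec))
    stopf("params has length %d, expected %d",
          length(params), msd_count_params(spec))
  if (is.null(norm_in))
    norm_in <- matrix(c(0, 1), nrow = 2, ncol = spec$c_in)
  norm_in <- matrix(as.numeric(norm_in), nrow = 2)
  if (ncol(norm_in) != spec$c_in) stopf("norm_in must have one column per channel")
  if (any(norm_in[2, ] <= 0) || norm_out[2] <= 0)
    stopf("normalization sd must be > 0")
  structure(list(spec = spec, params = as.numeric(params), norm_in = norm_in,
                 norm_out = as.numeric(norm_out), history = history),
            class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf("stage_model: MS-D c_in=%d depth=%d c_out=%d, %d parameters\n",
              x$spec$c_in, x$spec$depth, x$spec$c_out,
              length(x$params)))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best validation loss %.4g\n",
                x$history$epochs_run, x$history$best_val))
  invisible(x)
}

#' Initialize an MS-D stage model
#'
#' He-normal initialization for the dense layers (sd `sqrt(2 / fan_in)`),
#' zero biases and a zero final layer (the initial prediction is then the
#' normalized-target mean, a stable starting point for regression).
#' Deterministic given `spec$seed`.
#'
#' @param spec An [msd_spec()] with `c_out = 1`.
#' @return A [stage_model()] with identity normalization.
#' @export
msd_init <- function(spec) {
  stopifnot(inherits(spec, "msd_spec"))
  if (spec$c_out != 1L) stopf("only c_out = 1 networks can be instantiated")
  shapes <- msd_param_shapes(spec)
  params <- with_seed(spec$seed, {
    unlist(lapply(seq_along(shapes), function(k) {
      sh <- shapes[[k]]
      n <- prod(sh)
      if (k > 2L * spec$depth) return(numeric(n))       # final layer: zeros
      if (length(sh) == 1L) return(numeric(n))          # bias: zeros
      stats::rnorm(n, 0, sqrt(2 / (9 * sh[3])))
    }))
  })
  stage_model(spec, params)
}

#' Identity stage model
#'
#' A depth-0 model whose output is exactly its last input channel: the
#' final 1x1 layer has weight 1 on that channel and 0 elsewhere, with
#' identity normalization.  Useful for pass-through contracts of the
#' multi-stage pipeline.
#'
#' @param c_in Number of input channels.
#' @return A [stage_model()].
#' @export
identity_stage_model <- function(c_in = 1L) {
  spec <- msd_spec(c_in = c_in, depth = 0L)
  stage_model(spec, c(rep(0, c_in - 1L), 1, 0))
}

#' Run a stage model on an image
#'
#' Normalizes each input channel with the stored constants, evaluates the
#' network, and de-normalizes the output.  Spatial dimensions are
#' preserved for any input of at least 3 x 3 pixels.
#'
#' @param model A [stage_model()].
#' @param x Matrix `(H, W)` for `c_in = 1`, or array `(H, W, c_in)`.
#' @return Matrix `(H, W)`.
#' @export
msd_forward <- function(model, x) {
  stopifnot(inherits(model, "stage_model"))
  spec <- model$spec
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L || dim(x)[3] != spec$c_in)
    stopf("input has %s channels, the model expects %d",
          if (length(dim(x)) == 3L) dim(x)[3] else "?", spec$c_in)
  if (any(dim(x)[1:2] < 3L)) stopf("spatial dimensions must be >= 3")
  for (c in seq_len(spec$c_in))
    x[, , c] <- (x[, , c] - model$norm_in[1, c]) / model$norm_in[2, c]
  y <- msd_forward_cpp(model$params, x, spec$depth, spec$c_out,
                       spec$dilations)[, , 1]
  y * model$norm_out[2] + model$norm_out[1]
}
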