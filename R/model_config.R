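# Model configuration and the learnable parameter set.
#
# All shapes derive from the configuration. Attention projections and the
# frame-score network are shared across bands (they act on whatever band's
# frame sequence they are given); the CNN filter banks are per band so that
# band information never mixes before the ECA stage.

#' SSAM network configuration
#'
#' @param grid_size Side of the scalp grid (default 9).
#' @param attention_embed_channels Output channels of the 1x1 attention
#'   projections W_G/W_F (default 8).
#' @param frame_score_hidden Hidden width of the frame-score network
#'   (default 64).
#' @param cnn_filters Three strictly increasing filter counts for the
#'   per-band CNN (default 32, 64, 128).
#' @param cnn_kernel Convolution kernel side (default 3).
#' @param eca_lambda,eca_b Hyperparameters of the adaptive ECA kernel-size
#'   rule (defaults 2 and 1).
#' @param dropout_rate Dropout fraction applied to the flattened feature
#'   vector in training mode (default 0.4, the midpoint of the 0.3-0.5
#'   range).
#' @param l2_lambda L2 regularization coefficient in the loss
#'   (default 1e-4).
#' @param n_classes Number of output classes (default 2).
#' @return Object of class `model_config`.
#' @export
model_config <- function(grid_size = 9L, attention_embed_channels = 8L,
                         frame_score_hidden = 64L,
                         cnn_filters = c(32L, 64L, 128L), cnn_kernel = 3L,
                         eca_lambda = 2, eca_b = 1, dropout_rate = 0.4,
                         l2_lambda = 1e-4, n_classes = 2L) {
  if (length(cnn_filters) != 3 || any(diff(cnn_filters) <= 0)) {
    stop("cnn_filters must be three strictly increasing counts")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (eca_lambda <= 0) stop("eca_lambda must be positive")
  structure(list(
    grid_size = as.integer(grid_size), n_bands = 4L,
    attention_embed_channels = as.integer(attention_embed_channels),
    frame_score_hidden = as.integer(frame_score_hidden),
    cnn_filters = as.integer(cnn_filters), cnn_kernel = as.integer(cnn_kernel),
    eca_lambda = eca_lambda, eca_b = eca_b, dropout_rate = dropout_rate,
    l2_lambda = l2_lambda, n_classes = as.integer(n_classes)
  ), class = "model_config")
}

band_names <- function() names(eeg_bands())

#' Initialize the learnable parameter set
#'
#' LeCun-normal initialization (the standard choice for SELU networks) for
#' weight matrices; biases start at zero; the classifier weights start at
#' zero so initial class probabilities are uniform. The spatial-attention
#' projections are drawn at a scale chosen so their effective score
#' temperature `<w_G, w_F>` is order 1 independent of the embedding width:
#' at smaller scales the per-frame attention is near-uniform, which
#' collapses every recalibrated frame toward its mean and erases the
#' spatial structure the network is meant to mine.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for reproducible initialization.
#' @return Object of class `ssam_params` (named list of arrays, with the
#'   config attached as attribute `config`).
#' @export
init_params <- function(cfg = model_config(), seed = 1L) {
  set.seed(as.integer(seed))
  n <- cfg$grid_size^2
  ce <- cfg$attention_embed_channels
  dh <- cfg$frame_score_hidden
  f <- cfg$cnn_filters
  kk <- cfg$cnn_kernel^2
  lecun <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(1 / fan_in)), nr, nc)
  }
  conv_band <- function() list(
    K1 = lecun(f[1], kk, kk), c1 = numeric(f[1]),
    K2 = lecun(f[2], kk * f[1], kk * f[1]), c2 = numeric(f[2]),
    K3 = lecun(f[3], kk * f[2], kk * f[2]), c3 = numeric(f[3]))
  k_eca <- eca_kernel_size(f[3], cfg$eca_lambda, cfg$eca_b)
  # Random directions, but with the initial score temperature <wg,wf>
  # pinned at a working value: wf is corrected along wg so the inner
  # product is exactly att_temp (a chance near-zero or negative draw would
  # start the attention uniform or inverted and stall learning).
  att_temp <- 2
  att_sd <- sqrt(2) / ce^0.25
  wg <- stats::rnorm(ce, sd = att_sd)
  wf <- stats::rnorm(ce, sd = att_sd)
  wf <- wf + (att_temp - sum(wg * wf)) / sum(wg^2) * wg
  p <- list(
    wg = wg, bg = numeric(ce),
    wf = wf, bf = numeric(ce),
    Wa = lecun(n, n, n),
    W1 = lecun(dh, n, n), W2 = lecun(dh, n, n), b2 = numeric(dh),
    W3 = lecun(n, dh, dh), b1 = numeric(n),
    conv = stats::setNames(replicate(4, conv_band(), simplify = FALSE),
                           band_names()),
    we = stats::rnorm(k_eca, sd = sqrt(1 / k_eca)),
    Wd = matrix(0, cfg$n_classes, 4L * n * f[3]), bd = numeric(cfg$n_classes)
  )
  structure(p, class = "ssam_params", config = cfg)
}

#' Flatten parameters into one numeric vector
#'
#' Deterministic depth-first order; inverse is [unflatten_params()].
#'
#' @param params An `ssam_params`.
#' @return Numeric vector.
#' @export
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' Rebuild a parameter set from a flat vector
#'
#' @param v Numeric vector from [flatten_params()].
#' @param skeleton An `ssam_params` providing shapes and attributes.
#' @return An `ssam_params`.
#' @export
unflatten_params <- function(v, skeleton) {
  idx <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    out <- v[(idx + 1L):(idx + n)]
    idx <<- idx + n
    dim(out) <- dim(s)
    out
  }
  out <- walk(unclass(skeleton))
  if (idx != length(v)) stop("flat vector length does not match skeleton")
  attributes(out) <- attributes(skeleton)
  out
}

# 1 for weight entries (subject to L2), 0 for biases, in flatten order.
l2_mask <- function(params) {
  mask <- lapply(unclass(params), function(x) x)
  ones <- function(x) array(1, dim = if (is.null(dim(x))) length(x) else dim(x))
  zeros <- function(x) array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  mask$wg <- ones(params$wg); mask$bg <- zeros(params$bg)
  mask$wf <- ones(params$wf); mask$bf <- zeros(params$bf)
  mask$Wa <- ones(params$Wa)
  mask$W1 <- ones(params$W1); mask$W2 <- ones(params$W2)
  mask$b2 <- zeros(params$b2)
  mask$W3 <- ones(params$W3); mask$b1 <- zeros(params$b1)
  mask$conv <- lapply(params$conv, function(cb) list(
    K1 = ones(cb$K1), c1 = zeros(cb$c1), K2 = ones(cb$K2), c2 = zeros(cb$c2),
    K3 = ones(cb$K3), c3 = zeros(cb$c3)))
  mask$we <- ones(params$we)
  mask$Wd <- ones(params$Wd); mask$bd <- zeros(params$bd)
  unlist(mask, use.names = FALSE)
}

# Sum of squared weight entries (biases excluded).
l2_penalty <- function(params) {
  v <- flatten_params(params)
  sum((v * l2_mask(params))^2)
}

#' Save a checkpoint (parameters + config + format version)
#'
#' @param params An `ssam_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  saveRDS(list(format_version = 1L, config = attr(params, "config"),
               params = unclass(params)), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' Refuses checkpoints with a different format version.
#'
#' @param path Checkpoint path.
#' @return An `ssam_params`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop("unsupported checkpoint format version: ", obj$format_version)
  }
  structure(obj$params, class = "ssam_params", config = obj$config)
}
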