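# The SSAM network, stage by stage, as a readable vectorized R reference
# implementation. Training uses the fused C++ kernel (src/ssam_core.cpp),
# which implements exactly the same arithmetic; tests tie the two together
# via loss equality and a finite-difference gradient check.
#
# Conventions shared with the C++ kernel:
#  * 9x9 frames are flattened column-major (R's as.vector order);
#  * feature maps are (channels x cells) matrices;
#  * im2col rows are ordered channel-major, and within a channel by
#    kernel offset k = 3*(dj+1) + (di+1) + 1 for row/col offsets di, dj;
#  * the flattened feature vector concatenates bands in eeg_bands() order,
#    each band's 9x9xC stack in column-major order (cells fastest).

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))

#' Spatial self-attention over one topographic frame
#'
#' Each grid position attends to all positions of the same frame: scores
#' are inner products of two learned 1x1 projections of the frame
#' (`s[(i,j),(p,q)] = <G(i,j), F(p,q)>`), the attention matrix is the
#' row-wise softmax of the scores over the attended positions, and the
#' recalibrated frame Z is the attention-weighted sum of the input values.
#'
#' @param frame Square numeric matrix (a topographic feature frame).
#' @param params An `ssam_params`.
#' @return List with `Z` (recalibrated frame, same shape) and `attention`
#'   (cells x cells matrix, each row summing to 1).
#' @export
spatial_attention <- function(frame, params) {
  if (!all(is.finite(frame))) stop("non-finite values in frame")
  x <- as.vector(frame)
  n <- length(x)
  ce <- length(params$wg)
  G <- tcrossprod(x, params$wg) + matrix(params$bg, n, ce, byrow = TRUE)
  Fm <- tcrossprod(params$wf, x) + matrix(params$bf, ce, n)
  A <- softmax_rows(G %*% Fm)
  z <- A %*% x
  list(Z = matrix(z, nrow(frame), ncol(frame)), attention = A)
}

#' Frame-importance weights over a recalibrated frame sequence
#'
#' Scores each frame against an alignment pattern vector (a learned linear
#' projection of the time-averaged recalibrated sequence) through a
#' one-hidden-layer ELU network, then softmax-normalizes the per-frame
#' score inner products into importance weights alpha.
#'
#' @param Z_seq List of recalibrated frames, or a cells x T matrix.
#' @param params An `ssam_params`.
#' @return Numeric vector alpha of length T (non-negative, sums to 1).
#' @export
frame_importance <- function(Z_seq, params) {
  Zmat <- as_frame_matrix(Z_seq)
  if (ncol(Zmat) < 1) stop("empty frame sequence")
  zbar <- rowMeans(Zmat)
  Cv <- params$Wa %*% zbar
  U <- params$W2 %*% Zmat + as.vector(params$W1 %*% Cv + params$b2)
  Imat <- params$W3 %*% elu(U) + params$b1
  e <- colSums(Imat * Zmat)
  softmax_vec(e)
}

as_frame_matrix <- function(Z_seq) {
  if (is.matrix(Z_seq)) return(Z_seq)
  do.call(cbind, lapply(Z_seq, as.vector))
}

#' Steady-state activation map from weighted frames
#'
#' Elementwise importance-weighted sum of the recalibrated frames,
#' `S = sum_t alpha_t * Z_t`.
#'
#' @param Z_seq List of frames or cells x T matrix.
#' @param alpha Importance weights, length T, summing to 1.
#' @return Square matrix S (same shape as one frame).
#' @export
compute_ssam <- function(Z_seq, alpha) {
  Zmat <- as_frame_matrix(Z_seq)
  if (length(alpha) != ncol(Zmat)) {
    stop("length of alpha must equal number of frames")
  }
  g <- sqrt(nrow(Zmat))
  matrix(Zmat %*% alpha, g, g)
}

# --- CNN spatial encoder -------------------------------------------------

# im2col neighbor table for a g x g grid, 3x3 kernel, zero padding:
# a 9 x g^2 matrix of source cell indices (NA = padding).
im2col_table <- function(g) {
  tab <- matrix(NA_integer_, 9, g * g)
  for (cell in seq_len(g * g)) {
    i <- (cell - 1) %% g + 1
    j <- (cell - 1) %/% g + 1
    for (dj in -1:1) for (di in -1:1) {
      k <- 3 * (dj + 1) + (di + 1) + 1
      ii <- i + di
      jj <- j + dj
      if (ii >= 1 && ii <= g && jj >= 1 && jj <= g) {
        tab[k, cell] <- (jj - 1) * g + ii
      }
    }
  }
  tab
}

# X: channels x cells matrix -> (9*channels) x cells patch matrix.
im2col <- function(X, tab) {
  C <- nrow(X)
  out <- matrix(0, 9 * C, ncol(X))
  for (c in seq_len(C)) {
    v <- X[c, ]
    for (k in 1:9) {
      src <- tab[k, ]
      row <- (c - 1) * 9 + k
      ok <- !is.na(src)
      out[row, ok] <- v[src[ok]]
    }
  }
  out
}

#' Per-band CNN spatial encoding of an activation map
#'
#' Three stacked 3x3 convolutions (stride 1, zero padding, spatial size
#' preserved) with SELU activations and per-band filter banks, mapping the
#' 9x9 map to a 9x9xC feature stack.
#'
#' @param ssam Square activation map (matrix).
#' @param band Band tag (`"theta","alpha","beta","gamma"`).
#' @param params An `ssam_params`.
#' @return Array g x g x cnn_filters[3].
#' @export
cnn_encode <- function(ssam, band, params) {
  if (!band %in% names(params$conv)) stop("unknown band tag: ", band)
  cb <- params$conv[[band]]
  g <- nrow(ssam)
  tab <- im2col_table(g)
  X <- matrix(as.vector(ssam), 1, g * g)
  for (layer in 1:3) {
    K <- cb[[sprintf("K%d", layer)]]
    bias <- cb[[sprintf("c%d", layer)]]
    X <- selu(K %*% im2col(X, tab) + bias)
  }
  array(t(X), dim = c(g, g, nrow(X)))
}

#' Adaptive ECA kernel size
#'
#' `k = |log2(C)/lambda + b/lambda|`, rounded to the nearest odd integer
#' (ties rounded up) so the channel convolution has a symmetric receptive
#' field; never below 1.
#'
#' @param C Channel count (>= 1).
#' @param lam,b ECA hyperparameters (defaults 2 and 1).
#' @return Odd integer kernel size.
#' @export
eca_kernel_size <- function(C, lam = 2, b = 1) {
  if (C < 1) stop("C must be >= 1")
  raw <- abs(log2(C) / lam + b / lam)
  lo <- 2 * floor((raw + 1) / 2) - 1          # largest odd <= raw (or raw-1)
  lo <- max(lo, 1)
  hi <- lo + 2
  k <- if ((raw - lo) < (hi - raw)) lo else hi # ties go up
  as.integer(max(k, 1))
}

#' Efficient channel attention across the per-band feature stacks
#'
#' Per band: global average pooling over the grid, a 1-D convolution of
#' adaptive kernel size across channels, a sigmoid gate, and channelwise
#' rescaling of the features. Gates are returned for the analysis module.
#'
#' @param encoded Named list (all four bands) of g x g x C arrays.
#' @param params An `ssam_params`.
#' @return List with `features` (reweighted stacks) and `gates`
#'   (bands x channels matrix of sigmoid gates in (0,1)).
#' @export
eca_attend <- function(encoded, params) {
  missing <- setdiff(band_names(), names(encoded))
  if (length(missing)) stop("missing band(s): ", paste(missing, collapse = ", "))
  we <- params$we
  k <- length(we)
  h <- (k - 1) / 2
  gates <- NULL
  features <- lapply(band_names(), function(b) {
    a <- encoded[[b]]
    d <- dim(a)
    Y <- matrix(a, d[1] * d[2], d[3])            # cells x channels
    p <- colMeans(Y)
    q <- vapply(seq_along(p), function(cc) {
      s <- 0
      for (j in seq_len(k)) {
        src <- cc + j - h - 1
        if (src >= 1 && src <= length(p)) s <- s + we[j] * p[src]
      }
      s
    }, 0)
    gate <- 1 / (1 + exp(-q))
    gates <<- rbind(gates, gate)
    array(sweep(Y, 2, gate, "*"), dim = d)
  })
  names(features) <- band_names()
  rownames(gates) <- band_names()
  list(features = features, gates = gates)
}

#' Softmax classification of the flattened feature vector
#'
#' @param x Flattened (possibly dropout-masked) feature vector.
#' @param params An `ssam_params`.
#' @return Class probability vector (length `n_classes`, sums to 1).
#' @export
classify_features <- function(x, params) {
  if (length(x) != ncol(params$Wd)) {
    stop("feature length ", length(x), " does not match classifier width ",
         ncol(params$Wd))
  }
  softmax_vec(as.vector(params$Wd %*% x + params$bd))
}

#' Regularized negative log-likelihood loss
#'
#' `-log(probs[label])` plus `l2_lambda` times the sum of squared weights
#' (biases excluded). A zero probability is clamped at 1e-12 with a
#' warning.
#'
#' @param probs Class probability vector.
#' @param label Class index in `{0, 1}`.
#' @param params An `ssam_params` (for the penalty term).
#' @param l2_lambda Penalty coefficient.
#' @return Scalar loss.
#' @export
model_loss <- function(probs, label, params, l2_lambda = 0) {
  stopifnot(label %in% c(0, 1))
  p <- probs[label + 1]
  if (p <= 0) {
    warning("zero predicted probability clamped at 1e-12")
    p <- 1e-12
  }
  -log(p) + if (l2_lambda > 0) l2_lambda * l2_penalty(params) else 0
}

#' Full forward pass of the SSAM network on one trial
#'
#' Per band: per-frame spatial self-attention, frame-importance weights,
#' steady-state activation map, CNN encoding; then ECA fusion across
#' bands, flattening, dropout (training mode only), and softmax
#' classification. All attention by-products are retained.
#'
#' @param topo A `topo_sequence` (all four bands, T >= 1).
#' @param params An `ssam_params`.
#' @param cfg A [model_config()] (defaults to the one attached to
#'   `params`).
#' @param training Logical; apply dropout when TRUE.
#' @param dropout_mask Optional precomputed mask (already scaled by
#'   `1/(1-rate)`); if NULL and `training`, a mask is drawn from the
#'   current RNG.
#' @param keep_attention Retain the per-frame cells x cells attention
#'   matrices (memory-heavy) in the output.
#' @return Object of class `ssam_forward`: `probs`, `ssam` (per band: `S`,
#'   `alpha`, `colmass`, optionally `attention`), `gates`, `x_raw`.
#' @export
ssam_forward <- function(topo, params, cfg = attr(params, "config"),
                         training = FALSE, dropout_mask = NULL,
                         keep_attention = FALSE) {
  mats <- topo_matrices(topo)
  if (!setequal(names(mats), band_names())) stop("need all four bands")
  g <- cfg$grid_size
  per_band <- lapply(band_names(), function(b) {
    Xb <- mats[[b]]
    T_n <- ncol(Xb)
    if (T_n < 1) stop("empty frame sequence")
    Zmat <- matrix(0, g * g, T_n)
    colmass_t <- matrix(0, g * g, T_n)
    attn <- if (keep_attention) vector("list", T_n)
    for (t in seq_len(T_n)) {
      sa <- spatial_attention(matrix(Xb[, t], g, g), params)
      Zmat[, t] <- as.vector(sa$Z)
      colmass_t[, t] <- colSums(sa$attention) / (g * g)
      if (keep_attention) attn[[t]] <- sa$attention
    }
    alpha <- frame_importance(Zmat, params)
    S <- compute_ssam(Zmat, alpha)
    out <- list(S = S, alpha = alpha,
                colmass = matrix(colmass_t %*% alpha, g, g))
    if (keep_attention) out$attention <- attn
    out
  })
  names(per_band) <- band_names()
  encoded <- lapply(band_names(), function(b) {
    cnn_encode(per_band[[b]]$S, b, params)
  })
  names(encoded) <- band_names()
  eca <- eca_attend(encoded, params)
  x_raw <- unlist(lapply(eca$features, as.vector), use.names = FALSE)
  x <- x_raw
  if (training) {
    if (is.null(dropout_mask)) {
      dropout_mask <- (stats::runif(length(x)) >= cfg$dropout_rate) /
        (1 - cfg$dropout_rate)
    }
    x <- x * dropout_mask
  }
  probs <- classify_features(x, params)
  structure(list(probs = probs, ssam = per_band, gates = eca$gates,
                 x_raw = x_raw), class = "ssam_forward")
}
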