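# Shared fixtures: tiny model configurations, random topographic inputs,
# and a straight-line nested-loop oracle for the attention stages that is
# kept deliberately independent of the package's vectorized code paths.

tiny_model_cfg <- function(grid_size = 9) {
  model_config(grid_size = grid_size, attention_embed_channels = 2L,
               frame_score_hidden = 3L, cnn_filters = c(2L, 3L, 4L),
               dropout_rate = 0, l2_lambda = 1e-3)
}

reduced_model_cfg <- function() {
  model_config(attention_embed_channels = 4L, cnn_filters = c(8L, 16L, 32L))
}

# topo_sequence with random values on the occupied cells (DE-like scale)
rand_topo <- function(T_n = 3, seed = 1, mean = 3, sd = 0.5, g = 9) {
  set.seed(seed)
  occ <- if (g == 9) ssam:::occupied_indices() else seq_len(g * g)
  maps <- lapply(ssam:::band_names(), function(b) {
    flat <- matrix(0, g * g, T_n)
    flat[occ, ] <- stats::rnorm(length(occ) * T_n, mean, sd)
    array(flat, c(g, g, T_n))
  })
  names(maps) <- ssam:::band_names()
  structure(list(maps = maps, layout_version = "test", window_s = 1,
                 meta = list()), class = "topo_sequence")
}

# short single-channel-of-interest recording for filter tests
sine_recording <- function(freq, fs = 128, dur = 4, amp = 1,
                           n_chan = 32) {
  tt <- (0:(fs * dur - 1)) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq * tt), each = n_chan),
                 n_chan, length(tt))
  raw_recording(data, fs, montage_channels()[seq_len(n_chan)])
}

fft_power_at <- function(x, fs, freq, half_width = 0.5) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  p <- Mod(stats::fft(x))^2 / n
  sum(p[f >= freq - half_width & f <= freq + half_width &
          f <= fs / 2])
}

# ---- nested-loop oracle for the attention stages (scores, softmax,
# recalibration, frame importance, steady-state map) ----------------------

oracle_spatial_attention <- function(x, wg, bg, wf, bf) {
  n <- length(x)
  ce <- length(wg)
  S <- matrix(0, n, n)
  for (i in 1:n) for (p in 1:n) {
    s <- 0
    for (cc in 1:ce) s <- s + (wg[cc] * x[i] + bg[cc]) * (wf[cc] * x[p] + bf[cc])
    S[i, p] <- s
  }
  A <- matrix(0, n, n)
  for (i in 1:n) {
    row <- S[i, ]
    ex <- exp(row - max(row))
    A[i, ] <- ex / sum(ex)
  }
  z <- numeric(n)
  for (i in 1:n) for (p in 1:n) z[i] <- z[i] + A[i, p] * x[p]
  list(A = A, z = z)
}

oracle_ssam <- function(Xmat, params) {
  n <- nrow(Xmat)
  T_n <- ncol(Xmat)
  Z <- matrix(0, n, T_n)
  for (t in 1:T_n) {
    Z[, t] <- oracle_spatial_attention(Xmat[, t], params$wg, params$bg,
                                       params$wf, params$bf)$z
  }
  zbar <- numeric(n)
  for (i in 1:n) zbar[i] <- sum(Z[i, ]) / T_n
  Cv <- as.numeric(params$Wa %*% zbar)
  e <- numeric(T_n)
  for (t in 1:T_n) {
    u <- as.numeric(params$W2 %*% Z[, t] + params$W1 %*% Cv + params$b2)
    h <- ifelse(u > 0, u, exp(u) - 1)
    I_t <- as.numeric(params$W3 %*% h + params$b1)
    e[t] <- sum(I_t * Z[, t])
  }
  ex <- exp(e - max(e))
  alpha <- ex / sum(ex)
  S_map <- numeric(n)
  for (t in 1:T_n) S_map <- S_map + alpha[t] * Z[, t]
  list(Z = Z, alpha = alpha, S = S_map)
}

# quick synthetic features for training tests: strongly separable topo
# sequences built directly (no filtering), so training converges in a few
# epochs
toy_separable_features <- function(n_per_class = 12, gap = 2, seed = 1) {
  set.seed(seed)
  topo <- list()
  labels <- integer(0)
  for (cl in c(0L, 1L)) {
    for (i in seq_len(n_per_class)) {
      tp <- rand_topo(T_n = if (cl == 0) 4 else 5,
                      seed = seed * 1000 + cl * 100 + i)
      if (cl == 1) {
        occ <- ssam:::occupied_indices()
        sel <- occ[1:5]
        for (b in ssam:::band_names()) {
          tp$maps[[b]][cbind(rep((sel - 1) %% 9 + 1, dim(tp$maps[[b]])[3]),
                             rep((sel - 1) %/% 9 + 1, dim(tp$maps[[b]])[3]),
                             rep(seq_len(dim(tp$maps[[b]])[3]), each = 5))] <-
            tp$maps[[b]][cbind(rep((sel - 1) %% 9 + 1, dim(tp$maps[[b]])[3]),
                               rep((sel - 1) %/% 9 + 1,
                                   dim(tp$maps[[b]])[3]),
                               rep(seq_len(dim(tp$maps[[b]])[3]),
                                   each = 5))] + gap
        }
      }
      topo[[length(topo) + 1L]] <- tp
      labels <- c(labels, cl)
    }
  }
  list(topo = topo, labels = labels)
}
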