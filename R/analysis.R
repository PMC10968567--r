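# Post-hoc interpretation of trained models: which electrodes the attention
# concentrates on, how much each band contributes at the ECA stage, how the
# steady-state map correlates with time, and which electrode pairs / cells
# are statistically associated with the class difference.

as_output_list <- function(outputs) {
  if (inherits(outputs, "ssam_forward")) outputs <- list(outputs)
  if (!length(outputs)) stop("empty model output collection")
  outputs
}

#' Thresholded attention topomap and electrode ranking
#'
#' Per-trial, per-band attention column masses (how much each grid position
#' is attended to, weighted by the frame-importance weights alpha) are
#' averaged over trials and bands, min-max normalized to [0, 1] over the
#' occupied cells, and thresholded. Electrodes are ranked by normalized
#' importance.
#'
#' @param outputs List of `ssam_forward` objects (from [ssam_forward()]).
#' @param threshold Fraction in [0, 1]; cells with normalized importance
#'   `>= threshold` enter the mask.
#' @param layout A `grid_layout`.
#' @return Object of class `attention_topomap`: `map` (9x9 normalized),
#'   `mask` (9x9 logical, unoccupied cells FALSE), `threshold`, `ranking`
#'   (data.frame channel/importance, descending).
#' @export
attention_topomap <- function(outputs, threshold = 0.5,
                              layout = grid_layout()) {
  outputs <- as_output_list(outputs)
  stopifnot(threshold >= 0, threshold <= 1)
  g <- layout$grid_size
  acc <- matrix(0, g, g)
  n_terms <- 0
  for (out in outputs) {
    for (b in names(out$ssam)) {
      acc <- acc + out$ssam[[b]]$colmass
      n_terms <- n_terms + 1
    }
  }
  acc <- acc / n_terms
  occ <- occupied_indices(layout)
  v <- acc[occ]
  rng <- range(v)
  v_norm <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(1, length(v))
  map <- matrix(0, g, g)
  map[occ] <- v_norm
  mask <- matrix(FALSE, g, g)
  mask[occ] <- v_norm >= threshold
  ranking <- data.frame(channel = montage_channels(), importance = v_norm)
  ranking <- ranking[order(-ranking$importance), ]
  rownames(ranking) <- NULL
  structure(list(map = map, mask = mask, threshold = threshold,
                 ranking = ranking), class = "attention_topomap")
}

#' Per-band contribution shares from the ECA gates
#'
#' Mean sigmoid gate mass per band over channels and trials, normalized
#' across the four bands to sum to 1.
#'
#' @param outputs List of `ssam_forward` objects.
#' @return Named numeric vector of four non-negative shares summing to 1.
#' @export
band_contributions <- function(outputs) {
  outputs <- as_output_list(outputs)
  if (is.null(outputs[[1]]$gates)) stop("model outputs retain no ECA gates")
  mass <- rowMeans(vapply(outputs, function(out) rowMeans(out$gates),
                          numeric(4)))
  mass / sum(mass)
}

#' Correlation between time frames and the steady-state map
#'
#' For each trial and band, the Pearson correlation between every frame
#' (occupied cells as a vector) and the SSAM map over the same cells.
#' Values below `threshold` are zeroed in the displayed matrix; raw values
#' are retained. Zero-variance frames yield `NA` (recorded as missing).
#'
#' @param topo_list List of `topo_sequence` (typically recomputed at a 2 s
#'   window), or a single one.
#' @param ssam_maps Named per-band list of 9x9 maps, or an `ssam_forward`
#'   (its per-band `S` maps are used).
#' @param threshold Correlation threshold for display (default 0.6).
#' @param layout A `grid_layout`.
#' @return List with `raw` and `thresholded`: per band a time x trial
#'   matrix (NA-padded for shorter trials), plus `band_mean` (raw,
#'   averaged over bands).
#' @export
temporal_state_correlation <- function(topo_list, ssam_maps, threshold = 0.6,
                                       layout = grid_layout()) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (inherits(topo_list, "topo_sequence")) topo_list <- list(topo_list)
  if (inherits(ssam_maps, "ssam_forward")) {
    ssam_maps <- lapply(ssam_maps$ssam, `[[`, "S")
  }
  occ <- occupied_indices(layout)
  t_max <- max(vapply(topo_list, function(tp) dim(tp$maps[[1]])[3], 0L))
  raw <- lapply(band_names(), function(b) {
    s_vec <- as.vector(ssam_maps[[b]])[occ]
    m <- matrix(NA_real_, t_max, length(topo_list))
    for (j in seq_along(topo_list)) {
      a <- topo_list[[j]]$maps[[b]]
      frames <- matrix(a, layout$grid_size^2, dim(a)[3])[occ, , drop = FALSE]
      for (t in seq_len(ncol(frames))) {
        f <- frames[, t]
        m[t, j] <- if (stats::sd(f) > 0 && stats::sd(s_vec) > 0) {
          stats::cor(f, s_vec)
        } else NA_real_
      }
    }
    m
  })
  names(raw) <- band_names()
  thresholded <- lapply(raw, function(m) {
    m[!is.na(m) & m < threshold] <- 0
    m
  })
  band_mean <- Reduce(`+`, raw) / length(raw)
  list(raw = raw, thresholded = thresholded, band_mean = band_mean,
       threshold = threshold)
}

#' Inter-electrode connectivity of DE time series
#'
#' Per band, the Pearson correlation between every electrode pair's
#' concatenated DE time series across trials, with p-values from
#' circular-shift surrogates (each channel independently rotated in time,
#' preserving its autocorrelation while destroying cross-channel
#' alignment).
#'
#' @param de_list List of `de_sequence` objects (one per trial).
#' @param n_perm Number of surrogate permutations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `connectivity_result`: per-band 32x32 `r` and
#'   `p` matrices (symmetric; unit/NA diagonal handling as below: `r` has
#'   unit diagonal, `p` diagonal is NA). Constant channels give NA rows.
#' @export
electrode_connectivity <- function(de_list, n_perm = 1000, seed = 1L) {
  if (inherits(de_list, "de_sequence")) de_list <- list(de_list)
  set.seed(as.integer(seed))
  chans <- de_list[[1]]$channel_names
  res_r <- list()
  res_p <- list()
  for (b in names(de_list[[1]]$de)) {
    X <- do.call(cbind, lapply(de_list, function(d) d$de[[b]]))  # 32 x N
    N <- ncol(X)
    if (N < 3) stop("need at least 3 time points per sequence")
    const <- apply(X, 1, stats::sd) == 0
    r_obs <- suppressWarnings(stats::cor(t(X)))
    diag(r_obs) <- 1
    r_obs[const, ] <- NA_real_
    r_obs[, const] <- NA_real_
    count <- matrix(0, nrow(X), nrow(X))
    for (perm in seq_len(n_perm)) {
      shifts <- sample(N - 1, nrow(X), replace = TRUE)
      Xp <- X
      for (i in seq_len(nrow(X))) {
        s <- shifts[i]
        Xp[i, ] <- X[i, c((s + 1):N, 1:s)]
      }
      r_perm <- suppressWarnings(stats::cor(t(Xp)))
      count <- count + (abs(r_perm) >= abs(r_obs))
    }
    p <- (1 + count) / (1 + n_perm)
    p[const, ] <- NA_real_
    p[, const] <- NA_real_
    diag(p) <- NA_real_
    dimnames(r_obs) <- dimnames(p) <- list(chans, chans)
    res_r[[b]] <- r_obs
    res_p[[b]] <- p
  }
  structure(list(r = res_r, p = res_p, n_perm = n_perm),
            class = "connectivity_result")
}

#' Edge list from a connectivity result
#'
#' One row per electrode pair and band; doubles as circle-plot input.
#'
#' @param res A `connectivity_result`.
#' @param r_threshold Keep edges with `|r| >= r_threshold` (default 0,
#'   keep all).
#' @param p_threshold Keep edges with `p < p_threshold` (default 1).
#' @return data.frame with columns electrode_a, electrode_b, band, r, p.
#' @export
connectivity_edges <- function(res, r_threshold = 0, p_threshold = 1) {
  rows <- list()
  for (b in names(res$r)) {
    r <- res$r[[b]]
    p <- res$p[[b]]
    chans <- rownames(r)
    for (i in seq_len(nrow(r) - 1)) {
      for (j in (i + 1):ncol(r)) {
        if (is.na(r[i, j])) next
        if (abs(r[i, j]) >= r_threshold && p[i, j] < p_threshold) {
          rows[[length(rows) + 1]] <- data.frame(
            electrode_a = chans[i], electrode_b = chans[j], band = b,
            r = r[i, j], p = p[i, j])
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(electrode_a = character(), electrode_b = character(),
                      band = character(), r = numeric(), p = numeric()))
  }
  do.call(rbind, rows)
}

#' Trial-averaged DE summaries per electrode and band
#'
#' @param de_list List of `de_sequence` objects.
#' @return Array trials x electrodes x bands of trial-mean DE.
#' @export
de_summary <- function(de_list) {
  if (inherits(de_list, "de_sequence")) de_list <- list(de_list)
  bands <- names(de_list[[1]]$de)
  chans <- de_list[[1]]$channel_names
  arr <- array(0, dim = c(length(de_list), length(chans), length(bands)),
               dimnames = list(NULL, chans, bands))
  for (i in seq_along(de_list)) {
    for (b in seq_along(bands)) {
      arr[i, , b] <- rowMeans(de_list[[i]]$de[[bands[b]]])
    }
  }
  arr
}

#' Per-electrode, per-band permutation significance screen
#'
#' Two-sample permutation test on the difference of class means of
#' trial-averaged DE, one cell per electrode x band. Raw p-values are
#' flagged at `alpha_level` (no multiple-testing correction, matching the
#' screening use); a Benjamini-Hochberg column is emitted alongside but
#' not used for the flags.
#'
#' @param features Array trials x electrodes x bands (see [de_summary()]),
#'   or a list of `de_sequence`.
#' @param labels 0/1 class labels, one per trial.
#' @param alpha_level Significance level for the flags (default 0.05).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return data.frame with electrode, band, class means, difference, `p`,
#'   `p_bh`, `significant`.
#' @export
significance_screen <- function(features, labels, alpha_level = 0.05,
                                n_perm = 10000, seed = 1L) {
  if (is.list(features)) features <- de_summary(features)
  labels <- as.integer(labels)
  stopifnot(dim(features)[1] == length(labels))
  if (length(unique(labels)) < 2) stop("both classes required")
  if (min(table(labels)) < 5) stop("need at least 5 trials per class")
  set.seed(as.integer(seed))
  n <- length(labels)
  w_obs <- ifelse(labels == 1, 1 / sum(labels == 1), -1 / sum(labels == 0))
  # permuted contrast weights, shared across cells (n x n_perm)
  W <- vapply(seq_len(n_perm), function(i) sample(w_obs), numeric(n))
  chans <- dimnames(features)[[2]]
  bands <- dimnames(features)[[3]]
  rows <- list()
  for (b in seq_along(bands)) {
    Xb <- features[, , b]                      # trials x electrodes
    obs <- as.vector(crossprod(Xb, w_obs))     # class-mean differences
    perm <- crossprod(Xb, W)                   # electrodes x n_perm
    p <- (1 + rowSums(abs(perm) >= abs(obs))) / (1 + n_perm)
    m1 <- colMeans(Xb[labels == 1, , drop = FALSE])
    m0 <- colMeans(Xb[labels == 0, , drop = FALSE])
    rows[[b]] <- data.frame(electrode = chans, band = bands[b],
                            mean_class0 = m0, mean_class1 = m1,
                            diff = obs, p = p)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha_level
  rownames(out) <- NULL
  out
}
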