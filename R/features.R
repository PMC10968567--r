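# Differential-entropy features on nonoverlapping windows, mapped onto the
# 9x9 scalp grid. For an (approximately) Gaussian windowed EEG segment the
# differential entropy has the closed form 0.5 * log(2*pi*e*sigma^2) nats,
# which is what makes DE both cheap and analytically checkable: scaling a
# signal by c shifts every DE value by exactly log(c).

#' Differential entropy of one window (nats)
#'
#' Gaussian closed form `0.5 * log(2*pi*e*var(x))` with the unbiased (n-1)
#' variance estimator.
#'
#' @param window Numeric vector, length >= 2, non-constant.
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(window) {
  if (length(window) < 2) stop("window must contain at least 2 samples")
  v <- stats::var(window)
  if (!is.finite(v) || v <= 0) {
    stop("degenerate window: zero variance, differential entropy undefined")
  }
  0.5 * log(2 * pi * exp(1) * v)
}

#' Windowed DE sequences for all bands
#'
#' Slices each band signal into nonoverlapping windows of `window_s`
#' seconds and computes per-channel differential entropy in each window.
#' A trailing partial window is dropped, never padded.
#'
#' @param bands A `band_signals` from [decompose_bands()].
#' @param window_s Window length in seconds (default 1).
#' @return Object of class `de_sequence`: list with `de` (named list of
#'   32 x T matrices, one per band), `window_s`, `fs`, `channel_names`,
#'   `meta`.
#' @export
extract_de_sequence <- function(bands, window_s = 1) {
  stopifnot(inherits(bands, "band_signals"))
  w <- round(window_s * bands$fs)
  n <- ncol(bands$bands[[1]])
  T_n <- floor(n / w)
  if (T_n < 1) {
    stop("trial shorter than one window (", window_s, " s): empty sequence")
  }
  de <- lapply(bands$bands, function(x) {
    out <- matrix(0, nrow(x), T_n)
    for (t in seq_len(T_n)) {
      seg <- x[, ((t - 1) * w + 1):(t * w), drop = FALSE]
      mu <- rowMeans(seg)
      v <- rowSums((seg - mu)^2) / (w - 1)
      if (any(v <= 0)) stop("degenerate window: zero variance channel")
      out[, t] <- 0.5 * log(2 * pi * exp(1) * v)
    }
    rownames(out) <- bands$channel_names
    out
  })
  structure(list(de = de, window_s = window_s, fs = bands$fs,
                 channel_names = bands$channel_names, meta = bands$meta),
            class = "de_sequence")
}

#' Build the per-band 9x9 topographic frame sequence
#'
#' Maps each window's 32 DE values onto the scalp grid, yielding per band a
#' stack of T 9x9 frames (the model input). Unoccupied cells are exactly 0.
#'
#' @param de A `de_sequence`.
#' @param layout A `grid_layout`.
#' @return Object of class `topo_sequence`: list with `maps` (named list of
#'   9 x 9 x T arrays), `layout_version`, `window_s`, `meta`.
#' @export
build_topo_sequence <- function(de, layout = grid_layout()) {
  stopifnot(inherits(de, "de_sequence"))
  g <- layout$grid_size
  occ <- layout$index
  maps <- lapply(de$de, function(m) {
    ord <- match(layout$channel, toupper(rownames(m)))
    if (anyNA(ord)) ord <- match(layout$channel, montage_channels())
    T_n <- ncol(m)
    flat <- matrix(0, g * g, T_n)
    flat[occ, ] <- m[ord, , drop = FALSE]
    array(flat, dim = c(g, g, T_n))
  })
  structure(list(maps = maps, layout_version = layout$version,
                 window_s = de$window_s, meta = de$meta),
            class = "topo_sequence")
}

# Per-band cells x T matrix view of a topo_sequence (model input layout).
topo_matrices <- function(topo) {
  lapply(topo$maps, function(a) {
    d <- dim(a)
    matrix(a, d[1] * d[2], d[3])
  })
}

#' Full feature pipeline for a dataset
#'
#' Convenience wrapper: band decomposition, DE extraction, grid mapping for
#' every trial of a dataset.
#'
#' @param dataset An `eeg_dataset`.
#' @param window_s DE window in seconds (default 1).
#' @param layout A `grid_layout`.
#' @param order Butterworth order for the band filters.
#' @return List with `topo` (list of `topo_sequence`) and `labels`.
#' @export
prepare_trials <- function(dataset, window_s = 1, layout = grid_layout(),
                           order = 3) {
  topo <- lapply(dataset$trials, function(rec) {
    build_topo_sequence(
      extract_de_sequence(decompose_bands(rec, order = order), window_s),
      layout)
  })
  list(topo = topo, labels = as.integer(dataset$labels))
}

#' Persist a topo sequence as a portable JSON container
#'
#' Arrays are stored band-wise with a metadata block (layout version,
#' window length, trial metadata).
#'
#' @param topo A `topo_sequence`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_topo_sequence <- function(topo, path) {
  obj <- list(metadata = list(layout_version = topo$layout_version,
                              window_s = topo$window_s, meta = topo$meta,
                              dims = lapply(topo$maps, dim)),
              maps = lapply(topo$maps, as.vector))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a topo sequence saved by [save_topo_sequence()]
#'
#' @param path JSON path.
#' @return A `topo_sequence`.
#' @export
load_topo_sequence <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  maps <- lapply(names(obj$maps), function(b) {
    array(obj$maps[[b]], dim = unlist(obj$metadata$dims[[b]]))
  })
  names(maps) <- names(obj$maps)
  structure(list(maps = maps,
                 layout_version = obj$metadata$layout_version,
                 window_s = obj$metadata$window_s,
                 meta = obj$metadata$meta),
            class = "topo_sequence")
}
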