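# 32-channel 10-20 montage and its 9x9 scalp grid.
#
# The grid embeds the electrodes into a 9x9 matrix that preserves scalp
# geometry: rows run anterior (row 1) to posterior (row 9), columns run left
# (col 1) to right (col 9), midline electrodes sit in column 5, and the
# mastoids M1/M2 occupy the lateral extremes of the central row. Cells with
# no electrode are identically zero in every feature frame.

#' The 32-channel montage, in canonical order
#'
#' Channel names of the international 10-20 system montage used throughout
#' the package. All channel-indexed objects follow this order.
#'
#' @return Character vector of 32 channel labels.
#' @export
montage_channels <- function() {
  c("FP1", "FPZ", "FP2", "F7", "F3", "FZ", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "CZ", "C4", "T8", "M2",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "PZ", "P4", "P8",
    "POZ", "O1", "OZ", "O2")
}

#' Scalp grid layout mapping channels to 9x9 cells
#'
#' Loads the versioned electrode-to-grid assignment shipped with the package
#' (or a user-supplied CSV with columns `channel,row,col`, rows/cols 0-based
#' as in the file format). The layout is validated against the structural
#' invariants: injective placement of all 32 channels, prefrontal channels in
#' the first row, occipital channels in the last, left-hemisphere channels
#' left of the midline column and right-hemisphere channels right of it.
#'
#' @param file Optional path to an alternative layout CSV.
#' @return Object of class `grid_layout`: list with `channel` (names),
#'   `row`, `col` (1-based integer positions), `grid_size`, `version`, and
#'   `index` (linear column-major cell index per channel).
#' @export
grid_layout <- function(file = NULL) {
  version <- if (is.null(file)) "v1" else basename(file)
  if (is.null(file)) {
    file <- system.file("extdata", "grid_layout_v1.csv", package = "ssam")
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "row", "col") %in% names(tab)))
  layout <- structure(list(
    channel = toupper(tab$channel),
    row = as.integer(tab$row) + 1L,
    col = as.integer(tab$col) + 1L,
    grid_size = 9L,
    version = version
  ), class = "grid_layout")
  layout$index <- (layout$col - 1L) * layout$grid_size + layout$row
  validate_grid_layout(layout)
  layout
}

#' Validate a grid layout against the montage invariants
#'
#' @param layout A `grid_layout`.
#' @return The layout, invisibly; errors if any invariant fails.
#' @export
validate_grid_layout <- function(layout) {
  g <- layout$grid_size
  chans <- montage_channels()
  if (!setequal(layout$channel, chans) || length(layout$channel) != 32L) {
    stop("layout must place exactly the 32 montage channels")
  }
  if (any(layout$row < 1L | layout$row > g | layout$col < 1L | layout$col > g)) {
    stop("grid positions must lie in 1..", g)
  }
  if (anyDuplicated(layout$index)) stop("grid placement must be injective")
  pos <- function(ch) layout$row[match(ch, layout$channel)]
  colof <- function(ch) layout$col[match(ch, layout$channel)]
  if (any(pos(c("FP1", "FPZ", "FP2")) != 1L)) {
    stop("prefrontal channels must occupy the first (anterior) row")
  }
  if (any(pos(c("O1", "OZ", "O2")) != g)) {
    stop("occipital channels must occupy the last (posterior) row")
  }
  mid <- (g + 1L) %/% 2L
  left <- c("FP1", "F7", "F3", "FC5", "FC1", "M1", "T7", "C3", "CP5", "CP1",
            "P7", "P3", "O1")
  right <- c("FP2", "F8", "F4", "FC6", "FC2", "M2", "T8", "C4", "CP6", "CP2",
             "P8", "P4", "O2")
  midline <- c("FPZ", "FZ", "CZ", "PZ", "POZ", "OZ")
  if (any(colof(left) >= mid)) stop("left-hemisphere channels must lie left of the midline column")
  if (any(colof(right) <= mid)) stop("right-hemisphere channels must lie right of the midline column")
  if (any(colof(midline) != mid)) stop("midline channels must lie in the midline column")
  invisible(layout)
}

#' Map a 32-channel value vector onto the 9x9 grid
#'
#' Occupied cells receive their channel's value; the 49 unoccupied cells are
#' zero. If `values` is named, channels are matched by name (case
#' insensitive); otherwise canonical montage order is assumed.
#'
#' @param values Numeric vector of length 32, optionally named by channel.
#' @param layout A `grid_layout` (default: packaged layout).
#' @return 9x9 numeric matrix.
#' @export
map_to_grid <- function(values, layout = grid_layout()) {
  if (length(values) != length(layout$channel)) {
    stop("`values` must have length ", length(layout$channel),
         ", got ", length(values))
  }
  if (!is.null(names(values))) {
    idx <- match(layout$channel, toupper(names(values)))
    if (anyNA(idx)) stop("missing channels: ",
                         paste(layout$channel[is.na(idx)], collapse = ", "))
    values <- values[idx]
  } else {
    values <- values[match(layout$channel, montage_channels())]
  }
  g <- layout$grid_size
  m <- matrix(0, g, g)
  m[layout$index] <- as.numeric(values)
  m
}

#' Recover the 32-channel vector from a grid frame
#'
#' Inverse of [map_to_grid()] on occupied cells; returned in canonical
#' montage order, named.
#'
#' @param m 9x9 numeric matrix.
#' @param layout A `grid_layout`.
#' @return Named numeric vector of length 32.
#' @export
grid_to_vector <- function(m, layout = grid_layout()) {
  stopifnot(is.matrix(m), all(dim(m) == layout$grid_size))
  v <- m[layout$index]
  names(v) <- layout$channel
  v[montage_channels()]
}

# Linear (column-major) indices of occupied cells, in montage order.
occupied_indices <- function(layout = grid_layout()) {
  layout$index[match(montage_channels(), layout$channel)]
}
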