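# Minimal European Data Format (EDF) I/O: ASCII header plus 16-bit
# little-endian integer records, one trial per file. Covers the plain EDF
# profile (no EDF+ annotations). Values are scaled through the per-signal
# physical/digital calibration fields, so a write/read round trip is exact
# up to 16-bit quantization of the channel's amplitude range.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' @param rec A [raw_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  data <- rec$data
  ns <- nrow(data)
  n <- ncol(data)
  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1  # avoid zero calibration span
  dig_min <- -32768L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr(paste("trial", rec$trial_id, "class", rec$class_label), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(1, 8)                            # one data record per file
  wr(format(n / rec$fs, digits = 10), 8)
  wr(ns, 4)
  for (f in rec$channel_names) wr(f, 16)
  for (i in seq_len(ns)) wr("", 80)                 # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(phys_min[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(phys_max[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)                 # prefiltering
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (phys_max[i] - phys_min[i])
    dig <- round((data[i, ] - phys_min[i]) * scale) + dig_min
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any single-record EDF)
#'
#' Channel labels are matched case-insensitively against the montage when
#' all 32 montage channels are present, in which case rows are reordered to
#' canonical montage order.
#'
#' @param path EDF file path.
#' @param class_label Optional class label to stamp on the recording.
#' @return A [raw_recording()].
#' @export
read_edf <- function(path, class_label = NA_integer_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)                                # date, time
  rd(8)                                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- toupper(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  data <- matrix(0, ns, sum(spr[1] * n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
        (dig_max[i] - dig_min[i]) + phys_min[i]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  fs <- spr[1] / (dur / 1)
  trial_id <- sub("^trial ", "", sub(" class.*$", "", rec_id))
  if (is.na(class_label) && grepl("class [01]", rec_id)) {
    class_label <- as.integer(sub(".*class ([01]).*", "\\1", rec_id))
  }
  if (setequal(labels, montage_channels())) {
    ord <- match(montage_channels(), labels)
    data <- data[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  raw_recording(data, fs, labels, subject_id, trial_id, class_label)
}

#' Write a dataset as EDF files plus a label sidecar table
#'
#' One EDF file per trial and a `labels.csv` with columns
#' `trial_id, subject_id, class, duration, file`.
#'
#' @param dataset An `eeg_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_edf <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$trials), function(i) {
    rec <- dataset$trials[[i]]
    fname <- sprintf("%s.edf", rec$trial_id)
    write_edf(rec, file.path(dir, fname))
    data.frame(trial_id = rec$trial_id, subject_id = rec$subject_id,
               class = rec$class_label,
               duration = ncol(rec$data) / rec$fs, file = fname)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset_edf()]
#'
#' @param dir Directory containing EDF files and `labels.csv`.
#' @return An `eeg_dataset` (with `config = NULL`).
#' @export
read_dataset_edf <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(tab)), function(i) {
    read_edf(file.path(dir, tab$file[i]), class_label = tab$class[i])
  })
  structure(list(trials = trials, labels = as.integer(tab$class),
                 config = NULL), class = "eeg_dataset")
}
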