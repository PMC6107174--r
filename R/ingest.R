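#' Construct a displacement series
#'
#' A displacement series is the basic analysis unit: a nonnegative sequence
#' `u(t)` of frame-to-frame postural displacements, sampled at a fixed rate,
#' with subject and condition labels. `u(t)` is treated as a mass-like
#' measure, so negative values are rejected.
#'
#' @param u numeric vector of nonnegative displacement values.
#' @param sample_rate sampling rate in Hz.
#' @param subject_id subject label.
#' @param condition condition code: `1` = wind stimulation, `0` = no wind.
#' @param onset_index 0-based sample offset at which stimulation begins;
#'   block partitioning starts there. Whole-series measures ignore it.
#'
#' @return An object of class `displacement_series`.
#' @export
displacement_series <- function(u, sample_rate = 50, subject_id = NA_character_,
                                condition = NA_integer_, onset_index = 0L) {
  u <- as.numeric(u)
  if (length(u) < 1L) stop("displacement series must contain at least one sample")
  if (anyNA(u) || any(!is.finite(u))) stop("displacement values must be finite")
  if (any(u < 0)) stop("displacement values must be nonnegative")
  if (onset_index < 0) stop("onset_index must be >= 0")
  structure(
    list(u = u, sample_rate = sample_rate,
         subject_id = as.character(subject_id),
         condition = condition,
         onset_index = as.integer(onset_index)),
    class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf("<displacement_series> %d samples @ %g Hz, subject %s, condition %s\n",
              length(x$u), x$sample_rate, x$subject_id,
              as.character(x$condition)))
  invisible(x)
}

#' @export
length.displacement_series <- function(x) length(x$u)

#' Euclidean displacement from a 3-D position series
#'
#' Converts a tracked 3-D position series into a postural-displacement
#' series: the Euclidean distance between each consecutive pair of points.
#' An n-sample position series yields n - 1 displacements; metadata is
#' propagated.
#'
#' @param pos data frame or matrix with columns `x`, `y`, `z` (a `t` column,
#'   if present, is ignored for the distance computation).
#' @inheritParams displacement_series
#' @return A [displacement_series].
#' @export
to_displacement <- function(pos, sample_rate = 50, subject_id = NA_character_,
                            condition = NA_integer_, onset_index = 0L) {
  pos <- as.data.frame(pos)
  need <- c("x", "y", "z")
  if (!all(need %in% names(pos))) {
    if (ncol(pos) >= 3 && !any(need %in% names(pos))) {
      names(pos)[1:3] <- need
    } else {
      stop("position input must have columns x, y, z")
    }
  }
  m <- as.matrix(pos[, need])
  if (nrow(m) < 2L) stop("need at least 2 position samples")
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite coordinates in position series")
  d <- sqrt(rowSums(diff(m)^2))
  displacement_series(d, sample_rate = sample_rate, subject_id = subject_id,
                      condition = condition, onset_index = onset_index)
}

#' Partition a displacement series into contiguous analysis blocks
#'
#' Splits the series into `n_blocks` contiguous, non-overlapping blocks of
#' `block_length` samples each, starting at the series' stimulation onset.
#' Trailing partial data are discarded. The default 1000 samples at 50 Hz is
#' one 20-s block; four blocks are the standard repeated-measures design.
#'
#' @param d a [displacement_series].
#' @param block_length samples per block (default 1000).
#' @param n_blocks number of blocks (default 4).
#' @return A list of class `block_set` with one [displacement_series] per
#'   block; each inherits the parent metadata and carries a `block` index.
#' @export
partition_blocks <- function(d, block_length = 1000L, n_blocks = 4L) {
  stopifnot(inherits(d, "displacement_series"))
  onset <- d$onset_index
  need <- onset + block_length * n_blocks
  if (length(d$u) < need) {
    stop(sprintf(
      "series too short for %d blocks of %d samples from onset %d: have %d, need %d (short by %d)",
      n_blocks, block_length, onset, length(d$u), need, need - length(d$u)))
  }
  blocks <- lapply(seq_len(n_blocks), function(b) {
    i0 <- onset + (b - 1L) * block_length
    blk <- displacement_series(d$u[(i0 + 1L):(i0 + block_length)],
                               sample_rate = d$sample_rate,
                               subject_id = d$subject_id,
                               condition = d$condition)
    blk$block <- b
    blk
  })
  structure(blocks, class = "block_set", block_length = block_length)
}

# Autodetect the field separator of a delimited text file (tab or comma).
detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a displacement series from a delimited text file
#'
#' Accepts comma- or tab-delimited files (autodetected). Files with a
#' `displacement` column use it; single-column files are read as bare
#' values; files with a `sample_index` column keep only the value column.
#'
#' @param path file path.
#' @inheritParams displacement_series
#' @return A [displacement_series].
#' @export
read_displacement_series <- function(path, sample_rate = 50,
                                     subject_id = NA_character_,
                                     condition = NA_integer_,
                                     onset_index = 0L) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  tab <- read.table(path, sep = sep, header = header)
  col <- if ("displacement" %in% names(tab)) tab$displacement else tab[[ncol(tab)]]
  displacement_series(col, sample_rate = sample_rate, subject_id = subject_id,
                      condition = condition, onset_index = onset_index)
}

#' Read a 3-D position series from a delimited text file
#'
#' Expects columns `x`, `y`, `z` (optionally `t`); headerless three- or
#' four-column files are interpreted as (`x`,`y`,`z`[, `t` last dropped]).
#'
#' @inheritParams read_displacement_series
#' @return A data frame with columns `x`, `y`, `z`.
#' @export
read_position_series <- function(path) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  tab <- read.table(path, sep = sep, header = header)
  if (!all(c("x", "y", "z") %in% names(tab))) {
    if (ncol(tab) < 3) stop("position file must have at least 3 columns")
    names(tab)[1:3] <- c("x", "y", "z")
  }
  tab[, c("x", "y", "z")]
}

#' Write a displacement series to a delimited text file
#'
#' Writes two columns, `sample_index` (1-based) and `displacement`, at full
#' precision, so a write/read round trip reproduces the values exactly.
#'
#' @param d a [displacement_series].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_displacement_series <- function(d, path, sep = "\t") {
  stopifnot(inherits(d, "displacement_series"))
  tab <- data.frame(sample_index = seq_along(d$u),
                    displacement = format(d$u, digits = 17, trim = TRUE,
                                          scientific = FALSE))
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest has one row per series: `subject_id`, `condition`
#' (1 = wind, 0 = no wind), `file` (path relative to the manifest), and
#' optionally `onset_index` (0-based, default 0).
#'
#' @param path manifest file path (comma- or tab-delimited, with header).
#' @return Data frame with one row per series; `file` resolved against the
#'   manifest's directory.
#' @export
read_manifest <- function(path) {
  sep <- detect_sep(path)
  man <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "file")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(man$onset_index)) man$onset_index <- rep(0L, nrow(man))
  man$file <- file.path(dirname(path), man$file)
  man
}
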