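#' Multichannel boundary-voltage frame series
#'
#' Container for a time series of EIT boundary-voltage frames. With 16
#' electrodes in adjacent drive/measurement mode each frame holds
#' 16 x 13 = 208 voltages, so the data matrix is frames x 208; column
#' `ch<k>` is measurement channel k in the fixed ordering documented by
#' [build_sensitivity()] (drive pair index major, measurement pair minor).
#'
#' @param data Numeric matrix, frames (rows) x 208 channels (columns), all
#'   entries finite.
#' @param fs Sampling (frame) rate in Hz, default 20.
#' @return An object of class `"frame_series"`.
#' @export
frame_series <- function(data, fs = 20) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("frame series must contain at least one frame")
  if (ncol(data) != 208L) {
    stop("a frame has 16 x 13 = 208 channels; got ", ncol(data), " columns")
  }
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop("non-finite value at frame ", bad[1L], ", channel ", bad[2L])
  }
  colnames(data) <- sprintf("ch%03d", seq_len(208L))
  structure(list(data = data, fs = fs), class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("EIT frame series: ", nrow(x$data), " frames x ", ncol(x$data),
      " channels @ ", x$fs, " Hz (", round(nrow(x$data) / x$fs, 2),
      " s)\n", sep = "")
  invisible(x)
}

#' @export
dim.frame_series <- function(x) dim(x$data)

#' Read / write signals as CSV
#'
#' Signals are exchanged as plain CSV with a header row, one column per
#' channel (`signal` for a single channel, `ch001..ch208` for frames) and the
#' decimal point `.`; non-finite values are spelled `nan`. Time is implicit
#' from the sampling rate, which travels in a JSON sidecar (see
#' [write_sidecar()]).
#'
#' @param x Numeric vector, matrix, or [frame_series()].
#' @param path CSV file path.
#' @param fs Sampling rate recorded when reading into a frame series.
#' @return `write_signal_csv` invisibly returns `path`. `read_signal_csv`
#'   returns a numeric matrix (1 column per channel); `read_frames_csv`
#'   returns a [frame_series()].
#' @export
write_signal_csv <- function(x, path) {
  if (inherits(x, "frame_series")) x <- x$data
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L, dimnames = list(NULL, "signal"))
  if (is.null(colnames(x))) {
    colnames(x) <- if (ncol(x) == 1L) "signal" else sprintf("ch%03d", seq_len(ncol(x)))
  }
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "nan")
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("nan", "NaN", "NA"))
  as.matrix(df)
}

#' @rdname write_signal_csv
#' @export
read_frames_csv <- function(path, fs = 20) {
  frame_series(read_signal_csv(path), fs)
}

#' Provenance sidecar
#'
#' Writes `<path>.json` next to an output file, recording the command or
#' function, full configuration, seed and package version, so every artifact
#' of a run is reproducible from its sidecar alone.
#'
#' @param path The data file the sidecar describes.
#' @param command Character label of the producing operation.
#' @param config List of configuration values (coerced to JSON).
#' @param seed Integer seed used, or `NULL`.
#' @return Invisibly, the sidecar path.
#' @export
write_sidecar <- function(path, command, config = list(), seed = NULL) {
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package = "eitclean",
         version = tryCatch(as.character(utils::packageVersion("eitclean")),
                            error = function(e) "unknown"),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sidecar, auto_unbox = TRUE, digits = NA, force = TRUE
  )
  invisible(sidecar)
}
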