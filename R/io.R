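# File I/O: multichannel WAV (minimal RIFF reader/writer, PCM16 and IEEE
# float32), CSV signal matrices, layout JSON, PNG images.

#' Write a multichannel WAV file
#'
#' Minimal RIFF/WAVE writer supporting 32-bit IEEE float (default, lossless
#' for normalized pipeline signals) and 16-bit PCM.
#'
#' @param rec A [pcg_recording()] or [ecg_trace()].
#' @param path Output file path.
#' @param format `"float32"` or `"pcm16"`. PCM samples are clipped to
#'   `[-1, 1]`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  data <- if (inherits(rec, "ecg_trace")) matrix(rec$samples, nrow = 1) else rec$data
  fs <- rec$fs
  nch <- nrow(data); n <- ncol(data)
  bps <- if (format == "float32") 32L else 16L
  fmt_code <- if (format == "float32") 3L else 1L
  block <- nch * bps / 8
  data_bytes <- n * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(round(fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs) * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bps, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  interleaved <- as.vector(data)  # column-major = frame by frame
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    s <- as.integer(round(pmin(pmax(interleaved, -1), 1) * 32767))
    writeBin(s, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a multichannel WAV file
#'
#' Reads RIFF/WAVE files with 16-bit PCM or 32-bit IEEE float samples.
#'
#' @param path WAV file path.
#' @return A [pcg_recording()] (channels x samples).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt_code <- nch <- fs <- bps <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bps <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      n_frames <- sz / (nch * bps / 8)
      x <- if (fmt_code == 3L && bps == 32L)
        readBin(con, numeric(), n = nch * n_frames, size = 4, endian = "little")
      else if (fmt_code == 1L && bps == 16L)
        readBin(con, integer(), n = nch * n_frames, size = 2,
                endian = "little", signed = TRUE) / 32767
      else stop(sprintf("unsupported WAV format (code %d, %d bits)",
                        fmt_code, bps), call. = FALSE)
      return(pcg_recording(matrix(x, nrow = nch), fs))
    } else {
      readBin(con, raw(), n = sz + sz %% 2)
    }
  }
}

#' Read/write signal matrices as CSV
#'
#' CSV layout: one column per channel (named `ch<id>`), one row per sample;
#' the sampling rate is carried in a `# fs=<Hz>` comment on the first line.
#'
#' @param rec A [pcg_recording()].
#' @param path CSV file path.
#' @return `write_signal_csv()`: the path, invisibly. `read_signal_csv()`:
#'   a [pcg_recording()].
#' @export
write_signal_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- paste0("ch", rec$channel_ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# fs=", first))
    stop("missing '# fs=' header line", call. = FALSE)
  fs <- as.numeric(sub("^# fs=", "", first))
  df <- utils::read.csv(path, skip = 1)
  ids <- sub("^ch", "", names(df))
  pcg_recording(t(as.matrix(df)), fs, channel_ids = ids)
}

#' Read/write a sensor layout as JSON
#'
#' JSON object mapping channel id to `[x, y]` pixel coordinates.
#'
#' @param layout A [sensor_layout()].
#' @param path JSON file path.
#' @return `write_layout_json()`: the path, invisibly.
#'   `read_layout_json()`: a [sensor_layout()].
#' @export
write_layout_json <- function(layout, path) {
  obj <- stats::setNames(
    lapply(seq_len(nrow(layout$coords)),
           function(i) as.numeric(layout$coords[i, ])),
    as.character(layout$channel_ids))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- do.call(rbind, obj)
  sensor_layout(coords, channel_ids = names(obj))
}

#' Read/write an RGB image as PNG
#'
#' Thin wrappers over the png package that guarantee a 3-channel array in
#' `[0, 1]` (gray and RGBA inputs are expanded/truncated to RGB).
#'
#' @param path PNG file path.
#' @param image RGB array.
#' @return `read_image()`: `height x width x 3` array.
#'   `write_image()`: the path, invisibly.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
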