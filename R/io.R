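# Image and configuration I/O: 8-bit PNG or 16-bit TIFF pixels with a
# sidecar JSON carrying the full capture configuration and seed.

pulse_to_list <- function(pulse) {
  if (is_pulsed(pulse)) c(list(kind = "pulsed"), unclass(pulse))
  else c(list(kind = "constant"), unclass(pulse))
}

pulse_from_list <- function(x) {
  if (identical(x$kind, "constant")) constant_excitation(x$amplitude)
  else excitation_pulse(x$frequency, x$duty_cycle, x$phase, x$amplitude)
}

sensor_to_list <- function(sensor) unclass(sensor)

sensor_from_list <- function(x) {
  do.call(sensor_config, x[c("n_rows", "n_cols", "line_time", "exposure_time",
                             "bit_depth", "photon_scale", "read_noise_sigma",
                             "full_well", "readout_reversed")])
}

#' Write a capture to disk
#'
#' Pixels go to an 8-bit PNG or 16-bit TIFF depending on the sensor's bit
#' depth (or the file extension); the sensor/excitation configuration and
#' seed go to a sidecar `<path>.json`.
#'
#' @param capture A `capture_result` from [simulate_capture()].
#' @param path Output image path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_capture <- function(capture, path) {
  img <- capture$image / max_code(capture$sensor)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 16)
  } else {
    sl_abort("unsupported image extension (use .png or .tif)", "shutterlum_input_error")
  }
  meta <- list(sensor = sensor_to_list(capture$sensor),
               pulse = pulse_to_list(capture$pulse),
               seed = capture$seed, noise = capture$noise)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a capture image (and sidecar metadata) from disk
#'
#' @param path Image path written by [write_capture()] or any RGB PNG/TIFF.
#' @param bit_depth Bit depth used to rescale pixel values to integer codes;
#'   taken from the sidecar when present.
#' @return A list with `image` (integer array), and `sensor`, `pulse`,
#'   `seed`, `noise` when a sidecar JSON is found (else `NULL`s).
#' @export
read_capture <- function(path, bit_depth = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else sl_abort("unsupported image extension", "shutterlum_input_error")
  sidecar <- paste0(path, ".json")
  sensor <- pulse <- seed <- noise <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    sensor <- sensor_from_list(meta$sensor)
    pulse <- pulse_from_list(meta$pulse)
    seed <- meta$seed
    noise <- meta$noise
  }
  depth <- bit_depth %||% (if (!is.null(sensor)) sensor$bit_depth
                           else if (ext == "png") 8L else 16L)
  img <- round(raw * (2^depth - 1))
  storage.mode(img) <- "integer"
  list(image = img, sensor = sensor, pulse = pulse, seed = seed, noise = noise)
}

#' Write a row-profile CSV (row, time, per-channel means)
#'
#' @param capture A `capture_result`.
#' @param path Output CSV path.
#' @param col_start,col_end Optional 0-based half-open column range (default
#'   middle 50%).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(capture, path, col_start = NULL, col_end = NULL) {
  chans <- split_channels(capture$image)
  profs <- lapply(names(chans), function(ch) {
    extract_row_profile(chans[[ch]], col_start, col_end,
                        max_code = max_code(capture$sensor), name = ch)
  })
  rows <- seq_len(capture$sensor$n_rows) - 1
  df <- data.frame(row = rows,
                   time_s = rows_to_time(rows, capture$sensor),
                   R = profs[[1]]$values, G = profs[[2]]$values,
                   B = profs[[3]]$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
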