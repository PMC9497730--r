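#' Read and write planar series as multi-page TIFF + CSV sidecar
#'
#' The declared on-disk dtype is 16-bit unsigned integer gray levels: the
#' writer requires (or rounds, with a warning) integer pixel values in
#' `[0, 65535]`, and the reader restores them exactly, so
#' write-then-read is lossless on that dtype. The baseline (pre-contrast)
#' image is stored as the first TIFF page with an empty `time_h` in the
#' sidecar; subsequent pages carry the acquisition times in hours. The
#' sidecar also records the pixel size.
#'
#' @param series a [planar_series()].
#' @param path TIFF file path; the sidecar is written next to it as
#'   `<path without extension>_times.csv` unless `csv_path` is given.
#' @param csv_path optional explicit sidecar path.
#' @return `read_planar_series()`: a [planar_series()].
#'   `write_planar_series()`: `path`, invisibly.
#' @export
write_planar_series <- function(series, path, csv_path = NULL) {
  stopifnot(inherits(series, "planar_series"))
  csv_path <- csv_path %||% default_sidecar(path)
  pages <- c(list(series$baseline), series$images)
  vals <- unlist(lapply(pages, range))
  if (min(vals) < 0 || max(vals) > 65535)
    stopf("pixel values outside the 16-bit range [0, 65535]")
  rounded <- lapply(pages, round)
  if (max(abs(unlist(rounded) - unlist(pages))) > 0)
    warning("non-integer gray levels rounded to the 16-bit grid",
            call. = FALSE)
  tiff::writeTIFF(lapply(rounded, function(p) p / 65535), path,
                  bits.per.sample = 16L)
  df <- data.frame(index = seq_along(pages) - 1L,
                   time_h = c(NA_real_, series$times),
                   pixel_size_mm = series$pixel_size)
  write.csv(df, csv_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_planar_series
#' @export
read_planar_series <- function(path, csv_path = NULL) {
  csv_path <- csv_path %||% default_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 0L) stopf("empty TIFF stack")
  df <- read.csv(csv_path)
  if (!all(c("index", "time_h", "pixel_size_mm") %in% names(df)))
    stopf("sidecar must have columns index, time_h, pixel_size_mm")
  if (nrow(df) != length(pages))
    stopf("sidecar/stack page count mismatch: %d vs %d",
          nrow(df), length(pages))
  if (!is.na(df$time_h[1]))
    stopf("first sidecar row must be the baseline (empty time_h)")
  mats <- lapply(pages, function(p) round(p * 65535))
  planar_series(images = mats[-1], times = df$time_h[-1],
                pixel_size = df$pixel_size_mm[1], baseline = mats[[1]])
}

default_sidecar <- function(path) {
  paste0(sub("\\.[Tt][Ii][Ff][Ff]?$", "", path), "_times.csv")
}
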