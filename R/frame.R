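#' CLE intensity frame
#'
#' A single 2-D fluorescence frame in arbitrary units (au) with its physical
#' pixel pitch. Pixels are stored as a numeric matrix, row-major display
#' convention with (0, 0) at the top-left pixel center; all coordinates used
#' by the package are 0-based pixel-center coordinates (x = column - 1,
#' y = row - 1), converted to micrometres via \code{pitch_um}.
#'
#' @param pixels numeric matrix of non-negative finite intensities (au).
#' @param pitch_um physical size of one pixel (um), > 0.
#' @return An object of class \code{frame_image}: a list with elements
#'   \code{pixels} and \code{pitch_um}.
#' @examples
#' fr <- frame_image(matrix(0, 64, 64), pitch_um = 0.826)
#' fr
#' @export
frame_image <- function(pixels, pitch_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and >= 0", call. = FALSE)
  stopifnot_scalar_pos(pitch_um, "pitch_um")
  structure(list(pixels = pixels, pitch_um = pitch_um),
            class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  cat(sprintf(
    "<frame_image> %d x %d px, pitch %.4g um (FOV %.4g x %.4g um)\n",
    nrow(x$pixels), ncol(x$pixels), x$pitch_um,
    ncol(x$pixels) * x$pitch_um, nrow(x$pixels) * x$pitch_um))
  cat(sprintf("  intensity range: [%.4g, %.4g] au\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.frame_image <- function(x) dim(x$pixels)

#' Read and write grayscale frames
#'
#' Frames are stored as 16-bit grayscale TIFF (or 8-bit PNG). Intensities in
#' au are written as rounded integers clamped to the bit range, so frames
#' with integer-valued intensities in range (0-65535 for TIFF, 0-255 for
#' PNG) round-trip exactly. The physical
#' pixel pitch is carried by a JSON sidecar (\code{<file>.meta.json}) written
#' alongside the image; \code{read_frame} reads it back, or accepts an
#' explicit \code{pitch_um} override.
#'
#' @param path file path ending in \code{.tif}, \code{.tiff} or \code{.png}.
#' @param pitch_um pixel pitch in um; required when no sidecar exists.
#' @param frame a \code{\link{frame_image}}.
#' @return \code{read_frame} returns a \code{\link{frame_image}};
#'   \code{write_frame} returns \code{path} invisibly.
#' @export
read_frame <- function(path, pitch_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path),
    stop("unsupported frame format '", ext, "' for ", path, call. = FALSE))
  if (length(dim(img)) == 3L)
    stop("color image not supported (expected single-channel grayscale): ",
         path, call. = FALSE)
  if (ext == "png") img <- round(img * 255)
  meta_path <- paste0(path, ".meta.json")
  if (is.null(pitch_um)) {
    if (!file.exists(meta_path))
      stop("pitch_um not given and no sidecar found at ", meta_path,
           call. = FALSE)
    meta <- jsonlite::read_json(meta_path)
    pitch_um <- meta$pitch_um
  }
  frame_image(img, pitch_um = pitch_um)
}

#' @rdname read_frame
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "frame_image"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(
      pmin(pmax(round(frame$pixels), 0), 65535) / 65535, path,
      bits.per.sample = 16L),
    png = png::writePNG(
      pmin(pmax(round(frame$pixels), 0), 255) / 255, path),
    stop("unsupported frame format '", ext, "'", call. = FALSE))
  jsonlite::write_json(list(pitch_um = frame$pitch_um,
                            units = "au (integer counts)"),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read and write result tables
#'
#' CSV with a fixed header and no row names, so tables round-trip through
#' \code{read_table_csv(write_table_csv(x))}.
#'
#' @param x a data.frame.
#' @param path CSV file path.
#' @return \code{read_table_csv} returns a data.frame; \code{write_table_csv}
#'   returns \code{path} invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
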