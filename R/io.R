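# Image readers/writers. Internal intensity scale is always [0, 1]:
# PNG/TIFF samples are mapped by their bit depth; plain-text "raw array"
# files (.txt/.csv/.dat) hold intensities verbatim.

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("txt", "csv", "dat")) return("raw")
  stop("unsupported image format: .", ext, call. = FALSE)
}

#' Read a grayscale image
#'
#' Reads PNG (8/16-bit), TIFF (8/16-bit) or a plain-text array file into a
#' numeric matrix on the `[0, 1]` scale. Multi-channel inputs are reduced
#' to one channel by averaging (with a message).
#'
#' @param path file path; format chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.txt`/`.csv`/`.dat`).
#' @return A numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- image_format(path)
  img <- switch(fmt,
                png = png::readPNG(path),
                tiff = tiff::readTIFF(path),
                raw = as.matrix(read.table(path,
                                           sep = if (grepl("\\.csv$", path)) "," else "")))
  if (length(dim(img)) == 3) {
    message("multi-channel image reduced to one channel by averaging")
    img <- apply(img, c(1, 2), mean)
  }
  if (length(dim(img)) != 2) stop("image is not 2-D", call. = FALSE)
  storage.mode(img) <- "double"
  dimnames(img) <- NULL
  img
}

#' Write a grayscale image
#'
#' Writes a matrix to PNG (8-bit), TIFF (8 or 16-bit) or a plain-text array
#' file. Values are clipped to `[0, 1]` first; a warning reports how many
#' pixels were clipped.
#'
#' @param img numeric matrix.
#' @param path output path; format chosen by extension.
#' @param depth bits per sample for TIFF (8 or 16); PNG is written 8-bit,
#'   text files keep full precision.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, depth = 16) {
  check_image(img)
  fmt <- image_format(path)
  n_clip <- sum(img < 0 | img > 1)
  if (n_clip > 0)
    warning(sprintf("%d pixel(s) outside [0,1] clipped on write", n_clip),
            call. = FALSE)
  img <- pmin(pmax(img, 0), 1)
  if (fmt == "png") {
    png::writePNG(img, path)
  } else if (fmt == "tiff") {
    if (!depth %in% c(8, 16)) stop("TIFF depth must be 8 or 16", call. = FALSE)
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(depth),
                    compression = "none")
  } else {
    write.table(format(img, digits = 17, scientific = TRUE, trim = TRUE),
                path, sep = if (grepl("\\.csv$", path)) "," else " ",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
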