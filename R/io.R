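## Grayscale image I/O.
##
## Images are held as plain numeric matrices in [0, 1], row 1 at the top
## of the picture (x along columns, y along rows).  Angles inside the
## package are measured from the +x axis toward the +y (row) axis; on a
## y-up display this reads as the mirrored (clockwise) angle, but since a
## motion blur at theta and -theta + 180 produces the same symmetric
## kernel the distinction only matters for signed directions, which the
## estimators do not resolve anyway.

#' Read a grayscale image
#'
#' Reads PNG, TIFF or JPEG into a numeric matrix in [0, 1].  Color
#' images are reduced to luminance with the ITU-R BT.601 weights
#' (0.299, 0.587, 0.114); an alpha channel is dropped.  8- and 16-bit
#' integer data are scaled to [0, 1].
#'
#' @param path image file path; format chosen by extension.
#' @return numeric matrix (height x width) in [0, 1].
#' @export
readImageGray <- function(path) {
    if (!file.exists(path))
        stopUsblur("ioError", sprintf("cannot read '%s'", path))
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
        png = png::readPNG(path),
        tif = , tiff = tiff::readTIFF(path),
        jpg = , jpeg = {
            if (!requireNamespace("jpeg", quietly = TRUE))
                stopUsblur("ioError", "the 'jpeg' package is required")
            jpeg::readJPEG(path)
        },
        stopUsblur("ioError", sprintf("unsupported image format '%s'", ext)))
    if (length(dim(img)) == 3L) {
        nc <- dim(img)[3L]
        img <- if (nc >= 3L) {
            0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
        } else {
            img[, , 1L]
        }
    }
    clip01(unname(as.matrix(img)))
}

#' Write a grayscale image
#'
#' Writes a [0, 1] matrix as 8-bit PNG/JPEG or (by default) 32-bit float
#' TIFF, clipping out-of-range values.
#'
#' @param image numeric matrix.
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
writeImageGray <- function(image, path) {
    stopifnot(is.matrix(image))
    img <- clip01(image)
    ext <- tolower(tools::file_ext(path))
    switch(ext,
        png = png::writePNG(img, path),
        tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 32L),
        jpg = , jpeg = {
            if (!requireNamespace("jpeg", quietly = TRUE))
                stopUsblur("ioError", "the 'jpeg' package is required")
            jpeg::writeJPEG(img, path, quality = 0.95)
        },
        stopUsblur("ioError", sprintf("unsupported image format '%s'", ext)))
    invisible(path)
}
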