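## Discrete linear-motion PSF construction and its frequency response.
##
## The continuous model is a uniform line mass of length L at angle theta:
##   h(x, y) = (1/L) * integral over t in [-L/2, L/2] of
##             delta(x - t cos theta) delta(y - t sin theta) dt.
## Two discretizations are provided.  "matrix" mode steps one pixel at a
## time along the dominant axis and snaps the other coordinate to the
## nearest pixel (a Bresenham-style line), reproducing the printed
## textbook kernels such as the exact 1/7 diagonal for L = 7 at 45
## degrees.  "subpixel" mode distributes ~16 samples per pixel of line
## with trapezoid weights and bilinear splatting; its kernels are
## centrosymmetric, so odd-order central moments vanish and the DFT is
## real, which the invariant machinery relies on.
##
## Coordinates: kernel columns are x and rows are y, with the origin at
## the central pixel.  Because the kernel is symmetric under
## (x, y) -> (-x, -y), the same kernel serves the y-up (mathematical) and
## y-down (matrix) readings of the angle; images read from disk keep
## their natural row order and angles are measured from the +x (column)
## axis toward the +y (row) axis.

#' Build a discrete linear-motion PSF kernel
#'
#' @param params a \code{\link{motionBlurParams}} object with positive
#'   length.  Lengths at or below 1 pixel collapse to the 1x1 identity
#'   kernel (no motion extent).
#' @param mode \code{"subpixel"} (default; anti-aliased, centrosymmetric)
#'   or \code{"matrix"} (nearest-pixel line, textbook appearance).
#' @return a \code{\link{PSFKernel}}; entries are nonnegative and sum to 1.
#' @examples
#' psfWeights(makeMotionPSF(motionBlurParams(7, 45), mode = "matrix"))
#' @export
makeMotionPSF <- function(params, mode = c("subpixel", "matrix")) {
    stopifnot(is(params, "MotionBlurParams"))
    mode <- match.arg(mode)
    L <- blurLength(params)
    if (L <= 0)
        stopUsblur("parameterError", "blur length must be positive")
    th <- blurAngle(params) * pi / 180
    if (L <= 1) {
        return(new("PSFKernel", weights = matrix(1, 1, 1),
                   center = c(1L, 1L), mode = "identity", params = params))
    }
    ct <- cos(th); st <- sin(th)
    if (mode == "matrix") {
        n <- max(2L, as.integer(round(L)))
        i <- (seq_len(n) - 1) - (n - 1) / 2
        if (abs(ct) >= abs(st)) {
            xs <- round(i); ys <- round(i * st / ct)
        } else {
            ys <- round(i); xs <- round(i * ct / st)
        }
        side <- oddAtLeast(2 * max(abs(xs), abs(ys)) + 1)
        ctr <- (side + 1L) / 2L
        w <- matrix(0, side, side)
        idx <- cbind(ctr + ys, ctr + xs)
        for (k in seq_len(nrow(idx)))
            w[idx[k, 1L], idx[k, 2L]] <- w[idx[k, 1L], idx[k, 2L]] + 1
    } else {
        side <- oddAtLeast(ceiling(L * max(abs(ct), abs(st))) + 2)
        ctr <- (side + 1L) / 2L
        nS <- 2L * as.integer(ceiling(8 * L)) + 1L
        t <- seq(-L / 2, L / 2, length.out = nS)
        wt <- rep(1, nS); wt[c(1L, nS)] <- 0.5   # trapezoid rule
        xs <- t * ct; ys <- t * st
        r0 <- floor(ys); c0 <- floor(xs)
        fr <- ys - r0; fc <- xs - c0
        w <- matrix(0, side, side)
        splat <- function(rr, cc, ww) {
            keep <- ww > 0
            if (!any(keep)) return(invisible(NULL))
            idx <- (cc[keep] + ctr - 1) * side + (rr[keep] + ctr)
            acc <- vapply(split(ww[keep], idx), sum, numeric(1))
            w[as.integer(names(acc))] <<- w[as.integer(names(acc))] + acc
        }
        splat(r0,     c0,     wt * (1 - fr) * (1 - fc))
        splat(r0 + 1, c0,     wt * fr * (1 - fc))
        splat(r0,     c0 + 1, wt * (1 - fr) * fc)
        splat(r0 + 1, c0 + 1, wt * fr * fc)
    }
    w <- w / sum(w)
    ctr <- as.integer((dim(w) + 1L) / 2L)
    new("PSFKernel", weights = w, center = ctr, mode = mode, params = params)
}

#' Analytic motion-blur transfer function
#'
#' Evaluates the closed-form OTF of a length-L motion blur on the DFT
#' grid of an M x N frame:
#' \deqn{H(u, v) = \mathrm{sinc}\!\left[\pi L \left(\frac{u\cos\theta}{M}
#'   + \frac{v\sin\theta}{N}\right)\right]}
#' with the unnormalized sinc \code{sin(x)/x}.  Zeros fall on the lines
#' \eqn{u\cos\theta/M + v\sin\theta/N = \pm k/L} (cycles per pixel), and
#' \eqn{H(0,0) = 1}.
#'
#' @param params a \code{MotionBlurParams}.
#' @param u,v frequency bin indices (vectors, recycled).
#' @param width,height frame size M, N.
#' @return real values in approximately [-0.217, 1].
#' @examples
#' analyticOTF(motionBlurParams(10, 0), u = 0, v = 0, 128, 128)  # 1
#' @export
analyticOTF <- function(params, u, v, width, height) {
    stopifnot(is(params, "MotionBlurParams"), width >= 1, height >= 1)
    th <- blurAngle(params) * pi / 180
    arg <- pi * blurLength(params) *
        (u * cos(th) / width + v * sin(th) / height)
    sincu(arg)
}

#' Numerical transfer function of a PSF kernel
#'
#' Zero-embeds the kernel in an M x N frame with its center at the DFT
#' origin (wrap-around) and returns the DFT.  The DC coefficient equals
#' the kernel sum (1 for normalized kernels); for subpixel-mode kernels
#' the low-frequency values agree with \code{\link{analyticOTF}}.
#'
#' @param psf a \code{PSFKernel}.
#' @param width,height frame size; must be at least the kernel size.
#' @return a \code{\link{FrequencyResponse}}.
#' @export
psfOTF <- function(psf, width, height) {
    stopifnot(is(psf, "PSFKernel"))
    h <- embedPSF(psf, width, height)
    new("FrequencyResponse", values = fft2(h),
        width = as.integer(width), height = as.integer(height))
}

#' Export / import PSF kernels
#'
#' \code{writePSF} writes the kernel as a plain-text whitespace-separated
#' matrix (extension \code{.txt}/\code{.psf}) or as a 32-bit float TIFF
#' (\code{.tif}/\code{.tiff}); \code{readPSF} reads either back,
#' renormalizing to unit sum.
#'
#' @param psf a \code{PSFKernel}.
#' @param path output (input) file path; format chosen by extension.
#' @param mode rasterization tag recorded on the re-imported kernel.
#' @return \code{readPSF} returns a \code{PSFKernel} (with a placeholder
#'   \code{params} slot of length \code{NA}-free nominal values, since the
#'   file does not store them).
#' @export
writePSF <- function(psf, path) {
    stopifnot(is(psf, "PSFKernel"))
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        tiff::writeTIFF(psfWeights(psf), path, bits.per.sample = 32L,
                        reduce = FALSE)
    } else {
        utils::write.table(psfWeights(psf), path, row.names = FALSE,
                           col.names = FALSE)
    }
    invisible(path)
}

#' @rdname writePSF
#' @export
readPSF <- function(path, mode = "subpixel") {
    ext <- tolower(tools::file_ext(path))
    w <- if (ext %in% c("tif", "tiff")) {
        x <- tiff::readTIFF(path, as.is = FALSE)
        if (length(dim(x)) == 3L) x <- x[, , 1L]
        x
    } else {
        as.matrix(utils::read.table(path))
    }
    w <- unname(as.matrix(w))
    if (any(w < 0) || sum(w) <= 0)
        stopUsblur("parameterError", "file does not contain a valid kernel")
    w <- w / sum(w)
    new("PSFKernel", weights = w, center = as.integer((dim(w) + 1L) / 2L),
        mode = mode, params = motionBlurParams(max(dim(w)), 0))
}
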