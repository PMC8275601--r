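## Ultrasound-like phantom generation and the forward degradation model.
##
## The phantom emulates the appearance of a log-compressed B-mode scan:
## smooth anatomy-like structures (random ellipse intensity fields,
## Gaussian-smoothed) multiplied by unit-mean gamma speckle, then
## log-compressed and confined to a soft elliptical scan region inside a
## dark margin.  The dark margin means a periodic convolution with any
## kernel whose half-extent is smaller than the margin equals the linear
## convolution, so the spectral and moment identities hold exactly in
## tests.  The forward model is g = f * h + n with periodic boundaries,
## additive Gaussian noise, and clipping to [0, 1].

#' Generate an ultrasound-like speckle phantom
#'
#' @param width,height frame size in pixels, both >= 64.
#' @param nStructures number of random ellipse structures (default 6).
#' @param speckleLooks gamma shape of the multiplicative speckle: the
#'   effective number of averaged looks.  Larger values give smoother
#'   speckle; the variance scales as 1/looks.  Default 3, a typical
#'   compounded-B-scan texture.
#' @param seed integer seed; the output is a deterministic function of
#'   the arguments.
#' @param marginFrac fraction of the frame left as dark margin around the
#'   elliptical scan region (default 0.15).
#' @return numeric matrix (height x width) with values spanning [0, 1].
#' @examples
#' f <- generatePhantom(128, 128, seed = 7)
#' range(f)
#' @export
generatePhantom <- function(width = 256L, height = 256L, nStructures = 6L,
                            speckleLooks = 3, seed = 1L,
                            marginFrac = 0.15) {
    if (width < 64L || height < 64L)
        stopUsblur("sizeError", "phantom sides must be >= 64 pixels")
    if (speckleLooks <= 0)
        stopUsblur("parameterError", "speckleLooks must be positive")
    withr::with_seed(as.integer(seed), {
        x <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
        y <- matrix(seq_len(height) - 1, height, width)
        bg <- matrix(0.3, height, width)
        for (i in seq_len(nStructures)) {
            cx <- stats::runif(1, 0.25, 0.75) * width
            cy <- stats::runif(1, 0.25, 0.75) * height
            ax <- stats::runif(1, 0.08, 0.3) * width
            ay <- stats::runif(1, 0.08, 0.3) * height
            ang <- stats::runif(1, 0, pi)
            amp <- stats::runif(1, -0.5, 0.7)
            xr <- (x - cx) * cos(ang) + (y - cy) * sin(ang)
            yr <- -(x - cx) * sin(ang) + (y - cy) * cos(ang)
            inside <- (xr / ax)^2 + (yr / ay)^2 <= 1
            bg <- bg + amp * inside
        }
        bg <- EBImage::gblur(bg, sigma = max(2, min(width, height) / 96))
        bg <- bg - min(bg)
        bg <- 0.1 + 0.9 * bg / max(bg)
        speckle <- matrix(stats::rgamma(width * height,
                                        shape = speckleLooks,
                                        rate = speckleLooks),
                          height, width)
        img <- bg * speckle
        cc <- 30
        img <- log(1 + cc * img) / log(1 + cc)
        ## soft elliptical scan region with a dark margin
        ex <- width / 2 - marginFrac * width
        ey <- height / 2 - marginFrac * height
        rr <- sqrt(((x - (width - 1) / 2) / ex)^2 +
                   ((y - (height - 1) / 2) / ey)^2)
        edge <- min(width, height) * 0.03
        mask <- clip01((1 - rr) * ex / edge + 0.5)
        mask <- 0.5 - 0.5 * cos(pi * mask)    # raised-cosine shoulder
        img <- img * mask
        img <- img - min(img)
        img / max(img)
    })
}

#' Apply the forward motion-blur degradation model
#'
#' Computes g = f * h + n: periodic-boundary convolution with the
#' subpixel motion PSF, plus additive Gaussian noise, clipped to [0, 1].
#' With \code{noiseSigma = 0} this is the noiseless model under which the
#' spectral ratio G/F equals the kernel transfer function exactly.
#'
#' @param image numeric matrix in [0, 1].
#' @param params a \code{\link{MotionBlurParams}}; lengths <= 1 leave the
#'   image unchanged (identity kernel).
#' @param noiseSigma standard deviation of the additive Gaussian noise
#'   (default 0).
#' @param seed seed for the noise (ignored when \code{noiseSigma} is 0).
#' @param boundary \code{"periodic"} (default; exact circular model) or
#'   \code{"replicate"} (realistic edges, breaks the exact identities).
#' @return degraded image, same size as the input.
#' @export
degradeImage <- function(image, params, noiseSigma = 0, seed = 1L,
                         boundary = c("periodic", "replicate")) {
    stopifnot(is.matrix(image), is(params, "MotionBlurParams"))
    boundary <- match.arg(boundary)
    if (noiseSigma < 0)
        stopUsblur("parameterError", "noiseSigma must be >= 0")
    psf <- makeMotionPSF(params, mode = "subpixel")
    if (nrow(psfWeights(psf)) > nrow(image) ||
        ncol(psfWeights(psf)) > ncol(image))
        stopUsblur("sizeError", "PSF kernel exceeds the image frame")
    g <- if (boundary == "periodic") {
        convolvePeriodic(image, psf)
    } else {
        EBImage::filter2(image, psfWeights(psf), boundary = "replicate")
    }
    if (noiseSigma > 0) {
        g <- g + withr::with_seed(as.integer(seed),
            matrix(stats::rnorm(length(g), sd = noiseSigma),
                   nrow(g), ncol(g)))
    }
    clip01(g)
}
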