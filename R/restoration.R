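## Wiener deconvolution and end-to-end blind deblurring.
##
## The minimum-mean-square-error linear restoration filter is
##   Lambda(u,v) = conj(H) S / (|H|^2 S + N)
## with S and N the signal and noise power spectra.  These are never
## known in practice, so the standard constant noise-to-signal reduction
## is used: Lambda = conj(H) / (|H|^2 + nsr).  With nsr = 0 this is the
## inverse filter wherever |H| > 0.

#' Wiener deconvolution with a known PSF
#'
#' @param g blurred image, numeric matrix in [0, 1].
#' @param psf a \code{\link{PSFKernel}} (normalized; smaller than the
#'   image).
#' @param nsr noise-to-signal power ratio: a nonnegative number, or
#'   \code{"auto"} to estimate it as the ratio of mean spectral power in
#'   the top-decile frequency radii to the mean over all non-DC
#'   frequencies.
#' @param edgeTaper logical; blend the image border toward its blurred
#'   version before deconvolving to suppress wrap-around ringing on
#'   non-periodic scenes (default FALSE: the internal model is periodic).
#' @return the restored image, clipped to [0, 1].
#' @examples
#' f <- generatePhantom(128, 128, seed = 3)
#' psf <- makeMotionPSF(motionBlurParams(10, 30))
#' g <- degradeImage(f, motionBlurParams(10, 30))
#' fr <- wienerDeconvolve(g, psf, nsr = 1e-4)
#' @export
wienerDeconvolve <- function(g, psf, nsr = 1e-3, edgeTaper = FALSE) {
    stopifnot(is.matrix(g), is(psf, "PSFKernel"))
    if (nrow(psfWeights(psf)) > nrow(g) || ncol(psfWeights(psf)) > ncol(g))
        stopUsblur("sizeError", "PSF kernel is larger than the image")
    if (edgeTaper) g <- edgeTaperImage(g, psf)
    H <- otfValues(psfOTF(psf, ncol(g), nrow(g)))
    G <- fft2(g)
    if (identical(nsr, "auto")) nsr <- estimateNSR(G)
    stopifnot(is.numeric(nsr), nsr >= 0)
    H2 <- Mod(H)^2
    den <- H2 + nsr
    filt <- Conj(H) / den
    if (nsr == 0) filt[H2 < 1e-14] <- 0    # inverse filter off the zeros
    clip01(Re(ifft2(filt * G)))
}

## Constant-NSR heuristic: mean power in the top decile of frequency
## radii over mean power at all non-DC frequencies.
estimateNSR <- function(G) {
    P <- Mod(G)^2
    n <- nrow(P); m <- ncol(P)
    kv <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))
    ku <- pmin(seq_len(m) - 1L, m - (seq_len(m) - 1L))
    rad <- sqrt(outer(kv^2, ku^2, `+`))
    hi <- rad >= stats::quantile(rad, 0.9)
    tot <- P; tot[1, 1] <- NA
    max(mean(P[hi]) / mean(tot, na.rm = TRUE), 1e-8)
}

## Blend the border of an image toward its blurred version using ramps
## derived from the autocorrelation of the PSF projections (so the taper
## width matches the kernel extent).
edgeTaperImage <- function(img, psf) {
    w <- psfWeights(psf)
    ramp <- function(p, n) {
        p <- p / sum(p)
        q <- stats::convolve(p, rev(p), type = "open")  # autocorrelation
        q <- q / max(q)
        k <- length(q)
        half <- (k - 1) %/% 2
        win <- rep(1, n)
        if (half > 0 && 2 * half < n) {
            win[seq_len(half)] <- q[seq_len(half)]
            win[n - seq_len(half) + 1] <- q[seq_len(half)]
        }
        win
    }
    wy <- ramp(rowSums(w), nrow(img))
    wx <- ramp(colSums(w), ncol(img))
    alpha <- outer(wy, wx)
    alpha * img + (1 - alpha) * convolvePeriodic(img, psf)
}

#' Blind motion deblurring
#'
#' Estimates the motion parameters with the spectral pipeline
#' (\code{\link{estimateParams}}), synthesizes the subpixel PSF, and
#' restores by Wiener deconvolution.  If no blur is detected the input is
#' returned unchanged with the length-0 sentinel parameters.
#'
#' @param g blurred image, numeric matrix in [0, 1].
#' @param nsr noise-to-signal ratio passed to
#'   \code{\link{wienerDeconvolve}}.
#' @param edgeTaper passed to \code{\link{wienerDeconvolve}}.
#' @param ... passed to \code{\link{estimateParams}}.
#' @return a list with elements \code{image} (restored), \code{params}
#'   (a \code{MotionBlurParams}; length 0 if no blur was detected),
#'   \code{detected} (logical) and \code{estimate} (the
#'   \code{MotionEstimate}, or NULL).
#' @export
blindDeblur <- function(g, nsr = 1e-3, edgeTaper = FALSE, ...) {
    est <- tryCatch(estimateParams(g, ...), noBlurError = function(e) NULL,
                    lengthIndeterminateError = function(e) NULL)
    if (is.null(est))
        return(list(image = g, params = motionBlurParams(0, 0),
                    detected = FALSE, estimate = NULL))
    psf <- makeMotionPSF(estimatedParams(est), mode = "subpixel")
    list(image = wienerDeconvolve(g, psf, nsr = nsr, edgeTaper = edgeTaper),
         params = estimatedParams(est), detected = TRUE, estimate = est)
}
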