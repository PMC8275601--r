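## Frequency-domain blur invariants.
##
## In the noiseless degradation model the blurred spectrum is the clean
## spectrum times the motion OTF, G = F * H.  The ratio xi(u, v) =
## G(u, v)/F(u, v) therefore depends only on the blur, and because the
## OTF is a sinc whose argument is linear in (u, v), the two lowest
## nonzero bins determine it completely:
##   a = sincInv[G(0,1)/F(0,1)] = pi * L * sin(theta) / N
##   b = sincInv[G(1,0)/F(1,0)] = pi * L * cos(theta) / M
## so xi(u, v) = sinc(a*v + b*u) for every frequency, and (theta, L)
## follow from (a, b) in closed form.  The (0,1)/(1,0) bins are used
## because the first sinc lobe is widest there, which keeps the
## inversion well-conditioned.

## DFT coefficient at bin (u, v) of an unshifted spectrum; negative
## indices wrap.  Matrix layout: rows are v, columns are u.
dftBin <- function(Fmat, u, v) {
    Fmat[cbind((v %% nrow(Fmat)) + 1L, (u %% ncol(Fmat)) + 1L)]
}

## Real-part projection of a spectrum ratio.  For a centered symmetric
## PSF and periodic convolution the ratio is real; a substantial
## imaginary part signals that the model does not apply.
realRatio <- function(g, f, imagTol) {
    if (Mod(f) < 1e-10)
        stopUsblur("degenerateImageError",
                   "clean-image spectrum is ~0 at a required low frequency")
    r <- g / f
    if (abs(Im(r)) > imagTol * max(Mod(r), 1e-12))
        warning(sprintf(
            "spectrum ratio has relative imaginary part %.3g; taking Re()",
            abs(Im(r)) / max(Mod(r), 1e-12)))
    Re(r)
}

#' Low-frequency (a, b) pair from a clean/blurred image pair
#'
#' Computes a = sincInv[G(0,1)/F(0,1)] and b = sincInv[G(1,0)/F(1,0)]
#' from the DFTs of the clean image \code{f} and its blurred version
#' \code{g}.  The ratios must be real (up to \code{imagTol}) and inside
#' the principal sinc branch (0, 1]; blurs long enough to push the
#' lowest-frequency ratio past the first sinc zero are outside the
#' validity range and raise an out-of-branch error.
#'
#' @param f,g numeric matrices of the same size: clean and blurred image.
#' @param imagTol maximum tolerated relative imaginary part of the
#'   spectrum ratios before a warning is issued (default 1e-6).
#' @return an \code{\link{ABPair}}.
#' @examples
#' f <- generatePhantom(128, 128, seed = 3)
#' g <- degradeImage(f, motionBlurParams(20, 45))
#' computeAB(f, g)
#' @export
computeAB <- function(f, g, imagTol = 1e-6) {
    stopifnot(is.matrix(f), is.matrix(g), all(dim(f) == dim(g)))
    Fm <- fft2(f); Gm <- fft2(g)
    r01 <- realRatio(dftBin(Gm, 0L, 1L), dftBin(Fm, 0L, 1L), imagTol)
    r10 <- realRatio(dftBin(Gm, 1L, 0L), dftBin(Fm, 1L, 0L), imagTol)
    new("ABPair", a = sincInv(min(r01, 1)), b = sincInv(min(r10, 1)),
        width = ncol(f), height = nrow(f))
}

#' Motion parameters from an (a, b) pair
#'
#' Converts the low-frequency sinc-inverse pair into motion parameters.
#' Since a = pi L sin(theta)/N and b = pi L cos(theta)/M, the angle is
#' atan2(a*N, b*M) (which reduces to atan(a/b) on square frames) and the
#' length is sqrt((a*N/pi)^2 + (b*M/pi)^2) (equivalently 2*pi*a*csc(theta)
#' in the angular-frequency normalization, rescaled to pixels by the DFT
#' bin-to-frequency factor).  a = b = 0 signals no blur and returns the
#' length-0 sentinel.
#'
#' @param ab an \code{\link{ABPair}}.
#' @return a \code{\link{MotionBlurParams}} with angle in [0, 90] (the
#'   direction sign is not recoverable from amplitude ratios).
#' @export
angleLengthFromAB <- function(ab) {
    stopifnot(is(ab, "ABPair"))
    Ls <- ab@a * ab@height / pi   # L * sin(theta)
    Lc <- ab@b * ab@width / pi    # L * cos(theta)
    if (Ls == 0 && Lc == 0)
        return(motionBlurParams(0, 0))
    motionBlurParams(sqrt(Ls^2 + Lc^2), atan2(Ls, Lc) * 180 / pi)
}

#' Frequency blur invariant xi(u, v)
#'
#' The predicted spectrum ratio sinc(a*v + b*u).  For a consistent
#' linear-motion blur this equals G(u, v)/F(u, v) across all frequencies
#' even though (a, b) were measured at the two lowest bins only.
#'
#' @param u,v frequency bin indices (vectors, recycled).
#' @param ab an \code{\link{ABPair}}.
#' @return real invariant values; \code{xiInvariant(0, 0, ab)} is 1.
#' @export
xiInvariant <- function(u, v, ab) {
    stopifnot(is(ab, "ABPair"))
    sincu(ab@a * v + ab@b * u)
}

#' Table of measured and predicted blur invariants
#'
#' For each requested frequency pair, records the amplitude and phase of
#' the measured ratio xi(u, v) = G(u, v)/F(u, v) together with the
#' sinc(a*v + b*u) prediction.  Frequencies where the clean spectrum is
#' near zero are flagged invalid rather than raising an error.
#'
#' @param f,g clean and blurred images (same size).
#' @param freqs two-column matrix or data.frame of (u, v) bin indices.
#' @param ab optionally a precomputed \code{\link{ABPair}}; computed from
#'   \code{(f, g)} when missing.
#' @return a data.frame with columns \code{u}, \code{v}, \code{amplitude},
#'   \code{phase_rad}, \code{predicted}, \code{valid}, suitable for
#'   \code{write.csv}.
#' @export
invariantTable <- function(f, g, freqs, ab = NULL) {
    stopifnot(all(dim(f) == dim(g)))
    freqs <- as.matrix(freqs)
    if (nrow(freqs) == 0L)
        stopUsblur("parameterError", "'freqs' must be nonempty")
    if (is.null(ab)) ab <- computeAB(f, g)
    Fm <- fft2(f); Gm <- fft2(g)
    Fv <- dftBin(Fm, freqs[, 1L], freqs[, 2L])
    Gv <- dftBin(Gm, freqs[, 1L], freqs[, 2L])
    valid <- Mod(Fv) > 1e-8 * Mod(Fm[1L, 1L])
    ratio <- ifelse(valid, Gv / Fv, NA_complex_)
    data.frame(u = freqs[, 1L], v = freqs[, 2L],
               amplitude = Mod(ratio), phase_rad = Arg(ratio),
               predicted = xiInvariant(freqs[, 1L], freqs[, 2L], ab),
               valid = valid)
}
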