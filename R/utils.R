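## Numeric and Fourier helpers shared across the package.

#' Unnormalized sinc
#'
#' \code{sincu(x) = sin(x)/x} with \code{sincu(0) = 1}.  This is the
#' convention in which the transfer function of a length-L motion blur is
#' \code{sincu(pi * L * (u cos(theta)/M + v sin(theta)/N))}: the first
#' zero along the motion direction sits where the argument reaches pi,
#' i.e. at L * omega / 2 = pi in radians-per-pixel units, so zero lines
#' fall at u cos(theta)/M + v sin(theta)/N = k/L (cycles per pixel).
#'
#' @param x numeric vector (radians).
#' @return \code{sin(x)/x}, elementwise, with the removable singularity
#'   at 0 filled in.
#' @examples
#' sincu(0)            # 1
#' sincu(pi)           # 0 (first zero)
#' @export
sincu <- function(x) {
    out <- rep(1, length(x))
    nz <- x != 0
    out[nz] <- sin(x[nz]) / x[nz]
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
}

#' Principal-branch inverse sinc
#'
#' Inverts \code{sincu} on its principal branch [0, pi), where it
#' decreases monotonically from 1 to 0, by bisection.  Ratios outside
#' (0, 1] cannot come from the principal branch (a blur long enough to
#' push the lowest-frequency ratio past the first sinc zero is outside
#' the validity range of the low-frequency inversion) and raise an
#' out-of-branch error.
#'
#' @param y numeric in (0, 1]; values in (1, 1 + tol] are clamped to 1.
#' @param tol bisection tolerance on x (default 1e-10).
#' @return x in [0, pi) with \code{sincu(x) = y}.
#' @examples
#' sincInv(sincu(0.5))  # 0.5
#' @export
sincInv <- function(y, tol = 1e-10) {
    vapply(y, function(yi) {
        if (!is.finite(yi))
            stopUsblur("outOfBranchError", "sinc ratio is not finite")
        if (yi > 1 + 1e-9 || yi <= 0)
            stopUsblur("outOfBranchError", sprintf(
                "ratio %.6g outside the principal sinc branch (0, 1]", yi))
        if (yi >= 1) return(0)
        lo <- 0; hi <- pi
        while (hi - lo > tol) {
            mid <- (lo + hi) / 2
            if (sincu(mid) > yi) lo <- mid else hi <- mid
        }
        (lo + hi) / 2
    }, numeric(1))
}

## 2-D FFT wrappers (stats::fft handles n-dimensional arrays).
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## Shift DC to the center: row floor(N/2)+1, col floor(M/2)+1.
fftshift2 <- function(x) {
    n <- nrow(x); m <- ncol(x)
    x[c((floor(n / 2) + 1):n, seq_len(floor(n / 2))),
      c((floor(m / 2) + 1):m, seq_len(floor(m / 2)))]
}

## Embed a PSF in an N x M frame with its center at index (1, 1),
## wrapping negative offsets (the standard origin-at-corner convention
## so the transfer function carries no linear phase for symmetric kernels).
embedPSF <- function(psf, width, height) {
    w <- psfWeights(psf)
    ctr <- psfCenter(psf)
    if (nrow(w) > height || ncol(w) > width)
        stopUsblur("sizeError", "PSF kernel is larger than the frame")
    out <- matrix(0, height, width)
    rows <- ((seq_len(nrow(w)) - ctr[1L]) %% height) + 1L
    cols <- ((seq_len(ncol(w)) - ctr[2L]) %% width) + 1L
    out[rows, cols] <- out[rows, cols] + w
    out
}

## Exact periodic (circular) convolution of an image with a PSF kernel.
## Used by the forward degradation model so that the spectral identity
## G = F * H and the moment convolution identity hold exactly in tests.
convolvePeriodic <- function(image, psf) {
    h <- embedPSF(psf, ncol(image), nrow(image))
    Re(ifft2(fft2(image) * fft2(h)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Periodic Hann window (length n), outer-product form for 2-D.
hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

## Bilinear interpolation of matrix `m` at fractional (row, col)
## positions; positions outside the grid return NA.
bilinearAt <- function(m, row, col) {
    n <- nrow(m); k <- ncol(m)
    r0 <- floor(row); c0 <- floor(col)
    fr <- row - r0; fc <- col - c0
    ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= n & c0 + 1 <= k
    out <- rep(NA_real_, length(row))
    if (any(ok)) {
        i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
        i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
        out[ok] <- m[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
            m[i10] * fr[ok] * (1 - fc[ok]) +
            m[i01] * (1 - fr[ok]) * fc[ok] +
            m[i11] * fr[ok] * fc[ok]
    }
    out
}

## Smallest odd integer >= x.
oddAtLeast <- function(x) {
    n <- as.integer(ceiling(x))
    if (n %% 2L == 0L) n + 1L else n
}

## Angular difference modulo 180 degrees (blur direction is unsigned).
angleDiff180 <- function(a, b) {
    d <- abs(a - b) %% 180
    pmin(d, 180 - d)
}
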