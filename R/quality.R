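## Image-quality scoring: full-reference SSIM and a block acutance map.

## Gaussian filtering with reflective padding; interior values match a
## "valid" convolution, which is what windowed SSIM statistics need.
gaussFilterReflect <- function(x, win, pad) {
    n <- nrow(x); m <- ncol(x)
    xp <- x[c(pad:1, 1:n, n:(n - pad + 1)), c(pad:1, 1:m, m:(m - pad + 1))]
    h <- matrix(0, nrow(xp), ncol(xp))
    k <- nrow(win)
    ctr <- (k + 1L) %/% 2L
    h[1:k, 1:k] <- win
    ## rotate so the window center sits at the origin
    h <- h[c(ctr:nrow(h), 1:(ctr - 1)), c(ctr:ncol(h), 1:(ctr - 1))]
    out <- Re(ifft2(fft2(xp) * fft2(h)))
    out[(pad + 1):(pad + n), (pad + 1):(pad + m)]
}

#' Structural similarity index (SSIM)
#'
#' Standard single-scale SSIM with an 11 x 11 Gaussian weighting window
#' (sigma 1.5), stability constants K1 = 0.01 and K2 = 0.03, and dynamic
#' range 1.  Local means, variances and covariance are computed with the
#' Gaussian window and the SSIM map is averaged after cropping the
#' half-window border (where the window support is incomplete).
#'
#' @param a,b images to compare: numeric matrices of identical size with
#'   values in [0, 1].
#' @param K1,K2 stability constants.
#' @param sigma Gaussian window standard deviation (window size 11).
#' @return mean SSIM in [-1, 1]; 1 iff the images are identical.
#' @examples
#' f <- generatePhantom(96, 96, seed = 1)
#' ssim(f, f)  # 1
#' @export
ssim <- function(a, b, K1 = 0.01, K2 = 0.03, sigma = 1.5) {
    if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
        stopUsblur("sizeError", "images must be matrices of identical size")
    half <- 5L
    g <- stats::dnorm(-half:half, sd = sigma)
    win <- outer(g, g); win <- win / sum(win)
    mu1 <- gaussFilterReflect(a, win, half + 1L)
    mu2 <- gaussFilterReflect(b, win, half + 1L)
    s11 <- gaussFilterReflect(a * a, win, half + 1L) - mu1^2
    s22 <- gaussFilterReflect(b * b, win, half + 1L) - mu2^2
    s12 <- gaussFilterReflect(a * b, win, half + 1L) - mu1 * mu2
    C1 <- K1^2; C2 <- K2^2
    map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
        ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
    n <- nrow(a); m <- ncol(a)
    mean(map[(half + 1):(n - half), (half + 1):(m - half)])
}

#' Block acutance map
#'
#' Divides the image into a grid of blocks and scores each block's
#' sharpness as the RMS gradient magnitude normalized by the block mean
#' intensity (blocks with zero mean score 0 by convention).  This
#' edge-contrast definition of acutance is a documented choice of this
#' package, not a canonical standard.  The per-row profile (block-row
#' means) mirrors the common display of acutance along the vertical axis.
#'
#' @param image numeric matrix.
#' @param grid integer (rows, cols) of the block grid; default
#'   \code{c(10, 1)}: ten horizontal slabs whose profile runs down the
#'   image.
#' @return a list with \code{map} (rows x cols matrix of block acutance)
#'   and \code{profile} (block-row means).
#' @export
acutanceMap <- function(image, grid = c(10L, 1L)) {
    stopifnot(is.matrix(image), length(grid) == 2L)
    gr <- as.integer(grid)
    if (nrow(image) < gr[1L] || ncol(image) < gr[2L])
        stopUsblur("sizeError", "image smaller than the block grid")
    n <- nrow(image); m <- ncol(image)
    gx <- (image[, c(2:m, m)] - image[, c(1, 1:(m - 1))]) / 2
    gy <- (image[c(2:n, n), ] - image[c(1, 1:(n - 1)), ]) / 2
    g2 <- gx^2 + gy^2
    blockIdx <- function(len, k)
        if (k == 1L) rep(1L, len) else cut(seq_len(len), k, labels = FALSE)
    rIdx <- blockIdx(n, gr[1L])
    cIdx <- blockIdx(m, gr[2L])
    map <- matrix(0, gr[1L], gr[2L])
    for (i in seq_len(gr[1L])) for (j in seq_len(gr[2L])) {
        blk <- image[rIdx == i, cIdx == j, drop = FALSE]
        mb <- mean(blk)
        map[i, j] <- if (mb <= 0) 0 else
            sqrt(mean(g2[rIdx == i, cIdx == j])) / mb
    }
    list(map = map, profile = rowMeans(map))
}
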