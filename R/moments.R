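## Geometric-moment machinery: discrete moments, the moment convolution
## theorem, closed-form motion-PSF moments, moment-based estimation of
## (theta, L), and blur-invariant moment features.
##
## Moments of a convolution combine binomially:
##   m_pq(g) = sum_k sum_l C(p,k) C(q,l) m_kl(h) m_{p-k,q-l}(f),
## exact for discrete convolution with untruncated support.  A centered
## motion kernel has closed-form moments about its own center:
##   m_pq(h) = (L/2)^{p+q} cos^p(theta) sin^q(theta) / (p+q+1)  (p+q even)
##   m_pq(h) = 0                                               (p+q odd)
## which gives the second-order relations
##   m20(g) - m20(f) = (L^2/12) cos^2(theta) m00(f)
##   m02(g) - m02(f) = (L^2/12) sin^2(theta) m00(f)
## and hence the estimators
##   theta = atan sqrt[(m02(g)-m02(f)) / (m20(g)-m20(f))]
##   L = 2*sqrt(3) * sqrt[(m20(g)+m02(g)-m20(f)-m02(f)) / m00(f)].
## These relations as written assume the kernel is centered at the
## coordinate origin; we therefore evaluate them on CENTRAL moments of f
## and g (a centered kernel preserves the centroid), which removes any
## dependence on the arbitrary image-coordinate origin.

#' Geometric moments of an image
#'
#' Discretizes \eqn{m_{pq} = \int f(x,y) x^p y^q \,dx\,dy} as a pixel sum
#' with 0-based coordinates (x along columns, y along rows, pixel centers
#' at integers).  Central moments are taken about the intensity centroid
#' (m10/m00, m01/m00).
#'
#' @param image nonnegative numeric matrix.
#' @param maxOrder maximum total order p + q (at most 6).
#' @param origin \code{"raw"} (pixel-grid origin) or \code{"central"}.
#' @param source provenance tag stored on the table.
#' @return a \code{\link{MomentTable}}; entries with p + q > maxOrder are NA.
#' @examples
#' img <- matrix(0, 8, 8); img[3, 5] <- 1      # point mass at x=4, y=2
#' momentValue(geometricMoments(img, 2), 1, 0) # 4
#' @export
geometricMoments <- function(image, maxOrder = 4L,
                             origin = c("raw", "central"),
                             source = "image") {
    origin <- match.arg(origin)
    stopifnot(is.matrix(image), is.numeric(image))
    if (maxOrder < 0L || maxOrder > 6L)
        stopUsblur("parameterError", "maxOrder must be in 0..6")
    maxOrder <- as.integer(maxOrder)
    tot <- sum(image)
    if (origin == "central" && tot <= 0)
        stopUsblur("degenerateImageError",
                   "central moments are undefined for an all-zero image")
    x <- as.numeric(seq_len(ncol(image)) - 1L)
    y <- as.numeric(seq_len(nrow(image)) - 1L)
    if (origin == "central") {
        x <- x - sum(image %*% x) / tot       # subtract centroid
        y <- y - sum(t(image) %*% y) / tot
    }
    k <- maxOrder + 1L
    Xp <- outer(x, 0:maxOrder, `^`)           # ncol x (maxOrder+1)
    Yq <- outer(y, 0:maxOrder, `^`)
    vals <- t(Yq) %*% image %*% Xp            # [q+1, p+1]
    vals <- t(vals)                           # [p+1, q+1]
    vals[outer(0:maxOrder, 0:maxOrder, `+`) > maxOrder] <- NA_real_
    new("MomentTable", values = vals, maxOrder = maxOrder,
        origin = origin, source = source)
}

#' Closed-form moments of the motion-blur PSF
#'
#' Moments of the continuous line-mass kernel about its center:
#' \eqn{(L/2)^{p+q}\cos^p\theta\,\sin^q\theta/(p+q+1)} for even total
#' order, 0 for odd total order.
#'
#' @param params a \code{MotionBlurParams}.
#' @param p,q moment orders (vectors, recycled).
#' @return exact closed-form moment values.
#' @examples
#' psfMomentsClosedForm(motionBlurParams(2, 0), 2, 0)  # 1/3
#' @export
psfMomentsClosedForm <- function(params, p, q) {
    stopifnot(is(params, "MotionBlurParams"))
    th <- blurAngle(params) * pi / 180
    L <- blurLength(params)
    n <- p + q
    out <- (L / 2)^n * cos(th)^p * sin(th)^q / (n + 1)
    out[n %% 2 == 1] <- 0
    out
}

#' @rdname psfMomentsClosedForm
#' @param maxOrder maximum total order for the assembled table.
#' @return \code{psfMomentTable} returns the same values assembled into a
#'   \code{\link{MomentTable}} (central origin: the kernel is centered).
#' @export
psfMomentTable <- function(params, maxOrder = 4L) {
    maxOrder <- as.integer(maxOrder)
    pq <- expand.grid(p = 0:maxOrder, q = 0:maxOrder)
    vals <- matrix(psfMomentsClosedForm(params, pq$p, pq$q),
                   maxOrder + 1L, maxOrder + 1L)
    vals[outer(0:maxOrder, 0:maxOrder, `+`) > maxOrder] <- NA_real_
    new("MomentTable", values = vals, maxOrder = maxOrder,
        origin = "central", source = "psf")
}

#' Moment convolution theorem
#'
#' Predicts the moments of g = f * h from the moments of f and of the
#' kernel h by the binomial combination rule.  The kernel table must be
#' taken about the kernel center; the image table may be raw or central
#' (for a centered kernel the centroid is preserved, so central-in gives
#' central-out about the same point).
#'
#' @param fMoments \code{MomentTable} of the image.
#' @param hMoments \code{MomentTable} of the kernel (about its center),
#'   e.g. from \code{\link{psfMomentTable}}.
#' @return a \code{MomentTable} of the blurred image, same origin as
#'   \code{fMoments}.
#' @export
convolveMoments <- function(fMoments, hMoments) {
    stopifnot(is(fMoments, "MomentTable"), is(hMoments, "MomentTable"))
    if (fMoments@maxOrder != hMoments@maxOrder)
        stopUsblur("parameterError", "moment tables have different maxOrder")
    mo <- fMoments@maxOrder
    fv <- fMoments@values; hv <- hMoments@values
    out <- matrix(NA_real_, mo + 1L, mo + 1L)
    for (p in 0:mo) for (q in 0:(mo - p)) {
        acc <- 0
        for (k in 0:p) for (l in 0:q) {
            acc <- acc + choose(p, k) * choose(q, l) *
                hv[k + 1L, l + 1L] * fv[p - k + 1L, q - l + 1L]
        }
        out[p + 1L, q + 1L] <- acc
    }
    new("MomentTable", values = out, maxOrder = mo,
        origin = fMoments@origin, source = "convolved")
}

## Second-order central-moment differences between blurred and clean
## tables, with a relative floor that zeroes tiny negative values caused
## by discretization.
momentDiffs2 <- function(gMoments, fMoments) {
    stopifnot(is(gMoments, "MomentTable"), is(fMoments, "MomentTable"))
    if (gMoments@origin != "central" || fMoments@origin != "central")
        stopUsblur("parameterError",
                   "angle/length estimation requires central moments")
    d20 <- momentValue(gMoments, 2, 0) - momentValue(fMoments, 2, 0)
    d02 <- momentValue(gMoments, 0, 2) - momentValue(fMoments, 0, 2)
    scale <- abs(momentValue(fMoments, 2, 0)) +
        abs(momentValue(fMoments, 0, 2))
    tol <- 1e-9 * max(scale, 1e-12)
    if (d20 < 0 && d20 > -tol) d20 <- 0
    if (d02 < 0 && d02 > -tol) d02 <- 0
    c(d20 = d20, d02 = d02)
}

#' Motion angle from second-order moments
#'
#' \eqn{\theta = \arctan\sqrt{(m_{02}^{(g)}-m_{02}^{(f)}) /
#' (m_{20}^{(g)}-m_{20}^{(f)})}} on central moments of the blurred and
#' clean images.  Second-order moments only determine the angle up to
#' reflection, so the result lies in [0, 90] degrees.
#'
#' @param gMoments,fMoments central \code{MomentTable}s of the blurred
#'   and clean images.
#' @return angle in degrees in [0, 90].
#' @export
estimateAngleMoments <- function(gMoments, fMoments) {
    d <- momentDiffs2(gMoments, fMoments)
    if (d["d20"] <= 0 && d["d02"] <= 0)
        stopUsblur("noBlurError",
                   "no second-moment growth: no blur detectable")
    if (d["d20"] < 0 || d["d02"] < 0)
        stopUsblur("inconsistentMomentsError",
                   "negative moment-difference ratio")
    if (d["d20"] == 0) return(90)
    unname(atan(sqrt(d["d02"] / d["d20"])) * 180 / pi)
}

#' Motion length from second-order moments
#'
#' \eqn{L = 2\sqrt{3}\sqrt{(m_{20}^{(g)}+m_{02}^{(g)}
#' -m_{20}^{(f)}-m_{02}^{(f)}) / m_{00}^{(f)}}} on central moments.
#'
#' @inheritParams estimateAngleMoments
#' @return blur length in pixels.
#' @export
estimateLengthMoments <- function(gMoments, fMoments) {
    d <- momentDiffs2(gMoments, fMoments)
    num <- d["d20"] + d["d02"]
    if (num <= 0)
        stopUsblur("noBlurError",
                   "no second-moment growth: no blur detectable")
    unname(2 * sqrt(3) * sqrt(num / momentValue(fMoments, 0, 0)))
}

## Invert the moment convolution theorem: recover the clean image's
## central moments from the blurred image's, given the kernel moment
## table.  Kernel moments of order >= 2 only reference lower-order image
## moments, so the recursion in increasing total order is well defined.
deconvolveMoments <- function(gMoments, hMoments) {
    mo <- gMoments@maxOrder
    gv <- gMoments@values; hv <- hMoments@values
    fv <- matrix(NA_real_, mo + 1L, mo + 1L)
    for (n in 0:mo) for (p in 0:n) {
        q <- n - p
        acc <- gv[p + 1L, q + 1L]
        for (k in 0:p) for (l in 0:q) {
            if (k == 0L && l == 0L) next
            acc <- acc - choose(p, k) * choose(q, l) *
                hv[k + 1L, l + 1L] * fv[p - k + 1L, q - l + 1L]
        }
        fv[p + 1L, q + 1L] <- acc
    }
    new("MomentTable", values = fv, maxOrder = mo,
        origin = gMoments@origin, source = "deconvolved")
}

#' Blur-invariant moment features M_0..M_4
#'
#' Computes per-order scalar features that are unchanged by symmetric
#' motion blur.  M_0 is the total mass m00 (preserved exactly by a
#' normalized kernel); M_1 is the magnitude of the raw first-moment
#' vector (m10, m01), preserved because a centered kernel does not move
#' the centroid.  For orders 2..4 the clean image's central moments are
#' reconstructed from the blurred image by estimating (theta, L) with the
#' second-order relations, evaluating the closed-form kernel moments, and
#' inverting the moment convolution theorem; M_r is the Euclidean norm of
#' the reconstructed central moments of total order r.  (Odd central
#' moments of order 3 are directly blur-invariant, since all odd-order
#' kernel moments vanish.)
#'
#' @param image clean reference image.
#' @param blurred a (possibly) blurred version of the same scene, same
#'   size.  If no blur is detectable the blurred image's own moments are
#'   used directly.
#' @param maxOrder highest order feature (default 4).
#' @return named numeric vector \code{M0..M4} (up to \code{maxOrder}).
#' @export
momentInvariants <- function(image, blurred, maxOrder = 4L) {
    stopifnot(all(dim(image) == dim(blurred)))
    maxOrder <- as.integer(maxOrder)
    fC <- geometricMoments(image, maxOrder, "central", source = "image_f")
    gC <- geometricMoments(blurred, maxOrder, "central", source = "image_g")
    gR <- geometricMoments(blurred, min(1L, maxOrder), "raw",
                           source = "image_g")
    rec <- tryCatch({
        theta <- estimateAngleMoments(gC, fC)
        L <- estimateLengthMoments(gC, fC)
        hT <- psfMomentTable(motionBlurParams(L, theta), maxOrder)
        deconvolveMoments(gC, hT)
    }, noBlurError = function(e) gC)
    out <- numeric(maxOrder + 1L)
    names(out) <- paste0("M", 0:maxOrder)
    out["M0"] <- momentValue(gC, 0, 0)
    if (maxOrder >= 1L)
        out["M1"] <- sqrt(momentValue(gR, 1, 0)^2 +
                          momentValue(gR, 0, 1)^2)
    if (maxOrder >= 2L) for (r in 2:maxOrder) {
        p <- 0:r
        out[paste0("M", r)] <-
            sqrt(sum(momentValue(rec, p, r - p)^2))
    }
    out
}
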