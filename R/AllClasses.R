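#' @import methods
NULL

## ---------------------------------------------------------------------------
## Condition helpers: typed errors so callers can distinguish "no blur
## detected" from genuine failures.
## ---------------------------------------------------------------------------

stopUsblur <- function(subclass, msg, call. = FALSE) {
    cond <- structure(
        class = c(subclass, "usblurError", "error", "condition"),
        list(message = msg, call = if (call.) sys.call(-1) else NULL))
    stop(cond)
}

## ---------------------------------------------------------------------------
## MotionBlurParams
## ---------------------------------------------------------------------------

#' Linear motion-blur parameters
#'
#' The pair (length, angle) that parameterizes a linear-motion point-spread
#' function: the probe (or patient) moves at constant velocity during the
#' exposure, sweeping a segment of \code{length} pixels at \code{angle}
#' degrees from the horizontal image axis.  A blur in direction
#' \eqn{\theta} and \eqn{\theta+180^\circ} produces the same symmetric
#' kernel, so angles are normalized into \eqn{[0, 180)}.
#'
#' A length of 0 is the explicit "no blur detected" sentinel returned by
#' the blind estimators; all kernel constructors require length > 0.
#'
#' @slot length blur length in pixels (extent of the motion path).
#' @slot angle blur angle in degrees, normalized into \eqn{[0, 180)}.
#'
#' @aliases MotionBlurParams
#' @exportClass MotionBlurParams
setClass("MotionBlurParams",
    representation(length = "numeric", angle = "numeric"),
    validity = function(object) {
        if (length(object@length) != 1L || !is.finite(object@length))
            return("'length' must be a single finite number")
        if (object@length < 0)
            return("'length' must be >= 0 (0 is the no-blur sentinel)")
        if (length(object@angle) != 1L || !is.finite(object@angle))
            return("'angle' must be a single finite number")
        if (object@angle < 0 || object@angle >= 180)
            return("'angle' must lie in [0, 180)")
        TRUE
    })

#' @param length blur length in pixels; must be positive (0 only as the
#'   internal no-blur sentinel).
#' @param angle blur angle in degrees; any finite value, normalized mod 180.
#' @return \code{motionBlurParams} returns a \code{MotionBlurParams} object.
#' @examples
#' motionBlurParams(20, 30)
#' motionBlurParams(20, 210)  # same kernel as 30 degrees
#' @rdname MotionBlurParams-class
#' @export
motionBlurParams <- function(length, angle) {
    if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
        length < 0)
        stopUsblur("parameterError", "blur length must be a finite number >= 0")
    new("MotionBlurParams", length = as.numeric(length),
        angle = as.numeric(angle) %% 180)
}

#' @param object,x a \code{MotionBlurParams} object.
#' @rdname MotionBlurParams-class
#' @export
setGeneric("blurLength", function(x) standardGeneric("blurLength"))
#' @rdname MotionBlurParams-class
#' @export
setGeneric("blurAngle", function(x) standardGeneric("blurAngle"))

#' @rdname MotionBlurParams-class
#' @export
setMethod("blurLength", "MotionBlurParams", function(x) x@length)
#' @rdname MotionBlurParams-class
#' @export
setMethod("blurAngle", "MotionBlurParams", function(x) x@angle)

#' @rdname MotionBlurParams-class
#' @export
setMethod("show", "MotionBlurParams", function(object) {
    if (object@length == 0)
        cat("MotionBlurParams: no blur (length 0 sentinel)\n")
    else
        cat(sprintf("MotionBlurParams: length %.3g px, angle %.3g deg\n",
                    object@length, object@angle))
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## PSFKernel
## ---------------------------------------------------------------------------

#' Discrete motion-blur point-spread function
#'
#' A small nonnegative kernel with odd side lengths whose entries sum to 1
#' (the blur is passive: no energy is absorbed or created, which also pins
#' the transfer function at DC to 1).  \code{mode} records the
#' rasterization used: \code{"matrix"} snaps each line sample to the
#' nearest pixel and reproduces the textbook printed kernels (e.g. the
#' exact 1/7 diagonal at 45 degrees for length 7), while
#' \code{"subpixel"} distributes a densely sampled line segment with
#' bilinear weights, giving a centrosymmetric kernel whose moments and
#' transfer function track the continuous model closely.
#'
#' @slot weights nonnegative numeric matrix, odd dimensions, sums to 1.
#' @slot center integer (row, col) of the kernel origin (the central pixel).
#' @slot mode \code{"matrix"} or \code{"subpixel"}.
#' @slot params the generating \code{MotionBlurParams}.
#'
#' @aliases PSFKernel
#' @exportClass PSFKernel
setClass("PSFKernel",
    representation(weights = "matrix", center = "integer",
                   mode = "character", params = "MotionBlurParams"),
    validity = function(object) {
        w <- object@weights
        if (!is.numeric(w)) return("'weights' must be numeric")
        if (any(w < 0)) return("kernel weights must be nonnegative")
        if (abs(sum(w) - 1) > 1e-12) return("kernel weights must sum to 1")
        if (nrow(w) %% 2L == 0L || ncol(w) %% 2L == 0L)
            return("kernel side lengths must be odd")
        if (length(object@center) != 2L)
            return("'center' must be (row, col)")
        if (!object@mode %in% c("matrix", "subpixel", "identity"))
            return("unknown rasterization mode")
        TRUE
    })

#' @param object,x a \code{PSFKernel}.
#' @rdname PSFKernel-class
#' @export
setGeneric("psfWeights", function(x) standardGeneric("psfWeights"))
#' @rdname PSFKernel-class
#' @export
setMethod("psfWeights", "PSFKernel", function(x) x@weights)

#' @rdname PSFKernel-class
#' @export
setGeneric("psfCenter", function(x) standardGeneric("psfCenter"))
#' @rdname PSFKernel-class
#' @export
setMethod("psfCenter", "PSFKernel", function(x) x@center)

#' @rdname PSFKernel-class
#' @export
setMethod("show", "PSFKernel", function(object) {
    cat(sprintf("PSFKernel (%s mode): %dx%d, length %.3g px at %.3g deg\n",
                object@mode, nrow(object@weights), ncol(object@weights),
                object@params@length, object@params@angle))
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## FrequencyResponse
## ---------------------------------------------------------------------------

#' Optical transfer function on a DFT grid
#'
#' Complex transfer function of a PSF embedded (center at the origin, with
#' wrap-around) in a width x height frame.  For the normalized kernels
#' produced here the DC coefficient is 1 and, because the kernel is real,
#' the array is conjugate-symmetric.
#'
#' @slot values complex matrix (height rows, width cols), unshifted DFT
#'   layout: element [v+1, u+1] is frequency (u, v).
#' @slot width,height frame size (M columns, N rows).
#'
#' @aliases FrequencyResponse
#' @exportClass FrequencyResponse
setClass("FrequencyResponse",
    representation(values = "matrix", width = "integer", height = "integer"),
    validity = function(object) {
        if (!is.complex(object@values)) return("'values' must be complex")
        if (nrow(object@values) != object@height ||
            ncol(object@values) != object@width)
            return("'values' shape must be height x width")
        TRUE
    })

#' @param object,x a \code{FrequencyResponse}.
#' @rdname FrequencyResponse-class
#' @export
setGeneric("otfValues", function(x) standardGeneric("otfValues"))
#' @rdname FrequencyResponse-class
#' @export
setMethod("otfValues", "FrequencyResponse", function(x) x@values)

#' @rdname FrequencyResponse-class
#' @export
setMethod("show", "FrequencyResponse", function(object) {
    cat(sprintf("FrequencyResponse: %d x %d grid, DC = %.6g\n",
                object@width, object@height, Re(object@values[1, 1])))
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## ABPair
## ---------------------------------------------------------------------------

#' Low-frequency sinc-inverse pair (a, b)
#'
#' The pair obtained by inverting the sinc on the principal branch at the
#' two lowest nonzero frequency bins of the ratio of blurred to clean
#' spectra: a = sinc^-1[G(0,1)/F(0,1)], b = sinc^-1[G(1,0)/F(1,0)].
#' For a linear-motion blur a and b encode L*sin(theta) and L*cos(theta)
#' (scaled by the DFT bin-to-frequency factors pi/N and pi/M), so the
#' motion angle and length follow in closed form and the full blur
#' invariant is xi(u, v) = sinc(a*v + b*u).
#'
#' @slot a,b nonnegative reals on the principal sinc branch [0, pi).
#' @slot width,height the DFT frame (M, N) the pair was measured on.
#'
#' @aliases ABPair
#' @exportClass ABPair
setClass("ABPair",
    representation(a = "numeric", b = "numeric",
                   width = "integer", height = "integer"),
    validity = function(object) {
        if (object@a < 0 || object@b < 0)
            return("'a' and 'b' must be >= 0 on the principal branch")
        TRUE
    })

#' @rdname ABPair-class
#' @param object an \code{ABPair}.
#' @export
setMethod("show", "ABPair", function(object) {
    cat(sprintf("ABPair: a = %.6g, b = %.6g (frame %d x %d)\n",
                object@a, object@b, object@width, object@height))
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## MomentTable
## ---------------------------------------------------------------------------

#' Table of geometric moments
#'
#' Geometric moments m_pq = sum f(x, y) x^p y^q for all p + q <= maxOrder,
#' stored as a (maxOrder+1) x (maxOrder+1) matrix indexed [p+1, q+1]
#' (entries with p + q > maxOrder are NA).  \code{origin} records whether
#' moments are about the pixel-grid origin (\code{"raw"}) or the centroid
#' (\code{"central"}).  Pixel coordinates are 0-based with pixel centers
#' at integers, so length estimates derived from moments are in pixels.
#'
#' @slot values numeric matrix indexed [p+1, q+1].
#' @slot maxOrder maximum total order p + q.
#' @slot origin \code{"raw"} or \code{"central"}.
#' @slot source free-text provenance tag (e.g. "image", "psf").
#'
#' @aliases MomentTable
#' @exportClass MomentTable
setClass("MomentTable",
    representation(values = "matrix", maxOrder = "integer",
                   origin = "character", source = "character"),
    validity = function(object) {
        k <- object@maxOrder + 1L
        if (nrow(object@values) != k || ncol(object@values) != k)
            return("'values' must be (maxOrder+1) square")
        if (!object@origin %in% c("raw", "central"))
            return("'origin' must be 'raw' or 'central'")
        TRUE
    })

#' Extract a single moment from a MomentTable
#'
#' @param x a \code{MomentTable}.
#' @param p,q moment orders along x (columns) and y (rows).
#' @return the moment m_pq.
#' @export
momentValue <- function(x, p, q) {
    stopifnot(is(x, "MomentTable"))
    if (any(p + q > x@maxOrder))
        stopUsblur("parameterError", "requested order exceeds maxOrder")
    x@values[cbind(p + 1L, q + 1L)]
}

#' @param object a \code{MomentTable}.
#' @rdname MomentTable-class
#' @export
setMethod("show", "MomentTable", function(object) {
    cat(sprintf("MomentTable (%s, source '%s') up to order %d; m00 = %.6g\n",
                object@origin, object@source, object@maxOrder,
                object@values[1, 1]))
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## SpectrumMap
## ---------------------------------------------------------------------------

#' DC-centered log-magnitude spectrum of the image gradient
#'
#' The diagnostic map on which the blind estimator operates: the gradient
#' magnitude of the image is Hann-windowed (to suppress the boundary
#' cross), Fourier transformed, and the log magnitude is centered so DC
#' sits at (floor(N/2)+1, floor(M/2)+1).  Motion blur imprints a family of
#' parallel dark "zero lines" whose orientation and spacing encode the
#' blur angle and length.
#'
#' @slot values real matrix (height x width), finite everywhere.
#' @slot width,height frame size.
#'
#' @aliases SpectrumMap
#' @exportClass SpectrumMap
setClass("SpectrumMap",
    representation(values = "matrix", width = "integer", height = "integer"),
    validity = function(object) {
        if (!all(is.finite(object@values)))
            return("spectrum map must be finite everywhere")
        if (nrow(object@values) != object@height ||
            ncol(object@values) != object@width)
            return("'values' shape must be height x width")
        TRUE
    })

#' @param object a \code{SpectrumMap}.
#' @rdname SpectrumMap-class
#' @export
setMethod("show", "SpectrumMap", function(object) {
    cat(sprintf("SpectrumMap: %d x %d log-magnitude gradient spectrum\n",
                object@width, object@height))
    invisible(NULL)
})

## ---------------------------------------------------------------------------
## MotionEstimate
## ---------------------------------------------------------------------------

#' Result of blind motion-parameter estimation
#'
#' Bundles the estimated \code{MotionBlurParams} with diagnostics of the
#' spectral geometry: the orientation-energy ratio (peak projection
#' variance over the median across angles; low values mean no dominant
#' line orientation, i.e. no detectable blur) and the number of zero-line
#' minima used for the length estimate.
#'
#' @slot params estimated \code{MotionBlurParams}.
#' @slot energyRatio orientation-energy ratio from the Radon criterion.
#' @slot nMinima number of spectral minima used for the spacing estimate.
#' @slot method estimation route, currently \code{"spectral"}.
#'
#' @aliases MotionEstimate
#' @exportClass MotionEstimate
setClass("MotionEstimate",
    representation(params = "MotionBlurParams", energyRatio = "numeric",
                   nMinima = "integer", method = "character"))

#' @param x,object a \code{MotionEstimate}.
#' @rdname MotionEstimate-class
#' @export
setGeneric("estimatedParams", function(x) standardGeneric("estimatedParams"))
#' @rdname MotionEstimate-class
#' @export
setMethod("estimatedParams", "MotionEstimate", function(x) x@params)

#' @rdname MotionEstimate-class
#' @export
setMethod("blurLength", "MotionEstimate", function(x) x@params@length)
#' @rdname MotionEstimate-class
#' @export
setMethod("blurAngle", "MotionEstimate", function(x) x@params@angle)

#' @rdname MotionEstimate-class
#' @export
setMethod("show", "MotionEstimate", function(object) {
    cat(sprintf(paste0("MotionEstimate (%s): length %.4g px, angle %.4g deg",
                       " [energy ratio %.3g, %d minima]\n"),
                object@method, object@params@length, object@params@angle,
                object@energyRatio, object@nMinima))
    invisible(NULL)
})
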