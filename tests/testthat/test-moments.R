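test_that("geometric moments match the brute-force oracle and point masses", {
    ## point mass: m_pq = x0^p * y0^q
    img <- matrix(0, 8, 8); img[3, 5] <- 1    # x0 = 4, y0 = 2
    mt <- geometricMoments(img, 3)
    for (p in 0:3) for (q in 0:(3 - p))
        expect_equal(momentValue(mt, p, q), 4^p * 2^q)
    ## random image vs double loop
    set.seed(2)
    img <- matrix(runif(256), 16, 16)
    for (origin in c("raw", "central")) {
        mt <- geometricMoments(img, 4, origin)
        for (p in 0:4) for (q in 0:(4 - p)) {
            ref <- bruteMoments(img, p, q, central = origin == "central")
            expect_equal(momentValue(mt, p, q), ref,
                         tolerance = 1e-10)
        }
    }
    ## central moments are translation invariant
    big <- matrix(0, 24, 24); big[5:12, 3:10] <- img[1:8, 1:8]
    big2 <- matrix(0, 24, 24); big2[11:18, 13:20] <- img[1:8, 1:8]
    m1 <- geometricMoments(big, 3, "central")
    m2 <- geometricMoments(big2, 3, "central")
    expect_equal(m1@values, m2@values, tolerance = 1e-9)
    expect_error(geometricMoments(matrix(0, 4, 4), 2, "central"),
                 class = "degenerateImageError")
})

test_that("closed-form PSF moments match the line-mass model", {
    p <- motionBlurParams(12, 37)
    expect_equal(psfMomentsClosedForm(p, 0, 0), 1)
    expect_equal(psfMomentsClosedForm(p, 1, 0), 0)   # odd order
    expect_equal(psfMomentsClosedForm(p, 2, 1), 0)
    ## (L/2)^2 cos^2(0) / 3 at L = 2 is 1/3
    expect_equal(psfMomentsClosedForm(motionBlurParams(2, 0), 2, 0), 1 / 3)
    ## numerical quadrature of the uniform line mass agrees
    L <- 10; th <- 55 * pi / 180
    for (pq in list(c(2, 0), c(1, 1), c(2, 2), c(4, 0))) {
        num <- stats::integrate(function(t)
            (t * cos(th))^pq[1] * (t * sin(th))^pq[2] / L,
            -L / 2, L / 2, rel.tol = 1e-10)$value
        expect_equal(psfMomentsClosedForm(motionBlurParams(L, 55),
                                          pq[1], pq[2]),
                     num, tolerance = 1e-8)
    }
})

test_that("closed-form kernel moments track the discrete subpixel kernel", {
    ## agreement at each order's magnitude scale; the rasterized line
    ## carries a unit-width cross-section (second moment ~ 1/12), so the
    ## discretization error scales as 1/L^2: within 2% for L >= 20 and
    ## 8% at L = 10
    for (L in c(10, 20, 40)) for (th in c(0, 30, 60, 85)) {
        pa <- motionBlurParams(L, th)
        w <- psfWeights(makeMotionPSF(pa, "subpixel"))
        mt <- geometricMoments(w, 4, "central", "psf")
        tol <- if (L >= 20) 0.02 else 0.08
        for (n in c(2, 4)) for (p in 0:n) {
            scale <- (L / 2)^n / (n + 1)
            expect_lt(abs(momentValue(mt, p, n - p) -
                          psfMomentsClosedForm(pa, p, n - p)) / scale,
                      tol)
        }
    }
})

test_that("moment convolution theorem is exact for discrete convolution", {
    ## identity kernel leaves moments unchanged
    set.seed(4)
    img <- matrix(runif(64), 8, 8)
    fM <- geometricMoments(img, 4)
    idM <- geometricMoments(matrix(1, 1, 1), 4, source = "psf")
    expect_equal(convolveMoments(fM, idM)@values, fM@values)
    ## full-support discrete convolution oracle
    ker <- matrix(runif(9), 3, 3); ker <- ker / sum(ker)
    out <- matrix(0, 10, 10)
    for (i in 1:8) for (j in 1:8) for (a in 1:3) for (b in 1:3)
        out[i + a - 1, j + b - 1] <- out[i + a - 1, j + b - 1] +
            img[i, j] * ker[a, b]
    ## kernel raw moments about its 0-based corner match the shifted
    ## output coordinates (y_g = y_f + y_h)
    kM <- geometricMoments(ker, 4, source = "psf")
    big <- matrix(0, 10, 10); big[1:8, 1:8] <- img
    pred <- convolveMoments(geometricMoments(big, 4), kM)
    gM <- geometricMoments(out, 4)
    expect_equal(pred@values, gM@values, tolerance = 1e-8)
    ## m00 multiplies: normalized kernel preserves mass
    expect_equal(momentValue(gM, 0, 0), momentValue(fM, 0, 0),
                 tolerance = 1e-12)
    expect_error(convolveMoments(geometricMoments(img, 3), kM),
                 class = "usblurError")
})

test_that("angle/length estimators invert the analytic moment relations exactly", {
    f <- cachedPhantom()
    fC <- geometricMoments(f, 4, "central")
    hT <- psfMomentTable(motionBlurParams(40, 45), 4)
    gT <- convolveMoments(fC, hT)
    expect_equal(estimateAngleMoments(gT, fC), 45, tolerance = 1e-6)
    expect_equal(estimateLengthMoments(gT, fC), 40, tolerance = 1e-6)
    ## limit cases on synthetic moment tables
    mk <- function(d20, d02) {
        v <- fC@values
        v[3, 1] <- v[3, 1] + d20
        v[1, 3] <- v[1, 3] + d02
        new("MomentTable", values = v, maxOrder = 4L,
            origin = "central", source = "image_g")
    }
    expect_equal(estimateAngleMoments(mk(5, 5), fC), 45)
    expect_equal(estimateAngleMoments(mk(7, 0), fC), 0)
    expect_equal(estimateAngleMoments(mk(0, 7), fC), 90)
    expect_error(estimateAngleMoments(fC, fC), class = "noBlurError")
    expect_error(estimateLengthMoments(fC, fC), class = "noBlurError")
})

test_that("second-order moment growth follows (L^2/12) cos^2/sin^2 on simulation", {
    f <- cachedPhantom()
    L <- 30; th <- 60
    g <- degradeImage(f, motionBlurParams(L, th))
    fC <- geometricMoments(f, 2, "central")
    gC <- geometricMoments(g, 2, "central")
    m00 <- momentValue(fC, 0, 0)
    d20 <- momentValue(gC, 2, 0) - momentValue(fC, 2, 0)
    d02 <- momentValue(gC, 0, 2) - momentValue(fC, 0, 2)
    expect_equal(d20, L^2 / 12 * cos(th * pi / 180)^2 * m00,
                 tolerance = 0.05)
    expect_equal(d02, L^2 / 12 * sin(th * pi / 180)^2 * m00,
                 tolerance = 0.05)
})

test_that("moment estimators recover simulation parameters", {
    f <- cachedPhantom()
    for (s in list(c(30, 60), c(20, 30), c(40, 45))) {
        g <- degradeImage(f, motionBlurParams(s[1], s[2]))
        fC <- geometricMoments(f, 2, "central")
        gC <- geometricMoments(g, 2, "central")
        expect_lt(angleErr(estimateAngleMoments(gC, fC), s[2]), 2)
        expect_lt(abs(estimateLengthMoments(gC, fC) - s[1]) / s[1], 0.1)
    }
})

test_that("moment invariant features are stable across blur settings", {
    f <- cachedPhantom()
    ## identical images reproduce the clean values exactly
    Mclean <- momentInvariants(f, f)
    expect_equal(unname(Mclean["M0"]), sum(f))
    settings <- list(c(20, 30), c(40, 45), c(30, 60), c(50, 85))
    M <- sapply(settings, function(s)
        momentInvariants(f, degradeImage(f, motionBlurParams(s[1], s[2]))))
    ## raw first moments preserved by centered kernels (0.1%)
    for (j in seq_along(settings)) {
        expect_equal(unname(M["M0", j]), unname(Mclean["M0"]),
                     tolerance = 1e-3)
        expect_equal(unname(M["M1", j]), unname(Mclean["M1"]),
                     tolerance = 1e-3)
    }
    ## higher orders: relative spread across the four versions <= 5%
    for (r in c("M2", "M3", "M4")) {
        spread <- (max(M[r, ]) - min(M[r, ])) / mean(M[r, ])
        expect_lt(spread, 0.05)
    }
})
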