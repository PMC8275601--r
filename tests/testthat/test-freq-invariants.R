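test_that("sinc inversion round-trips on the principal branch", {
    xs <- seq(0, 0.9 * pi, length.out = 40)
    expect_equal(sincInv(sincu(xs)), xs, tolerance = 1e-8)
    expect_equal(sincInv(1), 0)
    expect_equal(sincInv(sincu(c(0.5, 0.25))), c(0.5, 0.25),
                 tolerance = 1e-9)
    expect_error(sincInv(1.01), class = "outOfBranchError")
    expect_error(sincInv(-0.1), class = "outOfBranchError")
})

test_that("computeAB recovers (a, b) and the motion parameters", {
    f <- cachedPhantom()
    ## no blur: a = b = 0 and the no-blur sentinel
    ab0 <- computeAB(f, f)
    expect_equal(ab0@a, 0)
    expect_equal(ab0@b, 0)
    p0 <- angleLengthFromAB(ab0)
    expect_equal(blurLength(p0), 0)
    ## 45 degrees forces a = b (within discretization)
    g <- degradeImage(f, motionBlurParams(40, 45))
    ab <- computeAB(f, g)
    expect_lt(abs(ab@a - ab@b) / ab@a, 0.02)
    p <- angleLengthFromAB(ab)
    expect_lt(angleErr(blurAngle(p), 45), 2)
    expect_lt(abs(blurLength(p) - 40) / 40, 0.1)
})

test_that("angleLengthFromAB limit cases", {
    mk <- function(a, b) new("ABPair", a = a, b = b,
                             width = 256L, height = 256L)
    expect_equal(blurAngle(angleLengthFromAB(mk(0.4, 0.4))), 45)
    expect_equal(blurAngle(angleLengthFromAB(mk(0.3, 0))), 90)
    expect_equal(blurAngle(angleLengthFromAB(mk(0, 0.3))), 0)
    ## vertical motion: L = a * N / pi
    expect_equal(blurLength(angleLengthFromAB(mk(0.3, 0))), 0.3 * 256 / pi)
})

test_that("xi equals sinc(av+bu) and matches measured ratios across frequencies", {
    f <- cachedPhantom()
    g <- degradeImage(f, motionBlurParams(30, 60))
    ab <- computeAB(f, g)
    expect_equal(xiInvariant(0, 0, ab), 1)
    expect_equal(xiInvariant(1, 0, ab), sincu(ab@b))
    expect_equal(xiInvariant(0, 1, ab), sincu(ab@a))
    set.seed(11)
    uv <- cbind(sample(-5:5, 20, TRUE), sample(-5:5, 20, TRUE))
    Fm <- stats::fft(f); Gm <- stats::fft(g)
    idx <- cbind((uv[, 2] %% 256) + 1L, (uv[, 1] %% 256) + 1L)
    measured <- Gm[idx] / Fm[idx]
    predicted <- xiInvariant(uv[, 1], uv[, 2], ab)
    expect_lte(median(abs(Mod(measured) - abs(predicted))), 0.05)
})

test_that("invariantTable reports amplitude/phase with validity flags", {
    f <- cachedPhantom(128, 128, seed = 3)
    tab <- invariantTable(f, f, cbind(c(0, 1, 2), c(0, 1, -1)))
    expect_equal(tab$amplitude, rep(1, 3), tolerance = 1e-9)
    expect_equal(tab$phase_rad, rep(0, 3), tolerance = 1e-9)
    g <- degradeImage(f, motionBlurParams(20, 30))
    tab2 <- invariantTable(f, g, cbind(0, 0))
    expect_equal(tab2$amplitude, 1, tolerance = 1e-9)  # DC preserved
    expect_error(invariantTable(f, g, cbind(numeric(0), numeric(0))),
                 class = "usblurError")
})

test_that("slow-scan and fast-scan blurs both match their own sinc prediction", {
    f <- cachedPhantom()
    set.seed(5)
    uv <- cbind(sample(-5:5, 20, TRUE), sample(-5:5, 20, TRUE))
    for (L in c(10, 50)) {
        g <- degradeImage(f, motionBlurParams(L, 30))
        tab <- invariantTable(f, g, uv)
        dev <- abs(tab$amplitude - abs(tab$predicted))
        expect_lte(max(dev, na.rm = TRUE), 0.05)
    }
})

test_that("parameter recovery from low-frequency ratios holds over the grid", {
    f <- cachedPhantom()
    for (L in c(10, 20, 30, 40)) for (th in c(15, 30, 45, 60, 75)) {
        g <- degradeImage(f, motionBlurParams(L, th))
        p <- angleLengthFromAB(computeAB(f, g))
        expect_lt(angleErr(blurAngle(p), th), 2)
        expect_lt(abs(blurLength(p) - L) / L, 0.1)
    }
})
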