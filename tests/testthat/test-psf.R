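test_that("matrix-mode kernel at 45 degrees reproduces the printed 1/7 diagonal", {
    k <- makeMotionPSF(motionBlurParams(7, 45), mode = "matrix")
    expect_equal(psfWeights(k), diag(7) / 7, tolerance = 1e-14)
    nz <- psfWeights(k)[psfWeights(k) > 0]
    expect_length(nz, 7L)
    expect_true(all(abs(nz - 1 / 7) < 1e-14))
})

test_that("degenerate and axis-aligned kernels match closed forms", {
    ## zero-extent motion is the identity blur
    for (mode in c("matrix", "subpixel")) {
        k <- makeMotionPSF(motionBlurParams(1, 33), mode = mode)
        expect_equal(psfWeights(k), matrix(1, 1, 1))
    }
    ## horizontal motion: a centered row of 1/L
    k <- makeMotionPSF(motionBlurParams(7, 0), mode = "matrix")
    w <- psfWeights(k)
    expect_equal(dim(w), c(7L, 7L))
    expect_equal(w[4L, ], rep(1 / 7, 7), tolerance = 1e-14)
    expect_equal(sum(w[-4L, ]), 0)
    ## angle normalization: theta and theta + 180 give the same kernel
    k1 <- makeMotionPSF(motionBlurParams(11, 25))
    k2 <- makeMotionPSF(motionBlurParams(11, 205))
    expect_equal(psfWeights(k1), psfWeights(k2))
    expect_error(makeMotionPSF(motionBlurParams(0, 0)), class = "usblurError")
})

test_that("kernels are normalized and subpixel kernels centrosymmetric over a grid", {
    for (L in c(5, 10, 20, 40, 60)) for (th in c(0, 30, 45, 60, 85)) {
        for (mode in c("matrix", "subpixel")) {
            w <- psfWeights(makeMotionPSF(motionBlurParams(L, th), mode))
            expect_true(all(w >= 0))
            expect_equal(sum(w), 1, tolerance = 1e-12)
        }
        w <- psfWeights(makeMotionPSF(motionBlurParams(L, th), "subpixel"))
        flipped <- w[rev(seq_len(nrow(w))), rev(seq_len(ncol(w)))]
        expect_lt(max(abs(w - flipped)), 1e-12)
        ## support covers the segment endpoints
        ext <- ceiling(L / 2 * max(abs(cos(th * pi / 180)),
                                   abs(sin(th * pi / 180))))
        expect_gte((nrow(w) - 1) / 2, ext - 1)
        ## odd-order central moments vanish (symmetry prerequisite)
        mt <- geometricMoments(w, 3, "central", "psf")
        for (p in 0:3) for (q in 0:(3 - p)) {
            if ((p + q) %% 2 == 1)
                expect_lt(abs(momentValue(mt, p, q)), 1e-9 * (L / 2)^(p + q))
        }
    }
})

test_that("analytic OTF has unit DC, sinc zeros, and matches the kernel DFT", {
    for (L in c(8, 20)) for (th in c(0, 30, 75)) {
        expect_equal(analyticOTF(motionBlurParams(L, th), 0, 0, 128, 128), 1)
    }
    ## first sinc zero along the motion axis at u = M/L
    expect_equal(analyticOTF(motionBlurParams(16, 0), u = 128 / 16, v = 0,
                             128, 128), 0, tolerance = 1e-12)
    ## vertical motion is constant along the orthogonal frequency axis
    p90 <- motionBlurParams(10, 90)
    expect_equal(analyticOTF(p90, u = 0:20, v = 0, 128, 128), rep(1, 21))
    H <- otfValues(psfOTF(makeMotionPSF(p90, "subpixel"), 128, 128))
    expect_lt(max(abs(Re(H[1L, 1:21]) - 1)), 0.02)
    ## range of the sinc
    vals <- analyticOTF(motionBlurParams(40, 30), -64:63, 17, 128, 128)
    expect_true(all(vals <= 1 + 1e-12 & vals >= -0.2173))
})

test_that("numerical OTF: DC equals kernel sum and zero spacing follows M/L", {
    ## identity kernel -> all-ones response
    H0 <- otfValues(psfOTF(makeMotionPSF(motionBlurParams(1, 0)), 32, 32))
    expect_lt(max(Mod(H0 - 1)), 1e-12)
    psf <- makeMotionPSF(motionBlurParams(20, 0), "subpixel")
    H <- otfValues(psfOTF(psf, 128, 128))
    expect_equal(Re(H[1L, 1L]), 1, tolerance = 1e-12)
    ## conjugate symmetry for a real kernel
    expect_lt(max(Mod(H - Conj(H[c(1L, 128:2), c(1L, 128:2)]))), 1e-9)
    ## first sign change along u near 128/20 = 6.4 bins
    re <- Re(H[1L, 1:20])
    firstZero <- which(diff(sign(re)) != 0)[1L]
    expect_true(firstZero %in% c(6L, 7L))
    ## kernel larger than frame errors
    expect_error(psfOTF(makeMotionPSF(motionBlurParams(40, 45)), 16, 16),
                 class = "sizeError")
})

test_that("analytic and numerical OTF agree at low frequencies", {
    for (th in c(0, 30, 60)) {
        pa <- motionBlurParams(20, th)
        H <- otfValues(psfOTF(makeMotionPSF(pa, "subpixel"), 128, 128))
        uv <- expand.grid(u = 0:12, v = 0:12)  # lowest ~10% of bins
        ha <- analyticOTF(pa, uv$u, uv$v, 128, 128)
        hn <- Re(H[cbind(uv$v + 1L, uv$u + 1L)])
        expect_lt(max(abs(ha - hn)), 0.05)
    }
})

test_that("PSF kernels round-trip through text and float-TIFF files", {
    k <- makeMotionPSF(motionBlurParams(9, 30))
    txt <- withr::local_tempfile(fileext = ".txt")
    tif <- withr::local_tempfile(fileext = ".tif")
    writePSF(k, txt)
    expect_lt(max(abs(psfWeights(readPSF(txt)) - psfWeights(k))), 1e-12)
    writePSF(k, tif)
    expect_lt(max(abs(psfWeights(readPSF(tif)) - psfWeights(k))), 1e-6)
})
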