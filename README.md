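# usblur

Motion-blur modeling, blur-invariant features, blind motion-parameter
estimation, and Wiener restoration for B-mode ultrasound images.

Freehand scanning blurs an ultrasound frame along the probe's motion
path. The degradation is a convolution with a line-segment
point-spread function parameterized by a length *L* (pixels) and an
angle *θ* (degrees from the horizontal image axis):

    g = f * h(L, θ) + n,     h(x, y) = (1/L) ∫ δ(x − t cosθ) δ(y − t sinθ) dt

Because the PSF is passive (Σh = 1, H(0,0) = 1) and its transfer
function is a sinc with zeros on the parallel lines
u·cosθ/M + v·sinθ/N = ±k/L, the blur leaves fingerprints that this
package exploits three ways:

* **Frequency invariants** (clean reference available): the ratio
  ξ(u,v) = G/F equals sinc(av + bu) for every frequency, where
  a = sinc⁻¹[G(0,1)/F(0,1)] and b = sinc⁻¹[G(1,0)/F(1,0)]; θ and L
  follow in closed form (`computeAB`, `angleLengthFromAB`,
  `xiInvariant`, `invariantTable`).
* **Moment invariants**: geometric moments of a convolution combine
  binomially, the line kernel has closed-form moments, and
  second-order moment growth yields θ = atan√(Δm02/Δm20) and
  L = 2√3·√((Δm20+Δm02)/m00) (`geometricMoments`, `convolveMoments`,
  `estimateAngleMoments`, `estimateLengthMoments`,
  `momentInvariants`).
* **Blind spectral estimation** (single blurred image): the
  log-spectrum of the image gradient shows dark zero lines whose
  orientation gives θ (Radon projection-variance criterion) and whose
  spacing d gives L = S/d with S the effective frame extent along the
  motion (`spectrumMap`, `estimateAngleSpectrum`,
  `estimateLengthSpectrum`, `estimateParams`).

Restoration is Wiener deconvolution with a constant noise-to-signal
ratio (`wienerDeconvolve`, `blindDeblur`); quality is scored with SSIM
and a block acutance map (`ssim`, `acutanceMap`). A seeded
ultrasound-like phantom generator (`generatePhantom`, `degradeImage`)
makes the whole pipeline testable without clinical data.

## Worked example

```r
library(usblur)

f <- generatePhantom(256, 256, seed = 7)          # clean phantom
g <- degradeImage(f, motionBlurParams(40, 45))    # blur: 40 px at 45 deg

estimateParams(g)                                 # blind, single image
#> MotionEstimate (spectral): length 39.99 px, angle 45 deg [energy ratio 106, 32 minima]

res <- blindDeblur(g, nsr = 1e-6)
ssim(g, f)                                        # 0.521  (blurred)
ssim(res$image, f)                                # 0.890  (restored)

## with the clean reference: frequency route ...
angleLengthFromAB(computeAB(f, g))
#> MotionBlurParams: length 40 px, angle 45 deg

## ... and moment route
fC <- geometricMoments(f, 2, "central")
gC <- geometricMoments(g, 2, "central")
estimateAngleMoments(gC, fC)                      # 45.00 deg
estimateLengthMoments(gC, fC)                     # 40.05 px
```

The blind estimate reads the blur parameters off the spectral zero-line
geometry alone; the energy ratio (peak orientation variance over its
baseline, here 106 against a detection threshold of 8) and the number
of zero-line minima are its confidence diagnostics. Restoration lifts
structural similarity to the clean scene from 0.52 to 0.89.

A command-line front end ships in `inst/cli/usblur`
(`synth`, `blur`, `estimate`, `deblur`, `invariants`, `quality`), e.g.:

```sh
usblur=$(Rscript -e 'cat(system.file("cli","usblur",package="usblur"))')
Rscript $usblur synth --width 256 --height 256 --seed 7 -o phantom.png
Rscript $usblur blur phantom.png --length 20 --angle 30 -o blurred.png
Rscript $usblur estimate blurred.png --json
```

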