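## Shared fixtures: phantoms are deterministic per seed, so cache them
## across tests instead of regenerating.

.phantomCache <- new.env(parent = emptyenv())

cachedPhantom <- function(width = 256L, height = width, seed = 7L) {
    key <- paste(width, height, seed, sep = "_")
    if (is.null(.phantomCache[[key]]))
        .phantomCache[[key]] <- generatePhantom(width, height, seed = seed)
    .phantomCache[[key]]
}

## brute-force geometric moments: the independent oracle
bruteMoments <- function(img, p, q, central = FALSE) {
    xs <- seq_len(ncol(img)) - 1
    ys <- seq_len(nrow(img)) - 1
    if (central) {
        m00 <- sum(img)
        xb <- 0; yb <- 0
        for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
            xb <- xb + img[r, cc] * xs[cc]
            yb <- yb + img[r, cc] * ys[r]
        }
        xs <- xs - xb / m00
        ys <- ys - yb / m00
    }
    acc <- 0
    for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img)))
        acc <- acc + img[r, cc] * xs[cc]^p * ys[r]^q
    acc
}

angleErr <- function(a, b) {
    d <- abs(a - b) %% 180
    min(d, 180 - d)
}
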