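## Shared fixture builders and independent oracles. Oracles are deliberately
## naive (double loops, direct formulas) so they stay independent of the
## implementation paths they check.

## Brute-force NCC: scalar loops over placements and pixels.
bruteNcc <- function(template, search) {
    th <- nrow(template); tw <- ncol(template)
    nr <- nrow(search) - th + 1; nc <- ncol(search) - tw + 1
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        s <- 0; sa2 <- 0; sb2 <- 0
        am <- 0; bm <- 0
        for (y in seq_len(th)) for (x in seq_len(tw)) {
            am <- am + template[y, x]
            bm <- bm + search[i + y - 1, j + x - 1]
        }
        am <- am / (th * tw); bm <- bm / (th * tw)
        for (y in seq_len(th)) for (x in seq_len(tw)) {
            a <- template[y, x] - am
            b <- search[i + y - 1, j + x - 1] - bm
            s <- s + a * b; sa2 <- sa2 + a * a; sb2 <- sb2 + b * b
        }
        out[i, j] <- if (sa2 == 0 || sb2 == 0) 0 else s / sqrt(sa2 * sb2)
    }
    out
}

## Element-loop mean of a list of matrices.
bruteMean <- function(mats) {
    out <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
    for (y in seq_len(nrow(out))) for (x in seq_len(ncol(out))) {
        s <- 0
        for (m in mats) s <- s + m[y, x]
        out[y, x] <- s / length(mats)
    }
    out
}

## RMS distance of detected corners to the ideal template grid, treated as
## periodic (cells can enter or leave the frame under correction, so the
## finite template is extended by its own pitch).
latticeRmsToTemplate <- function(det, tmpl) {
    pitchY <- tmpl@y[2, 1] - tmpl@y[1, 1]
    pitchX <- tmpl@x[1, 2] - tmpl@x[1, 1]
    ry <- ((det@y - tmpl@y[1, 1] + pitchY / 2) %% pitchY) - pitchY / 2
    rx <- ((det@x - tmpl@x[1, 1] + pitchX / 2) %% pitchX) - pitchX / 2
    sqrt(mean(ry^2 + rx^2))
}

## A small on-disk acquisition used by several test files.
makeSmallBrain <- function(root, brainId = "TB01", nSections = 2,
                           rows = 2, cols = 2, tilePx = 160, stepPx = 120,
                           channels = c("red", "green"), seed = 5, ...) {
    writeFixtureTree(root, brainId, nSections, tilesPerCol = rows,
                     tilesPerRow = cols, tileHeightPx = tilePx,
                     tileWidthPx = tilePx, stepYPx = stepPx, stepXPx = stepPx,
                     channelNames = channels, cellDensity = 400, seed = seed,
                     ...)
}
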