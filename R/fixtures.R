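## Synthetic-acquisition generators with known ground truth. Every stage of
## the pipeline is testable against these fixtures without instrument data.

#' Generate a synthetic phantom section
#'
#' Renders Gaussian-profile bright disks ("cells") on a uniform background
#' with additive Gaussian noise. The sampling procedure is, in order, under
#' `set.seed(spec@seed)`: the cell count is drawn as
#' `rpois(1, cellDensity * heightPx * widthPx / 1e6)`, then cell centers
#' `runif(n, 1, heightPx)` and `runif(n, 1, widthPx)`, then the noise field
#' `rnorm(heightPx * widthPx, 0, noiseSd)`. The generator is a pure function
#' of its specification: identical specs give bit-identical images.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [SectionImage-class]; `@provenance$nCells` records the number of
#'   cells drawn.
#' @examples
#' ph <- generatePhantomSection(phantomSpec(200, 300, seed = 7))
#' dim(pixels(ph))
#' @export
generatePhantomSection <- function(spec) {
    validObject(spec)
    h <- spec@heightPx; w <- spec@widthPx
    img <- matrix(spec@backgroundLevel, h, w)
    drawn <- withSeed(spec@seed, {
        n <- rpois(1, spec@cellDensity * h * w / 1e6)
        cy <- if (n > 0) runif(n, 1, h) else numeric()
        cx <- if (n > 0) runif(n, 1, w) else numeric()
        noise <- if (spec@noiseSd > 0) rnorm(h * w, 0, spec@noiseSd) else NULL
        list(n = n, cy = cy, cx = cx, noise = noise)
    })
    sigma <- spec@cellRadiusPx / 2
    support <- ceiling(2 * spec@cellRadiusPx)
    for (k in seq_len(drawn$n)) {
        ys <- max(1, floor(drawn$cy[k] - support)):min(h, ceiling(drawn$cy[k] + support))
        xs <- max(1, floor(drawn$cx[k] - support)):min(w, ceiling(drawn$cx[k] + support))
        d2 <- outer((ys - drawn$cy[k])^2, (xs - drawn$cx[k])^2, "+")
        blob <- spec@cellAmplitude * exp(-d2 / (2 * sigma^2))
        blob[d2 > support^2] <- 0
        img[ys, xs] <- img[ys, xs] + blob
    }
    if (!is.null(drawn$noise)) img <- img + matrix(drawn$noise, h, w)
    img[img < 0] <- 0
    img[img > 65535] <- 65535
    sectionImage(img, sectionIndex = 0L, channel = "synthetic",
                 provenance = list(nCells = drawn$n, seed = spec@seed))
}

#' Render a vignetting gain image
#'
#' The gain equals `centerGain` at the (continuous) tile center, decreases
#' radially, and equals `edgeGain` at the farthest corner pixel. Both the
#' quadratic and the Gaussian falloff hit the corner value exactly.
#'
#' @param model a [VignetteModel-class].
#' @return Numeric gain matrix in (0, 1], tile-shaped.
#' @examples
#' g <- makeVignetteGain(vignetteModel(101, 101, edgeGain = 0.5))
#' range(g)
#' @export
makeVignetteGain <- function(model) {
    validObject(model)
    h <- model@tileHeightPx; w <- model@tileWidthPx
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
    dmax <- sqrt((cy - 1)^2 + (cx - 1)^2)
    cg <- model@centerGain; eg <- model@edgeGain
    if (cg == eg) return(matrix(cg, h, w))
    r2 <- (d / dmax)^2
    switch(model@profileShape,
        radial_quadratic = cg - (cg - eg) * r2,
        radial_gaussian = cg * exp(-r2 * log(cg / eg)))
}

#' Generate a smooth synthetic warp field
#'
#' Draws Gaussian control values on a coarse grid of spacing
#' `smoothnessScalePx`, bicubically upsamples them to a dense per-pixel
#' displacement field, and rescales so the maximum displacement magnitude
#' equals `amplitudePx`.
#'
#' @param heightPx,widthPx field dimensions in pixels.
#' @param amplitudePx maximum displacement magnitude in pixels.
#' @param smoothnessScalePx control-point spacing in pixels.
#' @param seed RNG seed.
#' @return A [SyntheticWarp-class].
#' @export
makeSyntheticWarp <- function(heightPx, widthPx, amplitudePx = 3,
                              smoothnessScalePx = 80, seed = 1L) {
    stopIfNot(isCount(heightPx) && isCount(widthPx), "dimensions must be positive integers")
    stopIfNot(amplitudePx >= 0, "amplitudePx must be >= 0")
    stopIfNot(smoothnessScalePx > 0, "smoothnessScalePx must be positive")
    s <- smoothnessScalePx
    n <- max(4L, ceiling((heightPx + 2 * s) / s) + 1L)
    m <- max(4L, ceiling((widthPx + 2 * s) / s) + 1L)
    ctrl <- withSeed(seed, list(dy = matrix(rnorm(n * m), n, m),
                                dx = matrix(rnorm(n * m), n, m)))
    ## pixel y (1-based) sits at control index ((y - 1) + s) / s + 1
    u <- ((seq_len(heightPx) - 1) + s) / s + 1
    v <- ((seq_len(widthPx) - 1) + s) / s + 1
    dy <- bicubicGrid(ctrl$dy, u, v)
    dx <- bicubicGrid(ctrl$dx, u, v)
    mx <- max(sqrt(dy^2 + dx^2))
    if (amplitudePx == 0 || mx == 0) {
        dy[] <- 0; dx[] <- 0
    } else {
        dy <- dy * (amplitudePx / mx)
        dx <- dx * (amplitudePx / mx)
    }
    new("SyntheticWarp", dy = dy, dx = dx, amplitudePx = amplitudePx,
        smoothnessScalePx = smoothnessScalePx, seed = seed)
}

#' Apply a synthetic warp to an image
#'
#' Inverse mapping: the warped image at pixel `p` samples the source at
#' `p - d(p)` by bilinear interpolation, with out-of-range coordinates
#' clamped to the nearest edge pixel — the same resampling convention the
#' distortion-correction module uses. A feature at source position `q`
#' therefore appears at the fixed point `p = q + d(p)` (see [warpPoints()]).
#'
#' @param img numeric matrix, same shape as the warp field.
#' @param warp a [SyntheticWarp-class].
#' @return Warped numeric matrix.
#' @export
warpImage <- function(img, warp) {
    stopIfNot(identical(dim(img), dim(warp@dy)), "image and warp shapes must match")
    h <- nrow(img); w <- ncol(img)
    Y <- matrix(seq_len(h), h, w)
    X <- matrix(seq_len(w), h, w, byrow = TRUE)
    matrix(bilinearSample(img, Y - warp@dy, X - warp@dx), h, w)
}

#' Warped position of source points
#'
#' Solves the fixed point `p = q + d(p)` by iteration, giving the exact
#' position in the warped image (per the [warpImage()] convention) of a
#' feature located at `q` in the source. Coordinates are 0-based pixels.
#'
#' @param warp a [SyntheticWarp-class].
#' @param y,x numeric vectors of 0-based source coordinates.
#' @return List with components `y` and `x` of warped positions.
#' @export
warpPoints <- function(warp, y, x) {
    py <- y; px <- x
    for (it in 1:50) {
        dy <- bilinearSample(warp@dy, py + 1, px + 1)
        dx <- bilinearSample(warp@dx, py + 1, px + 1)
        ny <- y + dy; nx <- x + dx
        if (max(abs(ny - py), abs(nx - px)) < 1e-10) { py <- ny; px <- nx; break }
        py <- ny; px <- nx
    }
    list(y = py, x = px)
}

#' Slice a section into overlapping tiles with known ground truth
#'
#' Crops a `tilesPerCol x tilesPerRow` grid of tiles of size
#' `tileHeightPx x tileWidthPx` at steps `(stepYPx, stepXPx)` (steps smaller
#' than the tile size, so neighbors overlap), then optionally multiplies each
#' tile by a vignetting gain and applies a synthetic warp. Ground-truth
#' placements are returned exactly.
#'
#' @param section a [SectionImage-class] or numeric matrix.
#' @param tilesPerCol,tilesPerRow tile grid shape (rows, columns).
#' @param stepYPx,stepXPx tile steps in pixels.
#' @param tileHeightPx,tileWidthPx tile dimensions in pixels.
#' @param gain `NULL`, a gain matrix, or a [VignetteModel-class].
#' @param warp `NULL` or a [SyntheticWarp-class] (tile-shaped).
#' @return List with `tiles` (list of [Tile-class], raster order) and
#'   `positions` (data.frame of zero-based `row`, `col`, `y0`, `x0`).
#' @export
sliceIntoTiles <- function(section, tilesPerCol, tilesPerRow,
                           stepYPx, stepXPx, tileHeightPx, tileWidthPx,
                           gain = NULL, warp = NULL) {
    img <- if (is(section, "SectionImage")) section@pixels else section
    h <- nrow(img); w <- ncol(img)
    stopIfNot(stepYPx < tileHeightPx && stepXPx < tileWidthPx,
              "steps must be smaller than the tile size so neighbors overlap")
    stopIfNot((tilesPerCol - 1) * stepYPx + tileHeightPx <= h &&
              (tilesPerRow - 1) * stepXPx + tileWidthPx <= w,
              "tile layout exceeds the section bounds")
    if (is(gain, "VignetteModel")) gain <- makeVignetteGain(gain)
    if (!is.null(gain))
        stopIfNot(all(dim(gain) == c(tileHeightPx, tileWidthPx)),
                  "gain shape must equal the tile shape")
    if (!is.null(warp))
        stopIfNot(all(dim(warp@dy) == c(tileHeightPx, tileWidthPx)),
                  "warp shape must equal the tile shape")
    tiles <- vector("list", tilesPerCol * tilesPerRow)
    pos <- data.frame(row = integer(), col = integer(), y0 = integer(), x0 = integer())
    k <- 0L
    for (r in seq_len(tilesPerCol) - 1L) {
        for (cc in seq_len(tilesPerRow) - 1L) {
            y0 <- r * stepYPx; x0 <- cc * stepXPx
            t <- img[(y0 + 1):(y0 + tileHeightPx), (x0 + 1):(x0 + tileWidthPx)]
            if (!is.null(gain)) t <- t * gain
            if (!is.null(warp)) t <- warpImage(t, warp)
            k <- k + 1L
            tiles[[k]] <- tile(t, sectionIndex = 0L, row = r, col = cc)
            pos <- rbind(pos, data.frame(row = r, col = cc, y0 = y0, x0 = x0))
        }
    }
    list(tiles = tiles, positions = pos)
}

#' Generate a synthetic mesh-grid calibration image
#'
#' Renders dark bars on bright holes (polarity configurable through the two
#' intensity levels) with 1-pixel antialiased edges, at bar centerlines on
#' every multiple of `pitchPx` (0-based pixel coordinates), and returns the
#' analytically known lattice of interior cell-corner coordinates. With a
#' warp, the image is resampled per the [warpImage()] convention and the true
#' corners are moved to their exact warped positions.
#'
#' @param pitchPx grid pitch in pixels.
#' @param barPx bar width in pixels (must be smaller than the pitch).
#' @param heightPx,widthPx image dimensions.
#' @param warp `NULL` or a [SyntheticWarp-class] (image-shaped).
#' @param noiseSd additive Gaussian noise SD.
#' @param holeLevel,barLevel intensities of holes and bars.
#' @param seed RNG seed for the noise.
#' @return List with `image`, `corners` (a truth [CornerLattice-class],
#'   0-based coordinates), `pitchPx` and `barPx`.
#' @export
generateGridImage <- function(pitchPx, barPx, heightPx, widthPx, warp = NULL,
                              noiseSd = 0, holeLevel = 45000, barLevel = 5000,
                              seed = 1L) {
    stopIfNot(barPx < pitchPx, "bar width must be smaller than the pitch")
    ky <- seq(pitchPx, heightPx, by = pitchPx)
    ky <- ky[ky < heightPx - 1]
    kx <- seq(pitchPx, widthPx, by = pitchPx)
    kx <- kx[kx < widthPx - 1]
    stopIfNot(length(ky) >= 1 && length(kx) >= 1, "image too small for the pitch")
    ys <- matrix(seq_len(heightPx) - 1, heightPx, widthPx)
    xs <- matrix(seq_len(widthPx) - 1, heightPx, widthPx, byrow = TRUE)
    if (!is.null(warp)) {
        stopIfNot(all(dim(warp@dy) == c(heightPx, widthPx)),
                  "warp shape must equal the image shape")
        ys <- ys - warp@dy
        xs <- xs - warp@dx
    }
    covAxis <- function(t) {
        dist <- abs(t - pitchPx * round(t / pitchPx))
        pmin(pmax(barPx / 2 + 0.5 - dist, 0), 1)
    }
    cy <- covAxis(ys); cx <- covAxis(xs)
    cov <- cy + cx - cy * cx
    img <- holeLevel + (barLevel - holeLevel) * cov
    if (noiseSd > 0)
        img <- img + matrix(withSeed(seed, rnorm(heightPx * widthPx, 0, noiseSd)),
                            heightPx, widthPx)
    cornY <- matrix(rep(ky, length(kx)), length(ky), length(kx))
    cornX <- matrix(rep(kx, each = length(ky)), length(ky), length(kx))
    if (!is.null(warp)) {
        wp <- warpPoints(warp, as.vector(cornY), as.vector(cornX))
        cornY <- matrix(wp$y, length(ky), length(kx))
        cornX <- matrix(wp$x, length(ky), length(kx))
    }
    list(image = img,
         corners = cornerLattice(cornY, cornX, "truth"),
         pitchPx = pitchPx, barPx = barPx)
}

#' Write a synthetic acquisition tree to disk
#'
#' Creates `<rootPath>/<brainId>/` with a brain-volume metadata text file and
#' one zero-padded subfolder per section, each holding a section metadata
#' file and per-channel 16-bit TIFF tiles sliced from per-section phantom
#' images. In `metadataOnly` mode only the metadata files are written, so
#' full-brain enumeration counts run in seconds.
#'
#' Defaults mirror a typical whole-brain acquisition: 832 x 832-pixel tiles
#' on an 11 x 14 grid, four channels, 732-pixel steps (nominal 100-pixel
#' overlap).
#'
#' @param rootPath writable directory to create the brain folder in.
#' @param brainId acquisition identifier.
#' @param nSections number of sections to write.
#' @param tilesPerCol,tilesPerRow tile grid shape.
#' @param tileHeightPx,tileWidthPx tile dimensions.
#' @param stepYPx,stepXPx tile steps.
#' @param channelNames channel labels.
#' @param metadataOnly write metadata without pixel payloads.
#' @param gain `NULL`, gain matrix or [VignetteModel-class] applied per tile.
#' @param warp `NULL` or tile-shaped [SyntheticWarp-class] applied per tile.
#' @param cellDensity,cellAmplitude,backgroundLevel,noiseSd phantom
#'   parameters (see [phantomSpec()]).
#' @param seed base RNG seed; each (section, channel) phantom derives its own.
#' @return Invisibly, a list with `brainDir` and the
#'   [BrainVolumeMetadata-class] written.
#' @export
writeFixtureTree <- function(rootPath, brainId, nSections,
                             tilesPerCol = 11L, tilesPerRow = 14L,
                             tileHeightPx = 832L, tileWidthPx = 832L,
                             stepYPx = 732L, stepXPx = 732L,
                             channelNames = c("red", "green", "blue", "farred"),
                             metadataOnly = FALSE, gain = NULL, warp = NULL,
                             cellDensity = 50, cellAmplitude = 20000,
                             backgroundLevel = 2000, noiseSd = 100, seed = 1L) {
    meta <- brainVolumeMetadata(brainId, nSections = nSections,
        tilesPerRow = tilesPerRow, tilesPerCol = tilesPerCol,
        tileHeightPx = tileHeightPx, tileWidthPx = tileWidthPx,
        channelNames = channelNames,
        nominalOverlapPx = min(tileHeightPx - stepYPx, tileWidthPx - stepXPx))
    brainDir <- file.path(rootPath, brainId)
    ok <- dir.create(brainDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(brainDir))
        stop("cannot create fixture directory: ", brainDir, call. = FALSE)
    writeBrainMetadata(meta, file.path(brainDir, "brain_volume_metadata.txt"))
    canvasH <- (tilesPerCol - 1) * stepYPx + tileHeightPx
    canvasW <- (tilesPerRow - 1) * stepXPx + tileWidthPx
    for (s in seq_len(nSections) - 1L) {
        secDir <- file.path(brainDir, sprintf("%04d", s))
        dir.create(secDir, showWarnings = FALSE)
        secMeta <- sectionMetadata(s, canvasH, canvasW, tilesPerRow, tilesPerCol,
                                   tileHeightPx, tileWidthPx,
                                   nChannels = length(channelNames), marginPx = 0L)
        writeSectionMetadata(secMeta, file.path(secDir, "section_metadata.txt"))
        if (metadataOnly) next
        for (ci in seq_along(channelNames)) {
            ph <- generatePhantomSection(phantomSpec(canvasH, canvasW,
                cellDensity = cellDensity, cellAmplitude = cellAmplitude,
                backgroundLevel = backgroundLevel, noiseSd = noiseSd,
                seed = seed + 1000L * s + ci))
            sl <- sliceIntoTiles(ph, tilesPerCol, tilesPerRow, stepYPx, stepXPx,
                                 tileHeightPx, tileWidthPx, gain = gain, warp = warp)
            for (t in sl$tiles)
                writeImageTiff(t@pixels,
                    file.path(secDir, tileFileName(brainId, s, t@row, t@col,
                                                   channelNames[ci])))
        }
    }
    invisible(list(brainDir = brainDir, meta = meta))
}
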