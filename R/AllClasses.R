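#' @import methods
NULL

## ---------------------------------------------------------------------------
## Acquisition metadata
## ---------------------------------------------------------------------------

#' Brain-volume acquisition metadata
#'
#' Describes one TissueCyte-style acquisition: the tile grid geometry, tile
#' pixel dimensions, imaging channels and physical spacings. One such object
#' accompanies every brain folder as a plain-text metadata file (see
#' [parseBrainMetadata()]).
#'
#' @slot brainId character identifier of the acquisition (e.g. `"B0039"`).
#' @slot nSections number of physical/optical sections in the brain.
#' @slot tilesPerRow number of tiles along a row (i.e. the column count).
#' @slot tilesPerCol number of tile rows.
#' @slot tileHeightPx,tileWidthPx tile dimensions in pixels.
#' @slot nChannels number of imaging channels.
#' @slot channelNames channel labels, length `nChannels`.
#' @slot nominalOverlapPx nominal overlap between adjacent tiles in pixels.
#' @slot inPlaneSpacingUm pixel-to-pixel spacing in micrometres.
#' @slot sectionSpacingUm section-to-section spacing in micrometres.
#' @slot scanOrder `"raster"` or `"serpentine"` stage scan pattern.
#' @export
setClass("BrainVolumeMetadata",
    slots = c(
        brainId = "character",
        nSections = "numeric",
        tilesPerRow = "numeric",
        tilesPerCol = "numeric",
        tileHeightPx = "numeric",
        tileWidthPx = "numeric",
        nChannels = "numeric",
        channelNames = "character",
        nominalOverlapPx = "numeric",
        inPlaneSpacingUm = "numeric",
        sectionSpacingUm = "numeric",
        scanOrder = "character"
    )
)

setValidity("BrainVolumeMetadata", function(object) {
    msgs <- character()
    for (s in c("nSections", "tilesPerRow", "tilesPerCol", "tileHeightPx",
                "tileWidthPx", "nChannels"))
        if (!isCount(slot(object, s)))
            msgs <- c(msgs, paste0(s, " must be a positive integer"))
    if (length(object@channelNames) != object@nChannels)
        msgs <- c(msgs, "n_channels must equal the number of channel_names")
    if (length(object@nominalOverlapPx) != 1 || object@nominalOverlapPx < 0 ||
        object@nominalOverlapPx >= min(object@tileHeightPx, object@tileWidthPx))
        msgs <- c(msgs, "nominal_overlap_px must be non-negative and smaller than the tile dimensions")
    if (object@inPlaneSpacingUm <= 0 || object@sectionSpacingUm <= 0)
        msgs <- c(msgs, "physical spacings must be positive")
    if (!object@scanOrder %in% c("raster", "serpentine"))
        msgs <- c(msgs, "scan_order must be 'raster' or 'serpentine'")
    if (length(msgs)) msgs else TRUE
})

#' Construct brain-volume metadata
#'
#' @param brainId acquisition identifier.
#' @param nSections number of sections.
#' @param tilesPerRow tiles along a row (columns).
#' @param tilesPerCol tile rows.
#' @param tileHeightPx,tileWidthPx tile dimensions in pixels.
#' @param channelNames character vector of channel labels.
#' @param nominalOverlapPx nominal tile overlap in pixels.
#' @param inPlaneSpacingUm,sectionSpacingUm physical spacings in micrometres.
#' @param scanOrder stage scan pattern.
#' @return A [BrainVolumeMetadata-class] object.
#' @examples
#' meta <- brainVolumeMetadata("B0039", nSections = 280)
#' tilesPerSection(meta)
#' @export
brainVolumeMetadata <- function(brainId, nSections,
                                tilesPerRow = 14L, tilesPerCol = 11L,
                                tileHeightPx = 832L, tileWidthPx = 832L,
                                channelNames = c("red", "green", "blue", "farred"),
                                nominalOverlapPx = 100L,
                                inPlaneSpacingUm = 1.25, sectionSpacingUm = 50,
                                scanOrder = "raster") {
    new("BrainVolumeMetadata", brainId = brainId, nSections = nSections,
        tilesPerRow = tilesPerRow, tilesPerCol = tilesPerCol,
        tileHeightPx = tileHeightPx, tileWidthPx = tileWidthPx,
        nChannels = length(channelNames), channelNames = channelNames,
        nominalOverlapPx = nominalOverlapPx,
        inPlaneSpacingUm = inPlaneSpacingUm, sectionSpacingUm = sectionSpacingUm,
        scanOrder = scanOrder)
}

#' Section metadata
#'
#' Per-section stitching geometry: canvas dimensions, tile grid and margin.
#' Canvas dimensions are validated against the placement arithmetic
#' `2 * margin + (n - 1) * step + tile` at stitch time.
#'
#' @slot sectionIndex zero-based section index.
#' @slot canvasHeightPx,canvasWidthPx stitched-canvas dimensions in pixels.
#' @slot tilesPerRow,tilesPerCol tile grid shape.
#' @slot tileHeightPx,tileWidthPx tile dimensions in pixels.
#' @slot nChannels number of channels.
#' @slot marginPx blank margin around the tile block, per side, in pixels.
#' @export
setClass("SectionMetadata",
    slots = c(
        sectionIndex = "numeric",
        canvasHeightPx = "numeric",
        canvasWidthPx = "numeric",
        tilesPerRow = "numeric",
        tilesPerCol = "numeric",
        tileHeightPx = "numeric",
        tileWidthPx = "numeric",
        nChannels = "numeric",
        marginPx = "numeric"
    )
)

setValidity("SectionMetadata", function(object) {
    msgs <- character()
    if (length(object@sectionIndex) != 1 || object@sectionIndex < 0 ||
        object@sectionIndex != round(object@sectionIndex))
        msgs <- c(msgs, "sectionIndex must be a non-negative integer")
    if (object@canvasHeightPx < object@tileHeightPx ||
        object@canvasWidthPx < object@tileWidthPx)
        msgs <- c(msgs, "canvas dimensions must be at least the tile dimensions")
    if (object@tilesPerRow < 1 || object@tilesPerCol < 1)
        msgs <- c(msgs, "tile counts must be positive")
    if (object@marginPx < 0)
        msgs <- c(msgs, "marginPx must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Construct section metadata
#' @param sectionIndex zero-based section index.
#' @param canvasHeightPx,canvasWidthPx canvas dimensions in pixels.
#' @param tilesPerRow,tilesPerCol tile grid shape.
#' @param tileHeightPx,tileWidthPx tile dimensions.
#' @param nChannels number of channels.
#' @param marginPx margin per side in pixels.
#' @return A [SectionMetadata-class] object.
#' @export
sectionMetadata <- function(sectionIndex, canvasHeightPx, canvasWidthPx,
                            tilesPerRow, tilesPerCol,
                            tileHeightPx = 832L, tileWidthPx = 832L,
                            nChannels = 4L, marginPx = 0L) {
    new("SectionMetadata", sectionIndex = sectionIndex,
        canvasHeightPx = canvasHeightPx, canvasWidthPx = canvasWidthPx,
        tilesPerRow = tilesPerRow, tilesPerCol = tilesPerCol,
        tileHeightPx = tileHeightPx, tileWidthPx = tileWidthPx,
        nChannels = nChannels, marginPx = marginPx)
}

## ---------------------------------------------------------------------------
## Images
## ---------------------------------------------------------------------------

#' A single tile image with its record
#'
#' Pixels are stored row-major conceptually (y down, x right) as an R matrix
#' indexed `[y, x]`. A tile flagged `missing` carries an all-zero placeholder
#' of the standard tile shape.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot sectionIndex,row,col zero-based grid position.
#' @slot channel channel label.
#' @slot missing logical; `TRUE` for a zero placeholder of an absent file.
#' @slot filePath source path ("" for in-memory tiles).
#' @export
setClass("Tile",
    slots = c(pixels = "matrix", sectionIndex = "numeric", row = "numeric",
              col = "numeric", channel = "character", missing = "logical",
              filePath = "character")
)

#' Construct a tile
#' @param pixels numeric matrix.
#' @param sectionIndex,row,col zero-based indices.
#' @param channel channel label.
#' @param missing placeholder flag.
#' @param filePath source path.
#' @return A [Tile-class] object.
#' @export
tile <- function(pixels, sectionIndex = 0L, row = 0L, col = 0L,
                 channel = "", missing = FALSE, filePath = "") {
    new("Tile", pixels = pixels, sectionIndex = sectionIndex, row = row,
        col = col, channel = channel, missing = missing, filePath = filePath)
}

#' Per-channel flat-field profile
#'
#' The per-pixel arithmetic mean over many tiles of one channel, used as a
#' per-pixel divisor to remove lens vignetting.
#'
#' @slot channel channel label.
#' @slot pixels tile-shaped numeric matrix of mean intensities.
#' @slot nTilesAveraged number of tiles contributing to the mean.
#' @slot epsilon division floor protecting against dead pixels.
#' @export
setClass("Profile",
    slots = c(channel = "character", pixels = "matrix",
              nTilesAveraged = "numeric", epsilon = "numeric")
)

setValidity("Profile", function(object) {
    msgs <- character()
    if (any(object@pixels < 0)) msgs <- c(msgs, "profile pixels must be >= 0")
    if (object@nTilesAveraged < 1) msgs <- c(msgs, "nTilesAveraged must be >= 1")
    if (object@epsilon <= 0) msgs <- c(msgs, "epsilon must be positive")
    if (length(msgs)) msgs else TRUE
})

#' A stitched 2D section image
#'
#' @slot pixels canvas-shaped numeric matrix.
#' @slot sectionIndex zero-based section index.
#' @slot channel channel label.
#' @slot provenance list of generation parameters (translation params,
#'   model identifiers, generator diagnostics).
#' @export
setClass("SectionImage",
    slots = c(pixels = "matrix", sectionIndex = "numeric",
              channel = "character", provenance = "list")
)

setValidity("SectionImage", function(object) {
    if (!all(is.finite(object@pixels))) "pixels must be finite" else TRUE
})

#' Construct a section image
#' @param pixels numeric matrix.
#' @param sectionIndex zero-based section index.
#' @param channel channel label.
#' @param provenance list of generation parameters.
#' @return A [SectionImage-class] object.
#' @export
sectionImage <- function(pixels, sectionIndex = 0L, channel = "",
                         provenance = list()) {
    new("SectionImage", pixels = pixels, sectionIndex = sectionIndex,
        channel = channel, provenance = provenance)
}

#' A 3D brain volume
#'
#' Voxels are ordered `(z = section, y, x)` with physical spacing in
#' micrometres per axis. The default spacing (50, 1.25, 1.25) um matches a
#' 50-um sectioning interval and a 1.25-um in-plane pixel size.
#'
#' @slot voxels 3D numeric array ordered (z, y, x).
#' @slot spacingUm numeric length-3, (z, y, x) spacing in micrometres.
#' @slot channel channel label.
#' @slot brainId acquisition identifier.
#' @export
setClass("Volume",
    slots = c(voxels = "array", spacingUm = "numeric",
              channel = "character", brainId = "character")
)

setValidity("Volume", function(object) {
    msgs <- character()
    if (length(dim(object@voxels)) != 3L) msgs <- c(msgs, "voxels must be a 3D array")
    if (length(object@spacingUm) != 3L || any(object@spacingUm <= 0))
        msgs <- c(msgs, "spacingUm must be 3 positive values (z, y, x)")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Calibration
## ---------------------------------------------------------------------------

#' A row/column-ordered lattice of grid-target corner points
#'
#' @slot y,x numeric matrices (`nRows x nCols`) of pixel coordinates
#'   (0-based, y down).
#' @slot source one of `"detected"`, `"template"`, `"truth"`. Template
#'   lattices are exactly equally spaced in both directions.
#' @export
setClass("CornerLattice",
    slots = c(y = "matrix", x = "matrix", source = "character")
)

setValidity("CornerLattice", function(object) {
    msgs <- character()
    if (!identical(dim(object@y), dim(object@x)))
        msgs <- c(msgs, "y and x must have identical dimensions")
    if (!all(is.finite(object@y)) || !all(is.finite(object@x)))
        msgs <- c(msgs, "lattice coordinates must be finite")
    if (!object@source %in% c("detected", "template", "truth"))
        msgs <- c(msgs, "source must be 'detected', 'template' or 'truth'")
    if (object@source == "template" && nrow(object@y) > 1 && ncol(object@y) > 1) {
        dy <- diff(object@y[, 1]); dx <- diff(object@x[1, ])
        if (length(dy) && max(abs(dy - dy[1])) > 1e-9)
            msgs <- c(msgs, "template lattice rows must be equally spaced")
        if (length(dx) && max(abs(dx - dx[1])) > 1e-9)
            msgs <- c(msgs, "template lattice columns must be equally spaced")
    }
    if (length(msgs)) msgs else TRUE
})

cornerLattice <- function(y, x, source) new("CornerLattice", y = y, x = x, source = source)

#' A planar projective transformation
#'
#' 3x3 matrix acting on homogeneous (y, x, 1) column vectors, normalized so
#' the bottom-right entry equals 1.
#'
#' @slot mat 3x3 numeric matrix.
#' @export
setClass("Homography", slots = c(mat = "matrix"))

setValidity("Homography", function(object) {
    msgs <- character()
    if (!identical(dim(object@mat), c(3L, 3L))) msgs <- c(msgs, "mat must be 3x3")
    else {
        if (abs(object@mat[3, 3] - 1) > 1e-9)
            msgs <- c(msgs, "mat must be normalized with bottom-right entry 1")
        if (abs(det(object@mat)) <= 1e-12)
            msgs <- c(msgs, "mat must be invertible")
    }
    if (length(msgs)) msgs else TRUE
})

#' Lens-distortion correction model
#'
#' A global homography plus a residual per-node displacement field, compiled
#' into a dense per-pixel source-coordinate lookup for the standard tile
#' shape. One model, calibrated once from a mesh-grid target image, is reused
#' for all tiles of all sections acquired on the same instrument.
#'
#' @slot homography the global [Homography-class] (detected -> template).
#' @slot nodeDy,nodeDx residual control displacements at template lattice
#'   nodes (template minus homography-projected detected corners).
#' @slot templateOriginY,templateOriginX,templatePitch geometry of the
#'   template lattice anchoring the residual field (0-based pixels).
#' @slot lutY,lutX dense per-pixel source coordinates (1-based R indexing)
#'   for the standard tile shape.
#' @slot tileShape integer (height, width) of the tiles the LUT covers.
#' @slot meta calibration metadata list (grid pitch, date, id).
#' @export
setClass("DeformationModel",
    slots = c(homography = "Homography", nodeDy = "matrix", nodeDx = "matrix",
              templateOriginY = "numeric", templateOriginX = "numeric",
              templatePitch = "numeric", lutY = "matrix", lutX = "matrix",
              tileShape = "numeric", meta = "list")
)

setValidity("DeformationModel", function(object) {
    msgs <- character()
    if (!identical(dim(object@lutY), dim(object@lutX)))
        msgs <- c(msgs, "lutY and lutX must have identical dimensions")
    if (!all(dim(object@lutY) == object@tileShape))
        msgs <- c(msgs, "LUT shape must equal tileShape")
    if (!all(is.finite(object@lutY)) || !all(is.finite(object@lutX)))
        msgs <- c(msgs, "LUT coordinates must be finite")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Translation estimation
## ---------------------------------------------------------------------------

#' Overlap-strip configuration for shift estimation
#'
#' From the leading tile a wide strip is taken at the shared edge, from the
#' trailing tile a narrower strip; the narrow strip is slid over the wide one
#' under normalized cross-correlation. Defaults follow the 100/50-pixel strip
#' scheme used for ~10% tile overlap.
#'
#' @slot wideStripPx strip width taken from the leading tile.
#' @slot narrowStripPx strip width taken from the trailing tile.
#' @slot maxPerpendicularShiftPx search half-range perpendicular to the
#'   stitching axis.
#' @slot confidenceFloor minimum peak NCC for a pair to count.
#' @export
setClass("StripConfig",
    slots = c(wideStripPx = "numeric", narrowStripPx = "numeric",
              maxPerpendicularShiftPx = "numeric", confidenceFloor = "numeric")
)

setValidity("StripConfig", function(object) {
    if (object@narrowStripPx >= object@wideStripPx)
        return("narrowStripPx must be smaller than wideStripPx")
    if (object@narrowStripPx < 1) return("strip widths must be positive")
    if (object@maxPerpendicularShiftPx < 0)
        return("maxPerpendicularShiftPx must be non-negative")
    TRUE
})

#' Construct a strip configuration
#' @param wideStripPx wide (leading-edge) strip width in pixels.
#' @param narrowStripPx narrow (trailing-edge) strip width in pixels.
#' @param maxPerpendicularShiftPx perpendicular search half-range.
#' @param confidenceFloor minimum acceptable peak NCC.
#' @return A [StripConfig-class] object.
#' @export
stripConfig <- function(wideStripPx = 100L, narrowStripPx = 50L,
                        maxPerpendicularShiftPx = 10L, confidenceFloor = 0.3) {
    new("StripConfig", wideStripPx = wideStripPx, narrowStripPx = narrowStripPx,
        maxPerpendicularShiftPx = maxPerpendicularShiftPx,
        confidenceFloor = confidenceFloor)
}

#' Global inter-tile translation parameters
#'
#' The integer pixel offsets between adjacent tiles used for canvas
#' placement, aggregated (median) over many tile pairs. These displacements
#' are consistent across sections and scans, so one estimate serves a whole
#' acquisition series.
#'
#' @slot stepXPx horizontal neighbor offset (left tile to right tile).
#' @slot stepYPx vertical neighbor offset (top tile to bottom tile).
#' @slot dyAtHorizontalPx perpendicular drift for left-to-right pairs.
#' @slot dxAtVerticalPx perpendicular drift for top-to-bottom pairs.
#' @slot nPairsUsed number of confident pairs aggregated.
#' @slot meanNcc mean peak NCC over the confident pairs.
#' @export
setClass("TranslationParams",
    slots = c(stepXPx = "numeric", stepYPx = "numeric",
              dyAtHorizontalPx = "numeric", dxAtVerticalPx = "numeric",
              nPairsUsed = "numeric", meanNcc = "numeric")
)

setValidity("TranslationParams", function(object) {
    msgs <- character()
    if (object@stepXPx < 1 || object@stepYPx < 1)
        msgs <- c(msgs, "steps must be positive")
    if (object@nPairsUsed < 1) msgs <- c(msgs, "nPairsUsed must be positive")
    if (abs(object@meanNcc) > 1 + 1e-9) msgs <- c(msgs, "meanNcc must lie in [-1, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Construct translation parameters
#' @param stepXPx,stepYPx neighbor offsets in pixels.
#' @param dyAtHorizontalPx,dxAtVerticalPx perpendicular drifts in pixels.
#' @param nPairsUsed pairs aggregated.
#' @param meanNcc mean peak correlation.
#' @return A [TranslationParams-class] object.
#' @export
translationParams <- function(stepXPx, stepYPx, dyAtHorizontalPx = 0L,
                              dxAtVerticalPx = 0L, nPairsUsed = 1L,
                              meanNcc = 1) {
    new("TranslationParams", stepXPx = stepXPx, stepYPx = stepYPx,
        dyAtHorizontalPx = dyAtHorizontalPx, dxAtVerticalPx = dxAtVerticalPx,
        nPairsUsed = nPairsUsed, meanNcc = meanNcc)
}

## ---------------------------------------------------------------------------
## Fixture specifications
## ---------------------------------------------------------------------------

#' Specification of a synthetic phantom section
#'
#' Phantoms emulate fluorescently labeled somata: Gaussian-profile bright
#' disks scattered over a uniform tissue background with additive Gaussian
#' noise, in a 16-bit intensity regime.
#'
#' @slot heightPx,widthPx image dimensions.
#' @slot cellDensity expected cells per megapixel.
#' @slot cellRadiusPx disk radius in pixels.
#' @slot cellAmplitude peak intensity added by a cell.
#' @slot backgroundLevel background intensity.
#' @slot noiseSd Gaussian noise standard deviation.
#' @slot seed RNG seed; identical seeds give identical phantoms.
#' @export
setClass("PhantomSpec",
    slots = c(heightPx = "numeric", widthPx = "numeric", cellDensity = "numeric",
              cellRadiusPx = "numeric", cellAmplitude = "numeric",
              backgroundLevel = "numeric", noiseSd = "numeric", seed = "numeric")
)

setValidity("PhantomSpec", function(object) {
    msgs <- character()
    if (!isCount(object@heightPx) || !isCount(object@widthPx))
        msgs <- c(msgs, "dimensions must be positive integers")
    if (object@cellDensity < 0) msgs <- c(msgs, "cellDensity must be >= 0")
    if (object@cellRadiusPx <= 0) msgs <- c(msgs, "cellRadiusPx must be positive")
    if (object@backgroundLevel < 0 || object@backgroundLevel > 65535)
        msgs <- c(msgs, "backgroundLevel must lie in [0, 65535]")
    if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a phantom specification
#' @param heightPx,widthPx image dimensions in pixels.
#' @param cellDensity expected cells per megapixel.
#' @param cellRadiusPx cell disk radius in pixels.
#' @param cellAmplitude peak added intensity of a cell.
#' @param backgroundLevel background intensity.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(heightPx, widthPx, cellDensity = 50,
                        cellRadiusPx = 4, cellAmplitude = 20000,
                        backgroundLevel = 2000, noiseSd = 100, seed = 1L) {
    new("PhantomSpec", heightPx = heightPx, widthPx = widthPx,
        cellDensity = cellDensity, cellRadiusPx = cellRadiusPx,
        cellAmplitude = cellAmplitude, backgroundLevel = backgroundLevel,
        noiseSd = noiseSd, seed = seed)
}

#' Radial vignetting gain model
#'
#' Lens vignetting makes tile centers brighter than edges; the gain image is
#' maximal (`centerGain`) at the tile center, falls radially and equals
#' `edgeGain` at the farthest corner.
#'
#' @slot tileHeightPx,tileWidthPx tile dimensions.
#' @slot centerGain gain at the tile center, in (0, 1].
#' @slot edgeGain gain at the farthest corner, in (0, centerGain].
#' @slot profileShape `"radial_quadratic"` or `"radial_gaussian"`.
#' @export
setClass("VignetteModel",
    slots = c(tileHeightPx = "numeric", tileWidthPx = "numeric",
              centerGain = "numeric", edgeGain = "numeric",
              profileShape = "character")
)

setValidity("VignetteModel", function(object) {
    msgs <- character()
    if (object@centerGain <= 0 || object@centerGain > 1)
        msgs <- c(msgs, "centerGain must lie in (0, 1]")
    if (object@edgeGain <= 0 || object@edgeGain > object@centerGain)
        msgs <- c(msgs, "edgeGain must lie in (0, centerGain]")
    if (!object@profileShape %in% c("radial_quadratic", "radial_gaussian"))
        msgs <- c(msgs, "profileShape must be 'radial_quadratic' or 'radial_gaussian'")
    if (length(msgs)) msgs else TRUE
})

#' Construct a vignetting model
#' @param tileHeightPx,tileWidthPx tile dimensions.
#' @param centerGain gain at the center.
#' @param edgeGain gain at the farthest corner.
#' @param profileShape radial falloff shape.
#' @return A [VignetteModel-class] object.
#' @export
vignetteModel <- function(tileHeightPx = 832L, tileWidthPx = 832L,
                          centerGain = 1, edgeGain = 0.6,
                          profileShape = "radial_quadratic") {
    new("VignetteModel", tileHeightPx = tileHeightPx, tileWidthPx = tileWidthPx,
        centerGain = centerGain, edgeGain = edgeGain, profileShape = profileShape)
}

#' A smooth synthetic warp field
#'
#' A random, smooth per-pixel displacement field emulating lens distortion:
#' coarse Gaussian control values at `smoothnessScalePx` spacing are
#' bicubically upsampled and rescaled so the maximum displacement magnitude
#' equals `amplitudePx`.
#'
#' @slot dy,dx dense per-pixel displacement maps (pixels).
#' @slot amplitudePx maximum displacement magnitude.
#' @slot smoothnessScalePx control-point spacing in pixels.
#' @slot seed RNG seed used for the control values.
#' @export
setClass("SyntheticWarp",
    slots = c(dy = "matrix", dx = "matrix", amplitudePx = "numeric",
              smoothnessScalePx = "numeric", seed = "numeric")
)

setValidity("SyntheticWarp", function(object) {
    msgs <- character()
    if (!identical(dim(object@dy), dim(object@dx)))
        msgs <- c(msgs, "dy and dx must have identical dimensions")
    if (object@amplitudePx < 0) msgs <- c(msgs, "amplitudePx must be >= 0")
    if (object@smoothnessScalePx <= 0)
        msgs <- c(msgs, "smoothnessScalePx must be positive")
    mag <- sqrt(object@dy^2 + object@dx^2)
    if (length(mag) && max(mag) > object@amplitudePx + 1e-6)
        msgs <- c(msgs, "displacement magnitude exceeds amplitudePx")
    if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "BrainVolumeMetadata", function(object) {
    cat("BrainVolumeMetadata '", object@brainId, "'\n", sep = "")
    cat("  sections: ", object@nSections,
        " | grid: ", object@tilesPerCol, " x ", object@tilesPerRow,
        " | tile: ", object@tileHeightPx, " x ", object@tileWidthPx, " px\n", sep = "")
    cat("  channels: ", paste(object@channelNames, collapse = ", "), "\n", sep = "")
    cat("  nominal overlap: ", object@nominalOverlapPx, " px | spacing: ",
        object@inPlaneSpacingUm, " um in-plane, ",
        object@sectionSpacingUm, " um between sections\n", sep = "")
})

setMethod("show", "SectionMetadata", function(object) {
    cat("SectionMetadata #", object@sectionIndex, ": canvas ",
        object@canvasHeightPx, " x ", object@canvasWidthPx, " px, grid ",
        object@tilesPerCol, " x ", object@tilesPerRow, ", margin ",
        object@marginPx, " px\n", sep = "")
})

setMethod("show", "Tile", function(object) {
    cat("Tile S", object@sectionIndex, " R", object@row, " C", object@col,
        " [", object@channel, "] ", nrow(object@pixels), "x", ncol(object@pixels),
        if (object@missing) " (missing placeholder)" else "", "\n", sep = "")
})

setMethod("show", "Profile", function(object) {
    cat("Profile [", object@channel, "]: ", nrow(object@pixels), "x",
        ncol(object@pixels), " px, mean ", signif(mean(object@pixels), 6),
        ", averaged over ", object@nTilesAveraged, " tiles\n", sep = "")
})

setMethod("show", "SectionImage", function(object) {
    cat("SectionImage #", object@sectionIndex, " [", object@channel, "]: ",
        nrow(object@pixels), " x ", ncol(object@pixels), " px\n", sep = "")
})

setMethod("show", "Volume", function(object) {
    d <- dim(object@voxels)
    cat("Volume '", object@brainId, "' [", object@channel, "]: ",
        d[1], " x ", d[2], " x ", d[3], " (z, y, x), spacing ",
        paste(object@spacingUm, collapse = " x "), " um\n", sep = "")
})

setMethod("show", "CornerLattice", function(object) {
    cat("CornerLattice (", object@source, "): ", nrow(object@y), " x ",
        ncol(object@y), " nodes\n", sep = "")
})

setMethod("show", "Homography", function(object) {
    cat("Homography:\n"); print(object@mat)
})

setMethod("show", "DeformationModel", function(object) {
    cat("DeformationModel: tile ", object@tileShape[1], " x ",
        object@tileShape[2], ", residual grid ", nrow(object@nodeDy), " x ",
        ncol(object@nodeDy), ", pitch ",
        paste(signif(object@templatePitch, 6), collapse = " x "),
        " px\n", sep = "")
})

setMethod("show", "TranslationParams", function(object) {
    cat("TranslationParams: step_x ", object@stepXPx, ", step_y ",
        object@stepYPx, ", drifts (dy_h ", object@dyAtHorizontalPx,
        ", dx_v ", object@dxAtVerticalPx, "), ", object@nPairsUsed,
        " pairs, mean NCC ", signif(object@meanNcc, 4), "\n", sep = "")
})

setMethod("show", "SyntheticWarp", function(object) {
    cat("SyntheticWarp: ", nrow(object@dy), " x ", ncol(object@dy),
        ", amplitude ", object@amplitudePx, " px, smoothness ",
        object@smoothnessScalePx, " px\n", sep = "")
})
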