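## Canvas placement and seamless blending of corrected tiles into a section
## image. Overlaps are resolved purely by placement plus blending — tiles
## are never trimmed.

#' Compute canvas placements for all tiles of a section
#'
#' Placement arithmetic (0-based canvas pixels):
#' `y0 = margin + row * step_y + col * dy_at_horizontal` and
#' `x0 = margin + col * step_x + row * dx_at_vertical`. The canvas dimension
#' implied by the grid, `2 * margin + (n - 1) * step + tile`, is checked
#' against the section metadata; a disagreement warns (metadata wins), while
#' a placement falling outside the canvas is an error showing the
#' arithmetic.
#'
#' @param secMeta a [SectionMetadata-class].
#' @param params a [TranslationParams-class].
#' @return data.frame with zero-based columns `row`, `col`, `y0`, `x0`.
#' @export
computeTilePositions <- function(secMeta, params) {
    m <- secMeta@marginPx
    rows <- seq_len(secMeta@tilesPerCol) - 1L
    cols <- seq_len(secMeta@tilesPerRow) - 1L
    g <- expand.grid(col = cols, row = rows)[, c("row", "col")]
    y0 <- m + g$row * params@stepYPx + g$col * params@dyAtHorizontalPx
    x0 <- m + g$col * params@stepXPx + g$row * params@dxAtVerticalPx
    th <- secMeta@tileHeightPx; tw <- secMeta@tileWidthPx
    expH <- 2 * m + (secMeta@tilesPerCol - 1) * params@stepYPx + th
    expW <- 2 * m + (secMeta@tilesPerRow - 1) * params@stepXPx + tw
    if (expH != secMeta@canvasHeightPx || expW != secMeta@canvasWidthPx)
        warning(sprintf(paste0(
            "canvas %d x %d from metadata differs from placement arithmetic ",
            "2*%d + (n-1)*step + tile = %d x %d; metadata canvas is used"),
            secMeta@canvasHeightPx, secMeta@canvasWidthPx, m, expH, expW),
            call. = FALSE)
    bad <- which(y0 < 0 | x0 < 0 | y0 + th > secMeta@canvasHeightPx |
                 x0 + tw > secMeta@canvasWidthPx)
    if (length(bad)) {
        b <- bad[1]
        stop(sprintf(paste0(
            "tile (row %d, col %d) placed at (%d, %d) + %d x %d exceeds the ",
            "%d x %d canvas"), g$row[b], g$col[b], y0[b], x0[b], th, tw,
            secMeta@canvasHeightPx, secMeta@canvasWidthPx), call. = FALSE)
    }
    data.frame(row = g$row, col = g$col, y0 = as.integer(y0), x0 = as.integer(x0))
}

featherWeights <- function(h, w, depth) {
    dy <- pmin(seq_len(h) - 1, h - seq_len(h))
    dx <- pmin(seq_len(w) - 1, w - seq_len(w))
    d <- pmin(matrix(dy, h, w), matrix(dx, h, w, byrow = TRUE))
    pmin(d + 1, depth) / depth
}

#' Stitch tiles into a section image
#'
#' Places each tile at its canvas position and blends overlaps: every output
#' pixel is `sum(w_i * tile_i) / sum(w_i)` over the tiles covering it. With
#' `blend = "feather"` the weight ramps linearly from the tile edge to 1 at
#' the overlap depth (linear blending), which removes seam steps; `"mean"`
#' weights all covering tiles equally. Either way the blend is convex, so a
#' pixel covered by one tile keeps that tile's value exactly and blended
#' values never leave the range of the contributing tiles. Uncovered canvas
#' pixels are 0. All-zero placeholder tiles participate with their zeros
#' (documented behavior: a missing tile leaves a dark region, not a hole).
#'
#' @param tiles list of [Tile-class] objects or matrices, one per placement,
#'   in the same order as `placements` rows.
#' @param placements data.frame from [computeTilePositions()] (or the
#'   ground-truth positions of a fixture).
#' @param canvasShape integer `(height, width)`.
#' @param blend `"feather"` or `"mean"`.
#' @param featherDepthPx feather ramp depth in pixels; default is the
#'   smallest positive overlap implied by the placements (falling back to 1).
#' @param sectionIndex,channel stored on the result.
#' @return A [SectionImage-class] with real-valued pixels.
#' @export
stitchSection <- function(tiles, placements, canvasShape,
                          blend = c("feather", "mean"), featherDepthPx = NULL,
                          sectionIndex = 0L, channel = "") {
    blend <- match.arg(blend)
    stopIfNot(length(tiles) == nrow(placements),
              "one tile per placement is required")
    mats <- lapply(tiles, function(t) if (is(t, "Tile")) t@pixels else t)
    th <- nrow(mats[[1]]); tw <- ncol(mats[[1]])
    for (m in mats)
        stopIfNot(nrow(m) == th && ncol(m) == tw, "all tiles must share one shape")
    if (is.null(featherDepthPx)) {
        ovY <- th - diff(sort(unique(placements$y0)))
        ovX <- tw - diff(sort(unique(placements$x0)))
        ov <- c(ovY[ovY > 0], ovX[ovX > 0])
        featherDepthPx <- if (length(ov)) max(1L, min(ov)) else 1L
    }
    w <- if (blend == "feather") featherWeights(th, tw, featherDepthPx)
         else matrix(1, th, tw)
    num <- matrix(0, canvasShape[1], canvasShape[2])
    den <- matrix(0, canvasShape[1], canvasShape[2])
    for (k in seq_along(mats)) {
        ys <- (placements$y0[k] + 1):(placements$y0[k] + th)
        xs <- (placements$x0[k] + 1):(placements$x0[k] + tw)
        stopIfNot(ys[length(ys)] <= canvasShape[1] && xs[length(xs)] <= canvasShape[2] &&
                  ys[1] >= 1 && xs[1] >= 1, "placement outside the canvas")
        num[ys, xs] <- num[ys, xs] + w * mats[[k]]
        den[ys, xs] <- den[ys, xs] + w
    }
    out <- num
    covered <- den > 0
    out[covered] <- num[covered] / den[covered]
    out[!covered] <- 0
    sectionImage(out, sectionIndex = sectionIndex, channel = channel,
                 provenance = list(blend = blend, featherDepthPx = featherDepthPx,
                                   nTiles = length(mats)))
}

#' Write a stitched section to TIFF
#'
#' Multiplies by `rescale` (conventionally the flat-field profile's global
#' mean, returning normalized intensities to the storage regime), clips to
#' the integer dtype range — the clip count is recorded — rounds, and writes
#' a 16-bit grayscale TIFF. Read-back equals the written values.
#'
#' @param image a [SectionImage-class] or numeric matrix.
#' @param path output TIFF path.
#' @param rescale multiplicative factor applied before conversion.
#' @param bits bits per sample (16 default).
#' @return Invisibly, a list with `path` and `clippedPixels`.
#' @export
writeSection <- function(image, path, rescale = 1, bits = 16L) {
    px <- if (is(image, "SectionImage")) image@pixels else image
    v <- round(px * rescale)
    maxv <- 2^bits - 1
    clipped <- sum(v < 0 | v > maxv)
    writeImageTiff(v, path, bits = bits)
    invisible(list(path = path, clippedPixels = clipped))
}

#' Read a stitched section TIFF back as a matrix
#'
#' @param path TIFF path.
#' @return Numeric matrix of stored integer values.
#' @export
readSection <- function(path) readImageTiff(path)

#' Canonical stitched-section file name
#'
#' @param brainId acquisition identifier.
#' @param section zero-based section index.
#' @param channel channel label.
#' @return File name like `B0039_S0000_red_stitched.tif`.
#' @export
sectionFileName <- function(brainId, section, channel) {
    sprintf("%s_S%04d_%s_stitched.tif", brainId, section, channel)
}
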