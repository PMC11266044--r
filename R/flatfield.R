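## Flat-field (vignetting) correction: per-channel average-tile profiles and
## per-pixel division.

#' Compute a per-channel flat-field profile
#'
#' The profile is the per-pixel arithmetic mean over the supplied tiles of
#' one channel. Missing-tile placeholders (and any all-zero tile) are
#' excluded from the mean, since they carry no illumination information.
#' Averaging many tiles cancels the tissue signal and leaves the smooth
#' vignetting field, which is brighter at the tile center than at the edges.
#'
#' The division floor is `epsilon = max(1e-6, 1e-3 * mean(profile))`: it
#' prevents blow-up at dead pixels without visibly biasing bright areas.
#'
#' @param tiles list of [Tile-class] objects (or numeric matrices) of one
#'   channel, all the same shape.
#' @param channel channel label recorded in the profile; defaults to the
#'   first tile's channel.
#' @return A [Profile-class].
#' @export
computeProfile <- function(tiles, channel = NULL) {
    mats <- lapply(tiles, function(t) if (is(t, "Tile")) t@pixels else t)
    keep <- vapply(tiles, function(t) {
        px <- if (is(t, "Tile")) t@pixels else t
        !(is(t, "Tile") && t@missing) && any(px != 0)
    }, logical(1))
    mats <- mats[keep]
    if (length(mats) == 0) stop("no tiles to average", call. = FALSE)
    shp <- dim(mats[[1]])
    for (m in mats)
        stopIfNot(identical(dim(m), shp), "all tiles must have the same shape")
    acc <- Reduce(`+`, mats)
    px <- acc / length(mats)
    if (is.null(channel)) {
        channel <- ""
        if (is(tiles[[which(keep)[1]]], "Tile")) channel <- tiles[[which(keep)[1]]]@channel
    }
    new("Profile", channel = channel, pixels = px,
        nTilesAveraged = length(mats),
        epsilon = max(1e-6, 1e-3 * mean(px)))
}

#' Normalize a tile by its flat-field profile
#'
#' Each pixel is divided by the corresponding profile pixel (floored at the
#' profile's epsilon). A tile equal to its profile maps to all ones; typical
#' tissue lands on a scale around 0-1, while brightly labeled cells stay
#' above 1 — values are deliberately not clamped, so labeled cells remain
#' brighter than the surrounding tissue. An all-zero placeholder tile maps
#' to all zeros (never NaN/Inf). The result is converted back to the storage
#' intensity regime only at section-writing time via a rescale factor
#' (conventionally the profile's global mean; see [writeSection()]).
#'
#' @param tile a [Tile-class] (or numeric matrix).
#' @param profile a [Profile-class] of matching shape and channel.
#' @return A [Tile-class] with real-valued pixels.
#' @export
normalizeTile <- function(tile, profile) {
    px <- if (is(tile, "Tile")) tile@pixels else tile
    stopIfNot(identical(dim(px), dim(profile@pixels)),
              "tile and profile shapes must match")
    if (is(tile, "Tile") && nzchar(tile@channel) && nzchar(profile@channel) &&
        tile@channel != profile@channel)
        stop(sprintf("channel mismatch: tile '%s' vs profile '%s'",
                     tile@channel, profile@channel), call. = FALSE)
    out <- px / pmax(profile@pixels, profile@epsilon)
    if (is(tile, "Tile"))
        new("Tile", pixels = out, sectionIndex = tile@sectionIndex,
            row = tile@row, col = tile@col, channel = tile@channel,
            missing = tile@missing, filePath = tile@filePath)
    else out
}

#' Save and load a flat-field profile
#'
#' Profiles are stored as a 32-bit float TIFF (pixels divided by a recorded
#' scale so they fit the float-TIFF unit range) plus a JSON sidecar
#' (`<path>.json`) carrying the channel, tile count, epsilon and scale.
#'
#' @param profile a [Profile-class].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return The path (save) or the restored [Profile-class] (load).
#' @export
saveProfile <- function(profile, path) {
    scale <- max(profile@pixels, 1e-12) * (1 + 1e-7)
    tiff::writeTIFF(profile@pixels / scale, path, bits.per.sample = 32L)
    jsonWrite(list(channel = profile@channel,
                   n_tiles_averaged = profile@nTilesAveraged,
                   epsilon = profile@epsilon, scale = scale),
              paste0(path, ".json"))
    invisible(path)
}

#' @rdname saveProfile
#' @export
loadProfile <- function(path) {
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    px <- tiff::readTIFF(path) * side$scale
    new("Profile", channel = side$channel, pixels = px,
        nTilesAveraged = side$n_tiles_averaged, epsilon = side$epsilon)
}
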