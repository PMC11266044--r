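## Metadata dialect: UTF-8 text, one "key: value" per line, '#' comments.
## File naming: <brain_id>_S<section:04d>_R<row:02d>_C<col:02d>_<channel>.tif
## Tile order on disk is raster (row-major); coordinates are 0-based, y down.

parseKeyValueText <- function(text) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
    lines <- sub("#.*$", "", lines)
    out <- list()
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        m <- regexpr(":", ln, fixed = TRUE)
        if (m < 0)
            stop(sprintf("metadata parse error on line %d: expected 'key: value', got '%s'",
                         i, ln), call. = FALSE)
        key <- trimws(substr(ln, 1, m - 1))
        val <- trimws(substr(ln, m + 1, nchar(ln)))
        out[[key]] <- val
        attr(out, "lines") <- c(attr(out, "lines"), stats::setNames(i, key))
    }
    out
}

requireKeys <- function(kv, keys) {
    absent <- setdiff(keys, names(kv))
    if (length(absent))
        stop("metadata is missing required key(s): ", paste(absent, collapse = ", "),
             call. = FALSE)
}

numericKey <- function(kv, key, default = NULL) {
    if (is.null(kv[[key]])) {
        if (!is.null(default)) return(default)
        stop("metadata is missing required key: ", key, call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) {
        ln <- attr(kv, "lines")[key]
        stop(sprintf("metadata parse error on line %d: '%s' is not a number (key '%s')",
                     ln, kv[[key]], key), call. = FALSE)
    }
    v
}

#' Parse and serialize brain-volume metadata
#'
#' The on-disk dialect is plain UTF-8 text with one `key: value` pair per
#' line and `#` comments. Required keys: `brain_id`, `n_sections`,
#' `tiles_per_row`, `tiles_per_col`, `tile_height_px`, `tile_width_px`,
#' `n_channels`, `channel_names` (comma-separated). Optional keys with
#' defaults: `nominal_overlap_px` (100), `in_plane_spacing_um` (1.25),
#' `section_spacing_um` (50), `scan_order` (`raster`).
#'
#' @param text character scalar or vector of metadata text.
#' @return [parseBrainMetadata()] a [BrainVolumeMetadata-class];
#'   [formatBrainMetadata()] a character scalar; the write/read pair operate
#'   on files and round-trip all fields exactly.
#' @examples
#' meta <- brainVolumeMetadata("B0039", nSections = 280)
#' identical(parseBrainMetadata(formatBrainMetadata(meta)), meta)
#' @export
parseBrainMetadata <- function(text) {
    kv <- parseKeyValueText(paste(text, collapse = "\n"))
    requireKeys(kv, c("brain_id", "n_sections", "tiles_per_row", "tiles_per_col",
                      "tile_height_px", "tile_width_px", "n_channels",
                      "channel_names"))
    channels <- trimws(strsplit(kv[["channel_names"]], ",", fixed = TRUE)[[1]])
    meta <- brainVolumeMetadata(
        brainId = kv[["brain_id"]],
        nSections = numericKey(kv, "n_sections"),
        tilesPerRow = numericKey(kv, "tiles_per_row"),
        tilesPerCol = numericKey(kv, "tiles_per_col"),
        tileHeightPx = numericKey(kv, "tile_height_px"),
        tileWidthPx = numericKey(kv, "tile_width_px"),
        channelNames = channels,
        nominalOverlapPx = numericKey(kv, "nominal_overlap_px", 100),
        inPlaneSpacingUm = numericKey(kv, "in_plane_spacing_um", 1.25),
        sectionSpacingUm = numericKey(kv, "section_spacing_um", 50),
        scanOrder = if (is.null(kv[["scan_order"]])) "raster" else kv[["scan_order"]])
    if (numericKey(kv, "n_channels") != meta@nChannels)
        stop("n_channels does not match the number of channel_names", call. = FALSE)
    meta
}

#' @rdname parseBrainMetadata
#' @param meta a [BrainVolumeMetadata-class].
#' @export
formatBrainMetadata <- function(meta) {
    paste0(
        "# brain volume metadata\n",
        "brain_id: ", meta@brainId, "\n",
        "n_sections: ", meta@nSections, "\n",
        "tiles_per_row: ", meta@tilesPerRow, "\n",
        "tiles_per_col: ", meta@tilesPerCol, "\n",
        "tile_height_px: ", meta@tileHeightPx, "\n",
        "tile_width_px: ", meta@tileWidthPx, "\n",
        "n_channels: ", meta@nChannels, "\n",
        "channel_names: ", paste(meta@channelNames, collapse = ", "), "\n",
        "nominal_overlap_px: ", meta@nominalOverlapPx, "\n",
        "in_plane_spacing_um: ", meta@inPlaneSpacingUm, "\n",
        "section_spacing_um: ", meta@sectionSpacingUm, "\n",
        "scan_order: ", meta@scanOrder, "\n")
}

#' @rdname parseBrainMetadata
#' @param path file path.
#' @export
writeBrainMetadata <- function(meta, path) {
    writeLines(formatBrainMetadata(meta), path, sep = "")
    invisible(path)
}

#' @rdname parseBrainMetadata
#' @export
readBrainMetadata <- function(path) {
    if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
    parseBrainMetadata(readLines(path, warn = FALSE))
}

#' Parse and serialize section metadata
#'
#' Same `key: value` dialect as the brain-volume file. Required keys:
#' `section_index`, `canvas_height_px`, `canvas_width_px`, `tiles_per_row`,
#' `tiles_per_col`, `tile_height_px`, `tile_width_px`, `n_channels`;
#' optional: `margin_px` (0).
#'
#' @param text character scalar or vector of metadata text.
#' @return A [SectionMetadata-class] (parse/read) or character (format).
#' @export
parseSectionMetadata <- function(text) {
    kv <- parseKeyValueText(paste(text, collapse = "\n"))
    requireKeys(kv, c("section_index", "canvas_height_px", "canvas_width_px",
                      "tiles_per_row", "tiles_per_col", "tile_height_px",
                      "tile_width_px", "n_channels"))
    sectionMetadata(
        sectionIndex = numericKey(kv, "section_index"),
        canvasHeightPx = numericKey(kv, "canvas_height_px"),
        canvasWidthPx = numericKey(kv, "canvas_width_px"),
        tilesPerRow = numericKey(kv, "tiles_per_row"),
        tilesPerCol = numericKey(kv, "tiles_per_col"),
        tileHeightPx = numericKey(kv, "tile_height_px"),
        tileWidthPx = numericKey(kv, "tile_width_px"),
        nChannels = numericKey(kv, "n_channels"),
        marginPx = numericKey(kv, "margin_px", 0))
}

#' @rdname parseSectionMetadata
#' @param secMeta a [SectionMetadata-class].
#' @export
formatSectionMetadata <- function(secMeta) {
    paste0(
        "# section metadata\n",
        "section_index: ", secMeta@sectionIndex, "\n",
        "canvas_height_px: ", secMeta@canvasHeightPx, "\n",
        "canvas_width_px: ", secMeta@canvasWidthPx, "\n",
        "tiles_per_row: ", secMeta@tilesPerRow, "\n",
        "tiles_per_col: ", secMeta@tilesPerCol, "\n",
        "tile_height_px: ", secMeta@tileHeightPx, "\n",
        "tile_width_px: ", secMeta@tileWidthPx, "\n",
        "n_channels: ", secMeta@nChannels, "\n",
        "margin_px: ", secMeta@marginPx, "\n")
}

#' @rdname parseSectionMetadata
#' @param path file path.
#' @export
writeSectionMetadata <- function(secMeta, path) {
    writeLines(formatSectionMetadata(secMeta), path, sep = "")
    invisible(path)
}

#' @rdname parseSectionMetadata
#' @export
readSectionMetadata <- function(path) {
    if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
    parseSectionMetadata(readLines(path, warn = FALSE))
}

#' Canonical tile file name
#'
#' @param brainId acquisition identifier.
#' @param section,row,col zero-based indices.
#' @param channel channel label.
#' @return File name like `B0039_S0000_R00_C00_red.tif`.
#' @export
tileFileName <- function(brainId, section, row, col, channel) {
    sprintf("%s_S%04d_R%02d_C%02d_%s.tif", brainId, section, row, col, channel)
}

#' Enumerate the tile hierarchy of a brain
#'
#' Builds the complete expected record set — exactly
#' `nSections * tilesPerCol * tilesPerRow * nChannels` rows, sorted by
#' (section, row, col, channel in metadata order) — and flags records whose
#' file is absent on disk with `missing = TRUE`. Missing tiles are later
#' substituted by all-zero placeholder images.
#'
#' @param rootPath directory containing the `<brainId>` folder.
#' @param meta a [BrainVolumeMetadata-class].
#' @return data.frame with columns `filePath`, `sectionIndex`, `row`, `col`,
#'   `channel`, `missing`.
#' @export
enumerateTiles <- function(rootPath, meta) {
    if (!dir.exists(rootPath))
        stop("root path does not exist: ", rootPath, call. = FALSE)
    grid <- expand.grid(channel = meta@channelNames,
                        col = seq_len(meta@tilesPerRow) - 1L,
                        row = seq_len(meta@tilesPerCol) - 1L,
                        sectionIndex = seq_len(meta@nSections) - 1L,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("sectionIndex", "row", "col", "channel")]
    paths <- file.path(rootPath, meta@brainId, sprintf("%04d", grid$sectionIndex),
                       tileFileName(meta@brainId, grid$sectionIndex, grid$row,
                                    grid$col, grid$channel))
    data.frame(filePath = paths, grid, missing = !file.exists(paths),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Load a tile image, substituting zeros for missing tiles
#'
#' A record flagged `missing` yields an all-zero placeholder of the standard
#' tile shape, so downstream normalization, correction and stitching never
#' stall on absent files. A present file whose shape disagrees with the
#' brain metadata is an error naming the path.
#'
#' @param record one row of the [enumerateTiles()] data.frame (or a list with
#'   the same fields).
#' @param meta a [BrainVolumeMetadata-class].
#' @return A [Tile-class].
#' @export
loadTile <- function(record, meta) {
    shape <- c(meta@tileHeightPx, meta@tileWidthPx)
    if (isTRUE(record$missing)) {
        return(tile(matrix(0, shape[1], shape[2]),
                    sectionIndex = record$sectionIndex, row = record$row,
                    col = record$col, channel = record$channel,
                    missing = TRUE, filePath = record$filePath))
    }
    px <- readImageTiff(record$filePath)
    if (!all(dim(px) == shape))
        stop(sprintf("tile shape mismatch for '%s': got %d x %d, expected %d x %d",
                     record$filePath, nrow(px), ncol(px), shape[1], shape[2]),
             call. = FALSE)
    tile(px, sectionIndex = record$sectionIndex, row = record$row,
         col = record$col, channel = record$channel, missing = FALSE,
         filePath = record$filePath)
}

#' Group tile records by section
#'
#' Partitions the record set into one group per section index; the union of
#' the groups equals the input and each group is sorted by (row, col,
#' channel).
#'
#' @param records data.frame from [enumerateTiles()].
#' @return Named list of data.frames, names are section indices.
#' @export
groupBySection <- function(records) {
    if (nrow(records) == 0) return(stats::setNames(list(), character()))
    groups <- split(records, records$sectionIndex)
    lapply(groups, function(g) {
        g[order(g$row, g$col, g$channel), , drop = FALSE]
    })
}
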