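## Orchestration of the two workflows: (1) tile adjustment + stitching,
## (2) 2D-to-3D conversion + visualization products. Tiles are independent
## through normalization/correction; stitching needs all tiles of a
## (section, channel), so sections are the parallel unit — results are
## identical for any worker count, only wall time changes.

#' Pipeline configuration
#'
#' @slot inputRoot directory containing the `<brainId>` acquisition folder.
#' @slot outputRoot directory for all outputs (created).
#' @slot brainId acquisition identifier.
#' @slot channels channel subset to process (empty = all).
#' @slot profileScope `"brain"` (one flat-field profile per channel from all
#'   sections, default) or `"section"` (profile recomputed per section).
#' @slot modelPath path to a saved [DeformationModel-class], or `NA` to skip
#'   distortion correction.
#' @slot paramsPath path to saved [TranslationParams-class] JSON, or `NA` to
#'   estimate them from a middle section.
#' @slot blend `"feather"` or `"mean"`.
#' @slot workers parallel worker count (section-level parallelism).
#' @slot seed RNG seed recorded in manifests (the pipeline itself is
#'   deterministic).
#' @slot rescale factor returning normalized intensities to storage units;
#'   `NA` uses each channel profile's global mean.
#' @slot downsampleUm in-plane target spacings for downsampled NIfTI
#'   exports.
#' @slot zarrLevels OME-Zarr pyramid levels.
#' @slot viewerHost base URL the zarr store would be served from.
#' @slot failFast stop at the first section error instead of recording it.
#' @export
setClass("PipelineConfig",
    slots = c(inputRoot = "character", outputRoot = "character",
              brainId = "character", channels = "character",
              profileScope = "character", modelPath = "character",
              paramsPath = "character", blend = "character",
              workers = "numeric", seed = "numeric", rescale = "numeric",
              downsampleUm = "numeric", zarrLevels = "numeric",
              viewerHost = "character", failFast = "logical")
)

setValidity("PipelineConfig", function(object) {
    msgs <- character()
    if (!dir.exists(object@inputRoot))
        msgs <- c(msgs, paste0("inputRoot does not exist: ", object@inputRoot))
    if (object@workers < 1) msgs <- c(msgs, "workers must be >= 1")
    if (!object@blend %in% c("feather", "mean"))
        msgs <- c(msgs, "blend must be 'feather' or 'mean'")
    if (!object@profileScope %in% c("brain", "section"))
        msgs <- c(msgs, "profileScope must be 'brain' or 'section'")
    if (length(msgs)) msgs else TRUE
})

#' Construct a pipeline configuration
#'
#' @param inputRoot,outputRoot,brainId see [PipelineConfig-class].
#' @param channels channel subset (default all).
#' @param profileScope `"brain"` or `"section"`.
#' @param modelPath,paramsPath optional saved calibration artifacts.
#' @param blend blending mode.
#' @param workers parallel worker count.
#' @param seed recorded seed.
#' @param rescale storage rescale factor (`NA` = profile mean).
#' @param downsampleUm downsampled NIfTI in-plane spacings.
#' @param zarrLevels pyramid levels.
#' @param viewerHost served-store base URL.
#' @param failFast stop on first error.
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(inputRoot, outputRoot, brainId,
                           channels = character(), profileScope = "brain",
                           modelPath = NA_character_, paramsPath = NA_character_,
                           blend = "feather", workers = 1L, seed = 1L,
                           rescale = NA_real_, downsampleUm = c(10, 50),
                           zarrLevels = 3L, viewerHost = "http://127.0.0.1:8080",
                           failFast = FALSE) {
    new("PipelineConfig", inputRoot = inputRoot, outputRoot = outputRoot,
        brainId = brainId, channels = channels, profileScope = profileScope,
        modelPath = modelPath, paramsPath = paramsPath, blend = blend,
        workers = workers, seed = seed, rescale = rescale,
        downsampleUm = downsampleUm, zarrLevels = zarrLevels,
        viewerHost = viewerHost, failFast = failFast)
}

configSnapshot <- function(config) {
    sn <- lapply(slotNames("PipelineConfig"), function(s) slot(config, s))
    names(sn) <- slotNames("PipelineConfig")
    sn
}

md5OfPaths <- function(paths) {
    paths <- sort(paths)
    sums <- tools::md5sum(paths)
    stats::setNames(as.vector(sums), basename(paths))
}

## Incremental per-channel mean over non-missing, non-zero tiles.
profileFromRecords <- function(records, meta, channel) {
    recs <- records[records$channel == channel & !records$missing, , drop = FALSE]
    acc <- NULL; n <- 0L
    for (i in seq_len(nrow(recs))) {
        px <- loadTile(recs[i, ], meta)@pixels
        if (!any(px != 0)) next
        acc <- if (is.null(acc)) px else acc + px
        n <- n + 1L
    }
    if (n == 0L) stop("no tiles to average for channel ", channel, call. = FALSE)
    px <- acc / n
    new("Profile", channel = channel, pixels = px, nTilesAveraged = n,
        epsilon = max(1e-6, 1e-3 * mean(px)))
}

#' Run the tile-adjustment and stitching workflow
#'
#' Stages: read brain metadata, enumerate tiles (missing tiles become zero
#' placeholders), compute or load per-channel flat-field profiles, load the
#' deformation model and translation parameters (estimating the latter from
#' a middle section when no saved file is given), then per section and
#' channel: load, normalize, correct, stitch, write. Sections run in
#' parallel across `workers`; outputs are byte-identical for any worker
#' count. A JSON run manifest (config snapshot, per-section status, missing
#' and clipped counts, timings, output checksums) is written even when some
#' sections fail.
#'
#' @param config a [PipelineConfig-class].
#' @return Invisibly, the manifest list.
#' @export
runStitchPipeline <- function(config) {
    validObject(config)
    t0 <- Sys.time()
    meta <- readBrainMetadata(file.path(config@inputRoot, config@brainId,
                                        "brain_volume_metadata.txt"))
    channels <- if (length(config@channels)) config@channels else meta@channelNames
    stopIfNot(all(channels %in% meta@channelNames), "unknown channel requested")
    records <- enumerateTiles(config@inputRoot, meta)
    groups <- groupBySection(records)
    secDir <- file.path(config@outputRoot, "sections")
    dir.create(secDir, recursive = TRUE, showWarnings = FALSE)

    model <- if (!is.na(config@modelPath)) loadDeformationModel(config@modelPath)
             else NULL
    params <- if (!is.na(config@paramsPath)) loadTranslationParams(config@paramsPath)
              else NULL
    profiles <- NULL
    if (config@profileScope == "brain")
        profiles <- lapply(stats::setNames(channels, channels),
                           function(ch) profileFromRecords(records, meta, ch))
    if (is.null(params)) {
        midSec <- sprintf("%d", (meta@nSections - 1) %/% 2)
        g <- groups[[midSec]]
        recs <- g[g$channel == channels[1], , drop = FALSE]
        recs <- recs[order(recs$row, recs$col), , drop = FALSE]
        tl <- lapply(seq_len(nrow(recs)), function(i) loadTile(recs[i, ], meta))
        ## estimate on processed tiles: vignetting and lens distortion bias
        ## the correlation peak, so normalization/correction come first
        prof0 <- if (config@profileScope == "brain") profiles[[channels[1]]]
                 else computeProfile(tl, channel = channels[1])
        tl <- lapply(tl, normalizeTile, profile = prof0)
        if (!is.null(model)) tl <- lapply(tl, applyCorrection, model = model)
        ## strip widths scale with the nominal overlap so the search range
        ## [narrow, wide] brackets it with headroom for drift
        ov <- meta@nominalOverlapPx
        mp <- min(10L, (min(meta@tileHeightPx, meta@tileWidthPx) - 2L) %/% 2L)
        wide <- min(ov + mp, min(meta@tileHeightPx, meta@tileWidthPx))
        narrow <- max(1L, ov %/% 2L)
        cfg <- stripConfig(wide, narrow, mp)
        params <- estimateTranslationParams(tl, meta@tilesPerCol, meta@tilesPerRow,
            cfg = cfg, nominalOverlapPx = ov)
        saveTranslationParams(params, file.path(config@outputRoot,
                                                "translation_params.json"))
    }

    processSection <- function(sKey) {
        st <- Sys.time()
        status <- list(section = as.integer(sKey), tilesLoaded = 0L,
                       missingTiles = 0L, clippedPixels = 0L,
                       outputs = character(), error = NULL)
        tryCatch({
            g <- groups[[sKey]]
            sPath <- file.path(config@inputRoot, config@brainId,
                               sprintf("%04d", as.integer(sKey)),
                               "section_metadata.txt")
            secMeta <- readSectionMetadata(sPath)
            placements <- computeTilePositions(secMeta, params)
            for (ch in channels) {
                recs <- g[g$channel == ch, , drop = FALSE]
                recs <- recs[order(recs$row, recs$col), , drop = FALSE]
                tl <- lapply(seq_len(nrow(recs)), function(i) loadTile(recs[i, ], meta))
                status$tilesLoaded <- status$tilesLoaded + length(tl)
                status$missingTiles <- status$missingTiles +
                    sum(vapply(tl, function(t) t@missing, logical(1)))
                prof <- if (config@profileScope == "brain") profiles[[ch]]
                        else computeProfile(tl, channel = ch)
                norm <- lapply(tl, normalizeTile, profile = prof)
                if (!is.null(model)) norm <- lapply(norm, applyCorrection, model = model)
                sec <- stitchSection(norm, placements,
                    c(secMeta@canvasHeightPx, secMeta@canvasWidthPx),
                    blend = config@blend,
                    sectionIndex = secMeta@sectionIndex, channel = ch)
                resc <- if (is.na(config@rescale)) mean(prof@pixels) else config@rescale
                out <- file.path(secDir, sectionFileName(meta@brainId,
                                                         secMeta@sectionIndex, ch))
                wr <- writeSection(sec, out, rescale = resc)
                status$clippedPixels <- status$clippedPixels + wr$clippedPixels
                status$outputs <- c(status$outputs, out)
            }
            NULL
        }, error = function(e) status$error <<- conditionMessage(e))
        status$seconds <- as.numeric(difftime(Sys.time(), st, units = "secs"))
        status
    }

    keys <- names(groups)
    results <- if (config@workers > 1)
        parallel::mclapply(keys, processSection, mc.cores = config@workers)
    else lapply(keys, processSection)
    errs <- Filter(Negate(is.null), lapply(results, `[[`, "error"))
    if (config@failFast && length(errs))
        stop("section failed: ", errs[[1]], call. = FALSE)

    outputs <- unlist(lapply(results, `[[`, "outputs"))
    manifest <- list(
        workflow = "stitch",
        config = configSnapshot(config),
        params = list(step_x_px = params@stepXPx, step_y_px = params@stepYPx,
                      dy_at_horizontal_px = params@dyAtHorizontalPx,
                      dx_at_vertical_px = params@dxAtVerticalPx),
        sections = results,
        sectionsProcessed = sum(vapply(results, function(r) is.null(r$error), logical(1))),
        missingTiles = sum(vapply(results, function(r) as.numeric(r$missingTiles %||% 0), numeric(1))),
        clippedPixels = sum(vapply(results, function(r) as.numeric(r$clippedPixels %||% 0), numeric(1))),
        totalSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
        checksums = as.list(md5OfPaths(outputs)))
    jsonWrite(manifest, file.path(config@outputRoot, "stitch_manifest.json"))
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the 2D-to-3D conversion and visualization workflow
#'
#' Reads the stitched section images written by [runStitchPipeline()],
#' stacks them per channel into a [Volume-class] with the metadata's
#' physical spacing, writes full-resolution and downsampled NIfTI files, a
#' multiscale OME-Zarr store, and a Neuroglancer viewer URL. A JSON manifest
#' with output checksums and the URLs is written alongside.
#'
#' @param config a [PipelineConfig-class].
#' @return Invisibly, the manifest list.
#' @export
runVolumePipeline <- function(config) {
    validObject(config)
    t0 <- Sys.time()
    meta <- readBrainMetadata(file.path(config@inputRoot, config@brainId,
                                        "brain_volume_metadata.txt"))
    channels <- if (length(config@channels)) config@channels else meta@channelNames
    secDir <- file.path(config@outputRoot, "sections")
    volDir <- file.path(config@outputRoot, "volumes")
    zarrDir <- file.path(config@outputRoot, "zarr")
    dir.create(volDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(zarrDir, recursive = TRUE, showWarnings = FALSE)
    spacing <- c(meta@sectionSpacingUm, meta@inPlaneSpacingUm, meta@inPlaneSpacingUm)
    outputs <- character(); urls <- list()
    for (ch in channels) {
        paths <- file.path(secDir, sectionFileName(meta@brainId,
                                                   seq_len(meta@nSections) - 1L, ch))
        absent <- which(!file.exists(paths))
        if (length(absent))
            stop("missing stitched sections for channel ", ch, ": ",
                 paste(absent - 1L, collapse = ", "), call. = FALSE)
        mats <- lapply(paths, readSection)
        vol <- stackSections(mats, spacingUm = spacing,
                             brainId = meta@brainId, channel = ch)
        full <- file.path(volDir, sprintf("%s_%s_full.nii.gz", meta@brainId, ch))
        writeNiftiVolume(vol, full)
        outputs <- c(outputs, full)
        for (tgt in config@downsampleUm) {
            if (tgt < meta@inPlaneSpacingUm) next
            ds <- downsampleVolume(vol, tgt)
            p <- file.path(volDir, sprintf("%s_%s_%gum.nii.gz", meta@brainId, ch, tgt))
            writeNiftiVolume(ds, p)
            outputs <- c(outputs, p)
        }
        store <- file.path(zarrDir, sprintf("%s_%s.zarr", meta@brainId, ch))
        writeOmeZarr(vol, store, nLevels = config@zarrLevels)
        urls[[ch]] <- viewerUrl(store, host = config@viewerHost)
        outputs <- c(outputs, list.files(store, recursive = TRUE,
                                         all.files = TRUE, full.names = TRUE,
                                         no.. = TRUE))
    }
    manifest <- list(
        workflow = "volume",
        config = configSnapshot(config),
        channels = channels,
        viewerUrls = urls,
        totalSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
        checksums = as.list(md5OfPaths(outputs)))
    jsonWrite(manifest, file.path(config@outputRoot, "volume_manifest.json"))
    invisible(manifest)
}
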