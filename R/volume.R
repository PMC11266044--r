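## 2D-to-3D assembly: stack stitched sections into a volume with physical
## spacing, export NIfTI-1 and multiscale OME-Zarr, and emit a Neuroglancer
## viewer URL. The default spacing is 1.25 um in-plane and 50 um between
## sections; downsampled exports target the isotropic in-plane resolutions
## the Allen CCF is distributed at.

#' Stack section images into a 3D volume
#'
#' Sections are ordered by their section index (not by arrival order);
#' indices must be contiguous unless `allowGaps` zero-fills absent planes.
#' All sections must share one shape.
#'
#' @param sections list of [SectionImage-class] objects (carrying their
#'   indices) or matrices (indexed 0, 1, ... in list order).
#' @param spacingUm numeric length-3 `(z, y, x)` spacing in micrometres.
#' @param brainId,channel recorded on the volume.
#' @param allowGaps zero-fill missing indices instead of erroring.
#' @return A [Volume-class] with voxels ordered (z, y, x).
#' @export
stackSections <- function(sections, spacingUm = c(50, 1.25, 1.25),
                          brainId = "", channel = "", allowGaps = FALSE) {
    stopIfNot(length(sections) >= 1, "at least one section is required")
    idx <- vapply(seq_along(sections), function(i) {
        s <- sections[[i]]
        if (is(s, "SectionImage")) as.numeric(s@sectionIndex) else i - 1
    }, numeric(1))
    mats <- lapply(sections, function(s)
        if (is(s, "SectionImage")) s@pixels else s)
    ord <- order(idx)
    idx <- idx[ord]; mats <- mats[ord]
    if (anyDuplicated(idx))
        stop("duplicate section indices: ",
             paste(idx[duplicated(idx)], collapse = ", "), call. = FALSE)
    shp <- dim(mats[[1]])
    for (i in seq_along(mats))
        if (!identical(dim(mats[[i]]), shp))
            stop(sprintf("section %d has shape %d x %d, expected %d x %d",
                         idx[i], nrow(mats[[i]]), ncol(mats[[i]]), shp[1], shp[2]),
                 call. = FALSE)
    zIdx <- idx - idx[1]
    nz <- max(zIdx) + 1
    if (!allowGaps && length(idx) != nz)
        stop("gap in section indices: missing ",
             paste(setdiff(seq_len(nz) - 1 + idx[1], idx), collapse = ", "),
             " (use allowGaps = TRUE to zero-fill)", call. = FALSE)
    vox <- array(0, c(nz, shp[1], shp[2]))
    for (i in seq_along(mats)) vox[zIdx[i] + 1, , ] <- mats[[i]]
    new("Volume", voxels = vox, spacingUm = spacingUm, channel = channel,
        brainId = brainId)
}

#' Write and read a volume as NIfTI-1
#'
#' The voxel array is stored in (x, y, z) order as NIfTI requires; the
#' header pixel dimensions carry the physical spacing in millimetres
#' (micrometres / 1000) in the (x, y, z) slots, and the affine is the
#' corresponding scaled identity. The anatomical orientation is not
#' calibrated: the z axis is the sectioning order as imaged. Round trips are
#' voxel-exact for integer data written as `uint16`.
#'
#' @param vol a [Volume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype `"uint16"`, `"float"` or `"double"`; default picks
#'   `uint16` for 16-bit-integer-valued voxels, `double` otherwise.
#' @return The path (write) or a restored [Volume-class] (read).
#' @export
writeNiftiVolume <- function(vol, path, datatype = NULL) {
    v <- vol@voxels
    if (is.null(datatype)) {
        intish <- all(v == round(v)) && min(v) >= 0 && max(v) <= 65535
        datatype <- if (intish) "uint16" else "double"
    }
    arr <- aperm(v, c(3, 2, 1))   # (z,y,x) -> (x,y,z)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol@spacingUm[c(3, 2, 1)] / 1000
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' @rdname writeNiftiVolume
#' @param brainId,channel recorded on the restored volume.
#' @export
readNiftiVolume <- function(path, brainId = "", channel = "") {
    img <- RNifti::readNifti(path)
    arr <- aperm(as.array(img), c(3, 2, 1))
    storage.mode(arr) <- "double"
    ## header pixdims are float32; strip the representation noise
    new("Volume", voxels = arr,
        spacingUm = signif(RNifti::pixdim(img)[c(3, 2, 1)] * 1000, 7),
        channel = channel, brainId = brainId)
}

blockMeanAxis <- function(arr, f, axis) {
    if (f == 1) return(arr)
    d <- dim(arr)
    keep <- floor(d[axis] / f) * f
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[axis]] <- seq_len(keep)
    arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- colMeans(array(a, c(f, prod(da) / f)))
    a <- array(m, c(da[1] / f, da[2], da[3]))
    aperm(a, order(perm))
}

#' Block-mean downsample a volume toward a target spacing
#'
#' Integer downsampling factors are chosen per axis as the nearest integer
#' to `target / source` (at least 1); voxels are averaged over blocks and
#' the spacing becomes `source * factor`. Constant volumes stay constant.
#'
#' @param vol a [Volume-class].
#' @param targetSpacingUm numeric length-3 `(z, y, x)` target spacing, or a
#'   scalar applied to the in-plane (y, x) axes only — the usual way to
#'   produce 10-um or 50-um reference-resolution versions.
#' @return A downsampled [Volume-class].
#' @export
downsampleVolume <- function(vol, targetSpacingUm) {
    src <- vol@spacingUm
    tgt <- if (length(targetSpacingUm) == 1)
        c(src[1], targetSpacingUm, targetSpacingUm) else targetSpacingUm
    stopIfNot(length(tgt) == 3, "targetSpacingUm must be length 1 or 3")
    if (any(tgt < src - 1e-9))
        stop("target spacing must be at least the source spacing per axis",
             call. = FALSE)
    f <- pmax(1L, as.integer(round(tgt / src)))
    v <- vol@voxels
    for (ax in 1:3) v <- blockMeanAxis(v, f[ax], ax)
    new("Volume", voxels = v, spacingUm = src * f, channel = vol@channel,
        brainId = vol@brainId)
}

#' Write a volume as multiscale OME-Zarr (NGFF 0.4)
#'
#' Intensities are first exposure-rescaled: the given percentiles of the
#' voxel distribution are mapped linearly onto the dtype range (clipping
#' outside), which makes faint labeling visible in the viewer. Level 0
#' holds the rescaled voxels; each further level halves y and x by block
#' averaging. Axes are (z, y, x) with micrometre units and per-level scale
#' metadata.
#'
#' @param vol a [Volume-class].
#' @param path store directory to create.
#' @param nLevels number of pyramid levels (>= 1).
#' @param chunkShape integer length-3 chunk shape; the default
#'   `(1, 512, 512)` makes section-aligned reads cheap.
#' @param exposure length-2 percentile pair for the rescale; `(0, 100)` on
#'   data already spanning the dtype range is a no-op.
#' @param dtype `"uint16"` or `"float32"`.
#' @return Invisibly, the store path.
#' @export
writeOmeZarr <- function(vol, path, nLevels = 3L, chunkShape = c(1L, 512L, 512L),
                         exposure = c(0.5, 99.5), dtype = c("uint16", "float32")) {
    dtype <- match.arg(dtype)
    stopIfNot(nLevels >= 1, "nLevels must be >= 1")
    v <- vol@voxels
    maxd <- if (dtype == "uint16") 65535 else 1
    lo <- as.numeric(stats::quantile(v, exposure[1] / 100, names = FALSE))
    hi <- as.numeric(stats::quantile(v, exposure[2] / 100, names = FALSE))
    if (hi > lo) {
        v <- (v - lo) / (hi - lo) * maxd
        v[v < 0] <- 0
        v[v > maxd] <- maxd
    }
    if (dtype == "uint16") v <- round(v)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    writeLines('{\n    "zarr_format": 2\n}\n', file.path(path, ".zgroup"), sep = "")
    zdt <- if (dtype == "uint16") "<u2" else "<f4"
    datasets <- vector("list", nLevels)
    lvl <- v
    for (k in seq_len(nLevels) - 1L) {
        if (k > 0) {
            lvl <- blockMeanAxis(blockMeanAxis(lvl, 2L, 2L), 2L, 3L)
            if (dtype == "uint16") lvl <- round(lvl)
        }
        zarrWriteArray(lvl, file.path(path, as.character(k)), chunkShape, zdt)
        datasets[[k + 1]] <- list(
            path = as.character(k),
            coordinateTransformations = list(list(
                type = "scale",
                scale = c(vol@spacingUm[1], vol@spacingUm[2] * 2^k,
                          vol@spacingUm[3] * 2^k))))
    }
    attrs <- list(multiscales = list(list(
        version = "0.4",
        name = if (nzchar(vol@brainId)) vol@brainId else "volume",
        axes = list(list(name = "z", type = "space", unit = "micrometer"),
                    list(name = "y", type = "space", unit = "micrometer"),
                    list(name = "x", type = "space", unit = "micrometer")),
        datasets = datasets,
        metadata = list(method = "block mean 2x in y/x",
                        exposure_percentiles = exposure))))
    jsonWrite(attrs, file.path(path, ".zattrs"))
    invisible(path)
}

#' Read one level of an OME-Zarr store written by [writeOmeZarr()]
#'
#' @param path the store directory.
#' @param level pyramid level (0 = full resolution).
#' @return A [Volume-class] with the level's voxels and spacing.
#' @export
readOmeZarr <- function(path, level = 0L) {
    attrs <- jsonlite::read_json(file.path(path, ".zattrs"))
    ds <- attrs$multiscales[[1]]$datasets[[level + 1]]
    scale <- unlist(ds$coordinateTransformations[[1]]$scale)
    arr <- zarrReadArray(file.path(path, ds$path))
    new("Volume", voxels = arr, spacingUm = as.numeric(scale),
        channel = "", brainId = "")
}

#' Build a Neuroglancer viewer URL for an OME-Zarr store
#'
#' Encodes a viewer state with one zarr-type image layer whose source points
#' at the store as served from `host`. Purely deterministic string
#' construction: the same store and host always give the same URL.
#'
#' @param storePath the OME-Zarr store directory (must exist).
#' @param host base URL under which the store directory is served.
#' @param viewer Neuroglancer instance URL.
#' @return The URL string, with the JSON state URL-encoded in the fragment.
#' @export
viewerUrl <- function(storePath, host = "http://127.0.0.1:8080",
                      viewer = "https://neuroglancer-demo.appspot.com") {
    if (!dir.exists(storePath))
        stop("zarr store not found: ", storePath, call. = FALSE)
    store <- paste0(sub("/+$", "", host), "/", sub("^/+", "", storePath))
    name <- basename(sub("/+$", "", storePath))
    state <- list(layers = list(list(type = "image",
                                     source = paste0("zarr://", store),
                                     name = name)),
                  layout = "4panel")
    json <- as.character(jsonlite::toJSON(state, auto_unbox = TRUE, digits = NA))
    paste0(viewer, "/#!", utils::URLencode(json, reserved = TRUE))
}
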