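## Minimal Zarr v2 store support: uncompressed raw chunks, C order,
## "." dimension separator. Enough to write/read the multiscale image
## pyramids this package produces; not a general Zarr client.

zarrDtypeSize <- function(dtype) {
    switch(dtype, "<u2" = 2L, "<f4" = 4L, "<f8" = 8L,
           stop("unsupported zarr dtype: ", dtype, call. = FALSE))
}

writeZarrChunk <- function(block, path, dtype) {
    ## `block` has dims (z, y, x); file layout is C order (x fastest)
    v <- as.vector(aperm(block, c(3, 2, 1)))
    con <- file(path, "wb")
    on.exit(close(con))
    if (dtype == "<u2") {
        v <- as.integer(round(v))
        v[v < 0] <- 0L
        v[v > 65535L] <- 65535L
        v[v > 32767L] <- v[v > 32767L] - 65536L   # two's-complement bytes
        writeBin(v, con, size = 2L, endian = "little")
    } else {
        writeBin(as.numeric(v), con, size = zarrDtypeSize(dtype), endian = "little")
    }
    invisible(path)
}

readZarrChunk <- function(path, chunkShape, dtype) {
    n <- prod(chunkShape)
    con <- file(path, "rb")
    on.exit(close(con))
    v <- if (dtype == "<u2") {
        x <- readBin(con, integer(), n, size = 2L, signed = FALSE, endian = "little")
        as.numeric(x)
    } else {
        readBin(con, numeric(), n, size = zarrDtypeSize(dtype), endian = "little")
    }
    aperm(array(v, rev(chunkShape)), c(3, 2, 1))
}

#' Write a 3D array as a Zarr v2 array directory
#'
#' Chunks are stored raw (no compressor), C order, little-endian, with `.`
#' as the dimension separator — readable by any Zarr v2 client. Edge chunks
#' are zero-padded to the full chunk shape, as the format requires.
#'
#' @param arr 3D numeric array ordered (z, y, x).
#' @param dir output directory (created).
#' @param chunkShape integer length-3 chunk shape.
#' @param dtype `"<u2"`, `"<f4"` or `"<f8"`.
#' @return Invisibly, `dir`.
#' @export
zarrWriteArray <- function(arr, dir, chunkShape = c(1L, 512L, 512L),
                           dtype = "<u2") {
    stopIfNot(length(dim(arr)) == 3L, "arr must be a 3D array")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    shape <- dim(arr)
    chunkShape <- pmin(as.integer(chunkShape), shape)
    meta <- paste0('{\n    "chunks": [', paste(chunkShape, collapse = ", "),
        '],\n    "compressor": null,\n    "dimension_separator": ".",',
        '\n    "dtype": "', dtype, '",\n    "fill_value": 0,',
        '\n    "filters": null,\n    "order": "C",\n    "shape": [',
        paste(shape, collapse = ", "), '],\n    "zarr_format": 2\n}\n')
    writeLines(meta, file.path(dir, ".zarray"), sep = "")
    nChunks <- ceiling(shape / chunkShape)
    for (cz in seq_len(nChunks[1]) - 1L)
        for (cy in seq_len(nChunks[2]) - 1L)
            for (cx in seq_len(nChunks[3]) - 1L) {
                zi <- (cz * chunkShape[1] + 1):min((cz + 1) * chunkShape[1], shape[1])
                yi <- (cy * chunkShape[2] + 1):min((cy + 1) * chunkShape[2], shape[2])
                xi <- (cx * chunkShape[3] + 1):min((cx + 1) * chunkShape[3], shape[3])
                block <- array(0, chunkShape)
                block[seq_along(zi), seq_along(yi), seq_along(xi)] <-
                    arr[zi, yi, xi, drop = FALSE]
                writeZarrChunk(block, file.path(dir, paste(cz, cy, cx, sep = ".")),
                               dtype)
            }
    invisible(dir)
}

#' Read a 3D Zarr v2 array directory written by [zarrWriteArray()]
#'
#' @param dir the array directory.
#' @return 3D numeric array ordered (z, y, x).
#' @export
zarrReadArray <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, ".zarray"), simplifyVector = TRUE)
    shape <- as.integer(meta$shape)
    chunkShape <- as.integer(meta$chunks)
    arr <- array(0, shape)
    nChunks <- ceiling(shape / chunkShape)
    for (cz in seq_len(nChunks[1]) - 1L)
        for (cy in seq_len(nChunks[2]) - 1L)
            for (cx in seq_len(nChunks[3]) - 1L) {
                block <- readZarrChunk(file.path(dir, paste(cz, cy, cx, sep = ".")),
                                       chunkShape, meta$dtype)
                zi <- (cz * chunkShape[1] + 1):min((cz + 1) * chunkShape[1], shape[1])
                yi <- (cy * chunkShape[2] + 1):min((cy + 1) * chunkShape[2], shape[2])
                xi <- (cx * chunkShape[3] + 1):min((cx + 1) * chunkShape[3], shape[3])
                arr[zi, yi, xi] <- block[seq_along(zi), seq_along(yi), seq_along(xi)]
            }
    arr
}
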