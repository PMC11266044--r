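## Lens-distortion calibration from a mesh-grid target image and per-tile
## correction. The model is a global projective transform plus a residual
## bicubic-spline displacement field, compiled to a dense per-pixel lookup
## that is calibrated once and reused for every tile of every section.

#' Detect cell corners on a mesh-grid calibration image
#'
#' Pipeline: Otsu threshold -> connected components of the grid holes
#' (`EBImage::bwlabel`) -> discard components touching the image border
#' (partial cells carry insufficient information) and small spurious
#' components -> intensity-weighted hole centroids, organized into a
#' row/column lattice -> each interior cell corner is estimated as the mean
#' of the four surrounding hole centroids, which cancels first-order local
#' distortion. Deterministic and subpixel-capable.
#'
#' @param img numeric matrix of the grid image.
#' @param expectedPitchPx approximate grid pitch in pixels (used to bin holes
#'   into rows and columns; the detected lattice carries its own spacing).
#' @param polarity `"bright_holes"` (dark bars, default) or `"dark_holes"`.
#' @return A detected [CornerLattice-class] (0-based pixel coordinates).
#' @export
detectGridCorners <- function(img, expectedPitchPx,
                              polarity = c("bright_holes", "dark_holes")) {
    polarity <- match.arg(polarity)
    h <- nrow(img); w <- ncol(img)
    rng <- range(img)
    n01 <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
    th <- EBImage::otsu(EBImage::Image(n01))
    mask <- if (polarity == "bright_holes") n01 > th else n01 < th
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    idx <- which(lab > 0)
    if (length(idx) == 0) stop("calibration error: no grid holes found", call. = FALSE)
    lb <- lab[idx]
    ys <- ((idx - 1) %% h) + 1
    xs <- ((idx - 1) %/% h) + 1
    area <- tabulate(lb)
    borderLabs <- unique(lb[ys == 1 | ys == h | xs == 1 | xs == w])
    keepLab <- which(area >= 0.3 * stats::median(area[area > 0]))
    keepLab <- setdiff(keepLab, borderLabs)
    if (length(keepLab) < 4)
        stop("calibration error: fewer than 4 complete cells on the grid",
             call. = FALSE)
    sel <- lb %in% keepLab
    lb <- lb[sel]; ysk <- ys[sel]; xsk <- xs[sel]
    wgt <- if (polarity == "bright_holes") pmax(n01[idx[sel]] - th, 0)
           else pmax(th - n01[idx[sel]], 0)
    wsum <- tapply(wgt, lb, sum)
    cy <- tapply(wgt * ysk, lb, sum) / wsum - 1    # 0-based
    cx <- tapply(wgt * xsk, lb, sum) / wsum - 1
    ## bin centroids into grid rows/columns with the expected pitch
    rowId <- round((cy - min(cy)) / expectedPitchPx)
    colId <- round((cx - min(cx)) / expectedPitchPx)
    nR <- max(rowId) + 1; nC <- max(colId) + 1
    if (nR < 2 || nC < 2)
        stop("calibration error: fewer than 4 complete cells on the grid",
             call. = FALSE)
    occ <- matrix(FALSE, nR, nC)
    HY <- matrix(NA_real_, nR, nC); HX <- matrix(NA_real_, nR, nC)
    for (k in seq_along(cy)) {
        i <- rowId[k] + 1; j <- colId[k] + 1
        if (occ[i, j])
            stop("calibration error: ambiguous hole lattice (check the pitch)",
                 call. = FALSE)
        occ[i, j] <- TRUE; HY[i, j] <- cy[k]; HX[i, j] <- cx[k]
    }
    ## drop incomplete outer rows/columns until the lattice is full
    while (any(!occ) && nrow(occ) >= 2 && ncol(occ) >= 2) {
        rowFill <- rowMeans(occ); colFill <- colMeans(occ)
        if (min(rowFill) <= min(colFill)) {
            i <- which.min(rowFill)
            occ <- occ[-i, , drop = FALSE]; HY <- HY[-i, , drop = FALSE]
            HX <- HX[-i, , drop = FALSE]
        } else {
            j <- which.min(colFill)
            occ <- occ[, -j, drop = FALSE]; HY <- HY[, -j, drop = FALSE]
            HX <- HX[, -j, drop = FALSE]
        }
    }
    if (any(!occ) || nrow(occ) < 2 || ncol(occ) < 2)
        stop("calibration error: could not assemble a complete hole lattice",
             call. = FALSE)
    nR <- nrow(HY); nC <- ncol(HY)
    CY <- (HY[-nR, -nC] + HY[-1, -nC] + HY[-nR, -1] + HY[-1, -1]) / 4
    CX <- (HX[-nR, -nC] + HX[-1, -nC] + HX[-nR, -1] + HX[-1, -1]) / 4
    cornerLattice(as.matrix(CY), as.matrix(CX), "detected")
}

#' Build an ideal template lattice
#'
#' Equally spaced corner positions representing the undistorted grid; the
#' node counts match the complete cells found on the distorted grid.
#'
#' @param nRows,nCols lattice dimensions (>= 2).
#' @param pitchPx node spacing in pixels (scalar, or length-2 `(y, x)`).
#' @param origin length-2 `(y, x)` position of node (1, 1), 0-based pixels.
#' @return A template [CornerLattice-class].
#' @export
buildTemplateLattice <- function(nRows, nCols, pitchPx, origin = c(0, 0)) {
    stopIfNot(nRows >= 2 && nCols >= 2, "lattice dimensions must be >= 2")
    pitchPx <- rep(pitchPx, length.out = 2)
    yv <- origin[1] + (seq_len(nRows) - 1) * pitchPx[1]
    xv <- origin[2] + (seq_len(nCols) - 1) * pitchPx[2]
    cornerLattice(matrix(yv, nRows, nCols),
                  matrix(xv, nRows, nCols, byrow = TRUE), "template")
}

#' Template lattice matched to a detected lattice
#'
#' Same node counts as the detected lattice, ideal pitch, origin chosen so
#' both lattices share their centroid (which keeps the corrected image close
#' to the distorted frame).
#'
#' @param detected a detected [CornerLattice-class].
#' @param pitchPx ideal pitch; default is the detected lattice's median
#'   spacing per axis.
#' @return A template [CornerLattice-class].
#' @export
templateLatticeFor <- function(detected, pitchPx = NULL) {
    nR <- nrow(detected@y); nC <- ncol(detected@y)
    if (is.null(pitchPx)) {
        py <- stats::median(diff(rowMeans(detected@y)))
        px <- stats::median(diff(colMeans(detected@x)))
        pitchPx <- c(py, px)
    }
    pitchPx <- rep(pitchPx, length.out = 2)
    origin <- c(mean(detected@y) - pitchPx[1] * (nR - 1) / 2,
                mean(detected@x) - pitchPx[2] * (nC - 1) / 2)
    buildTemplateLattice(nR, nC, pitchPx, origin)
}

latticeXY <- function(p) {
    if (is(p, "CornerLattice")) latticePoints(p)
    else { stopifnot(ncol(p) == 2); p }
}

#' Fit a projective transformation between two corner lattices
#'
#' Least-squares projective fit (normalized direct linear transform) over all
#' correspondences; for an exact projective relation between the point sets
#' the residual is at numerical precision.
#'
#' @param src,dst [CornerLattice-class] objects (or n x 2 `(y, x)` matrices)
#'   of the same shape, n >= 4.
#' @return A [Homography-class] mapping src points onto dst points, acting on
#'   homogeneous `(y, x, 1)` vectors.
#' @export
fitHomography <- function(src, dst) {
    P <- latticeXY(src); Q <- latticeXY(dst)
    stopIfNot(nrow(P) == nrow(Q), "point sets must have the same size")
    stopIfNot(nrow(P) >= 4, "at least 4 correspondences are required")
    normalizeT <- function(M) {
        ctr <- colMeans(M)
        d <- sqrt(rowSums(sweep(M, 2, ctr)^2))
        s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
        T <- diag(c(s, s, 1)); T[1, 3] <- -s * ctr[1]; T[2, 3] <- -s * ctr[2]
        T
    }
    Tp <- normalizeT(P); Tq <- normalizeT(Q)
    Pn <- t(Tp %*% rbind(t(P), 1))
    Qn <- t(Tq %*% rbind(t(Q), 1))
    n <- nrow(P)
    A <- matrix(0, 2 * n, 9)
    for (i in seq_len(n)) {
        p <- c(Pn[i, 1:2], 1)
        Y <- Qn[i, 1]; X <- Qn[i, 2]
        A[2 * i - 1, ] <- c(p, 0, 0, 0, -Y * p)
        A[2 * i, ] <- c(0, 0, 0, p, -X * p)
    }
    sv <- svd(A)
    if (sv$d[8] / sv$d[1] < 1e-10)
        stop("degenerate (collinear) point configuration", call. = FALSE)
    M <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
    M <- solve(Tq) %*% M %*% Tp
    if (abs(M[3, 3]) < 1e-12)
        stop("homography fit failed (vanishing normalization)", call. = FALSE)
    M <- M / M[3, 3]
    new("Homography", mat = M)
}

#' Apply a homography to points or a lattice
#'
#' @param h a [Homography-class] (or 3x3 matrix).
#' @param y,x numeric vectors of point coordinates.
#' @return `applyHomographyPoints` returns a list with `y` and `x`;
#'   `transformLattice` a transformed [CornerLattice-class].
#' @export
applyHomographyPoints <- function(h, y, x) {
    M <- if (is(h, "Homography")) h@mat else h
    wv <- M[3, 1] * y + M[3, 2] * x + M[3, 3]
    if (any(abs(wv) < 1e-9))
        stop("homography is non-invertible at the queried points", call. = FALSE)
    list(y = (M[1, 1] * y + M[1, 2] * x + M[1, 3]) / wv,
         x = (M[2, 1] * y + M[2, 2] * x + M[2, 3]) / wv)
}

#' @rdname applyHomographyPoints
#' @param lattice a [CornerLattice-class].
#' @export
transformLattice <- function(h, lattice) {
    p <- applyHomographyPoints(h, as.vector(lattice@y), as.vector(lattice@x))
    cornerLattice(matrix(p$y, nrow(lattice@y)), matrix(p$x, nrow(lattice@x)),
                  "detected")
}

#' Fit the residual displacement spline
#'
#' After the global projective alignment a locally varying residual remains.
#' It is modeled as one C2 bicubic (natural spline) interpolant over the
#' per-node displacements `template - projected`, anchored at the template
#' lattice nodes: the field reproduces each node displacement exactly and is
#' bicubic between nodes. (A bicubic spline through a net of Bezier control
#' patches is the same surface in a different basis.)
#'
#' @param projected [CornerLattice-class] of homography-projected detected
#'   corners.
#' @param template the matching template [CornerLattice-class] (regular).
#' @return An object of class `ResidualField`: node displacements plus the
#'   template geometry anchoring the interpolant. Evaluate it with
#'   [evalResidualField()].
#' @export
fitResidualSpline <- function(projected, template) {
    stopIfNot(identical(dim(projected@y), dim(template@y)),
              "lattice shapes must match")
    stopIfNot(template@source == "template",
              "the second lattice must be a template lattice")
    nR <- nrow(template@y); nC <- ncol(template@y)
    structure(list(
        nodeDy = template@y - projected@y,
        nodeDx = template@x - projected@x,
        originY = template@y[1, 1], originX = template@x[1, 1],
        pitchY = if (nR > 1) template@y[2, 1] - template@y[1, 1] else 1,
        pitchX = if (nC > 1) template@x[1, 2] - template@x[1, 1] else 1,
        nRows = nR, nCols = nC), class = "ResidualField")
}

#' Evaluate a residual displacement field
#'
#' Bicubic interpolation of the node displacements at arbitrary positions in
#' template coordinates; queries beyond the lattice hull are clamped
#' (constant extrapolation of the boundary value).
#'
#' @param field a `ResidualField` from [fitResidualSpline()].
#' @param y,x numeric vectors of 0-based template-space coordinates.
#' @return List with displacement components `dy` and `dx`.
#' @export
evalResidualField <- function(field, y, x) {
    u <- (y - field$originY) / field$pitchY + 1
    v <- (x - field$originX) / field$pitchX + 1
    list(dy = bicubicAt(field$nodeDy, u, v),
         dx = bicubicAt(field$nodeDx, u, v))
}

#' Compile the dense per-pixel correction lookup
#'
#' For each output (corrected) pixel `t`, the source coordinate in the
#' distorted image is `H^-1 (t - D(t))`, where `H` is the global homography
#' (detected -> template) and `D` the residual field: at every template node
#' the lookup lands exactly on the detected corner. Beyond the lattice hull
#' the residual is extended by clamped extrapolation.
#'
#' @param h the [Homography-class] mapping detected corners onto the
#'   template.
#' @param residual a `ResidualField` from [fitResidualSpline()].
#' @param tileShape integer `(height, width)` the lookup must cover.
#' @param meta calibration metadata list (grid pitch, id, ...).
#' @return A [DeformationModel-class].
#' @export
buildCorrectionLut <- function(h, residual, tileShape, meta = list()) {
    H <- tileShape[1]; W <- tileShape[2]
    y0 <- seq_len(H) - 1; x0 <- seq_len(W) - 1
    u <- (y0 - residual$originY) / residual$pitchY + 1
    v <- (x0 - residual$originX) / residual$pitchX + 1
    Dy <- bicubicGrid(residual$nodeDy, u, v)
    Dx <- bicubicGrid(residual$nodeDx, u, v)
    qy <- matrix(y0, H, W) - Dy
    qx <- matrix(x0, H, W, byrow = TRUE) - Dx
    Minv <- solve(if (is(h, "Homography")) h@mat else h)
    wv <- Minv[3, 1] * qy + Minv[3, 2] * qx + Minv[3, 3]
    bad <- abs(wv) < 1e-9
    if (any(bad)) {
        ib <- which(bad, arr.ind = TRUE)
        stop(sprintf("non-invertible correction inside the tile near pixel (%d, %d)",
                     ib[1, 1], ib[1, 2]), call. = FALSE)
    }
    srcY <- (Minv[1, 1] * qy + Minv[1, 2] * qx + Minv[1, 3]) / wv
    srcX <- (Minv[2, 1] * qy + Minv[2, 2] * qx + Minv[2, 3]) / wv
    new("DeformationModel",
        homography = if (is(h, "Homography")) h else new("Homography", mat = h),
        nodeDy = residual$nodeDy, nodeDx = residual$nodeDx,
        templateOriginY = residual$originY, templateOriginX = residual$originX,
        templatePitch = c(residual$pitchY, residual$pitchX),
        lutY = srcY + 1, lutX = srcX + 1,   # 1-based for R indexing
        tileShape = as.numeric(tileShape), meta = meta)
}

#' Calibrate a deformation model from a grid-target image
#'
#' Convenience wrapper: detect corners, build the matched template, fit the
#' homography and the residual spline, and compile the dense lookup for the
#' given tile shape. One model per instrument; reuse it for all channels,
#' sections and brains scanned on that instrument.
#'
#' @param gridImage numeric matrix of the imaged calibration grid.
#' @param expectedPitchPx approximate grid pitch in pixels.
#' @param tileShape `(height, width)` of the tiles to correct; defaults to
#'   the grid image shape.
#' @param id free-text calibration identifier stored in the model metadata.
#' @return A [DeformationModel-class].
#' @export
calibrateDeformation <- function(gridImage, expectedPitchPx,
                                 tileShape = dim(gridImage), id = "calibration") {
    det <- detectGridCorners(gridImage, expectedPitchPx)
    tmpl <- templateLatticeFor(det, expectedPitchPx)
    h <- fitHomography(det, tmpl)
    proj <- transformLattice(h, det)
    res <- fitResidualSpline(proj, tmpl)
    buildCorrectionLut(h, res, tileShape,
                       meta = list(grid_pitch_px = expectedPitchPx, id = id,
                                   n_corners = length(det@y)))
}

#' Apply a deformation correction to a tile
#'
#' Resamples the tile at the model's per-pixel source coordinates by bilinear
#' interpolation; out-of-bounds sources take the nearest edge pixel. An
#' identity model returns the input bit-identically; a constant tile stays
#' constant.
#'
#' @param x a [Tile-class] or numeric matrix of the model's tile shape.
#' @param model a [DeformationModel-class].
#' @return Corrected object of the same type as `x`.
#' @export
applyCorrection <- function(x, model) {
    px <- if (is(x, "Tile")) x@pixels else x
    stopIfNot(all(dim(px) == model@tileShape),
              "tile shape does not match the model's tile shape")
    out <- matrix(bilinearSample(px, model@lutY, model@lutX),
                  nrow(px), ncol(px))
    if (is(x, "Tile"))
        new("Tile", pixels = out, sectionIndex = x@sectionIndex, row = x@row,
            col = x@col, channel = x@channel, missing = x@missing,
            filePath = x@filePath)
    else out
}

#' Serialize a deformation model
#'
#' Single-file container: one JSON header (shapes, template geometry,
#' metadata) followed by the raw little-endian float64 payload (homography,
#' node displacements, dense lookup), gzip-compressed. Round trips are
#' bit-exact, so a saved model applied later gives results identical to the
#' session that calibrated it.
#'
#' @param model a [DeformationModel-class].
#' @param path output file path.
#' @return The path (save) or the restored model (load).
#' @export
saveDeformationModel <- function(model, path) {
    header <- jsonlite::toJSON(list(
        format = "BrainMosaic-deformation-model", version = 1L,
        tile_shape = model@tileShape, node_shape = dim(model@nodeDy),
        template_origin = c(model@templateOriginY, model@templateOriginX),
        template_pitch = model@templatePitch, meta = model@meta),
        auto_unbox = TRUE, digits = NA)
    con <- gzfile(path, "wb")
    on.exit(close(con))
    hraw <- charToRaw(as.character(header))
    writeBin(length(hraw), con, size = 4L, endian = "little")
    writeBin(hraw, con)
    writeBin(c(as.vector(model@homography@mat),
               as.vector(model@nodeDy), as.vector(model@nodeDx),
               as.vector(model@lutY), as.vector(model@lutX)),
             con, size = 8L, endian = "little")
    invisible(path)
}

#' @rdname saveDeformationModel
#' @export
loadDeformationModel <- function(path) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    hlen <- readBin(con, integer(), 1, size = 4L, endian = "little")
    header <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), hlen)))
    ts <- as.numeric(header$tile_shape); ns <- as.integer(header$node_shape)
    npay <- 9 + 2 * prod(ns) + 2 * prod(ts)
    pay <- readBin(con, numeric(), npay, size = 8L, endian = "little")
    off <- 0
    take <- function(n) { v <- pay[(off + 1):(off + n)]; off <<- off + n; v }
    Hm <- matrix(take(9), 3, 3)
    nodeDy <- matrix(take(prod(ns)), ns[1], ns[2])
    nodeDx <- matrix(take(prod(ns)), ns[1], ns[2])
    lutY <- matrix(take(prod(ts)), ts[1], ts[2])
    lutX <- matrix(take(prod(ts)), ts[1], ts[2])
    meta <- header$meta
    if (is.null(meta)) meta <- list()
    new("DeformationModel", homography = new("Homography", mat = Hm),
        nodeDy = nodeDy, nodeDx = nodeDx,
        templateOriginY = as.numeric(header$template_origin[1]),
        templateOriginX = as.numeric(header$template_origin[2]),
        templatePitch = as.numeric(header$template_pitch),
        lutY = lutY, lutX = lutX, tileShape = ts, meta = as.list(meta))
}

#' An identity deformation model
#'
#' Useful as a no-op stand-in when no calibration is available; applying it
#' returns tiles unchanged.
#'
#' @param tileShape `(height, width)` in pixels.
#' @return A [DeformationModel-class] whose lookup is the identity map.
#' @export
identityDeformationModel <- function(tileShape) {
    H <- tileShape[1]; W <- tileShape[2]
    new("DeformationModel", homography = new("Homography", mat = diag(3)),
        nodeDy = matrix(0, 2, 2), nodeDx = matrix(0, 2, 2),
        templateOriginY = 0, templateOriginX = 0,
        templatePitch = c(max(H - 1, 1), max(W - 1, 1)),
        lutY = matrix(seq_len(H), H, W),
        lutX = matrix(seq_len(W), H, W, byrow = TRUE),
        tileShape = as.numeric(tileShape), meta = list(id = "identity"))
}
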