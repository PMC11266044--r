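## Inter-tile translation estimation from overlap strips via normalized
## cross-correlation. Placement is integer-pixel: the mosaic is assembled
## pixel by pixel, so no subpixel refinement is applied by default.

#' Normalized cross-correlation surface
#'
#' Slides `template` over every placement at which it fits inside `search`
#' and computes, per placement, `sum((a - mean(a)) * (b - mean(b))) /
#' (N * sd(a) * sd(b))` over the overlap (population SDs), i.e. values in
#' [-1, 1]. A zero-variance template or window yields 0 at that placement
#' (no evidence either way, flagged low-confidence downstream).
#'
#' @param template numeric matrix.
#' @param search numeric matrix at least as large as `template`.
#' @return Matrix of size `(nrow(search) - nrow(template) + 1) x
#'   (ncol(search) - ncol(template) + 1)`; entry `(i, j)` is the correlation
#'   with the template's top-left pixel over `search[i, j]`.
#' @export
nccSurface <- function(template, search) {
    th <- nrow(template); tw <- ncol(template)
    sh <- nrow(search); sw <- ncol(search)
    stopIfNot(th <= sh && tw <= sw,
              "template must fit inside the search region")
    a <- template - mean(template)
    sa <- sqrt(sum(a * a))
    nr <- sh - th + 1L; nc <- sw - tw + 1L
    out <- matrix(0, nr, nc)
    for (j in seq_len(nc)) {
        block <- search[, j:(j + tw - 1), drop = FALSE]
        for (i in seq_len(nr)) {
            b <- block[i:(i + th - 1), , drop = FALSE]
            bc <- b - mean(b)
            sb <- sqrt(sum(bc * bc))
            out[i, j] <- if (sa == 0 || sb == 0) 0 else sum(a * bc) / (sa * sb)
        }
    }
    out
}

#' Estimate the shift between one pair of adjacent tiles
#'
#' For a horizontal pair, a wide strip is taken from the leading (left)
#' tile's right edge and a narrower strip from the trailing (right) tile's
#' left edge; the narrow strip is slid over the wide one under NCC, over the
#' along-axis range implied by the strip widths and a +/-
#' `maxPerpendicularShiftPx` perpendicular range. Vertical pairs are handled
#' by transposition. Ties at equal correlation break toward the nominal
#' overlap (and zero drift), which makes the estimate deterministic.
#'
#' @param leading,trailing [Tile-class] objects or matrices of equal shape;
#'   `leading` is the left (horizontal) or top (vertical) tile.
#' @param direction `"horizontal"` or `"vertical"`.
#' @param cfg a [StripConfig-class].
#' @param nominalOverlapPx nominal overlap used for tie-breaking.
#' @return List with `dx`, `dy` (integer offsets of the trailing tile's
#'   origin relative to the leading tile's origin), `peakNcc`, and `ok`
#'   (`FALSE` when the peak falls below the confidence floor; such pairs are
#'   excluded from aggregation).
#' @export
estimatePairShift <- function(leading, trailing,
                              direction = c("horizontal", "vertical"),
                              cfg = stripConfig(), nominalOverlapPx = 100L) {
    direction <- match.arg(direction)
    L <- if (is(leading, "Tile")) leading@pixels else leading
    R <- if (is(trailing, "Tile")) trailing@pixels else trailing
    stopIfNot(identical(dim(L), dim(R)), "tiles must have the same shape")
    if (direction == "vertical") {
        res <- estimatePairShift(t(L), t(R), "horizontal", cfg, nominalOverlapPx)
        return(list(dx = res$dy, dy = res$dx, peakNcc = res$peakNcc, ok = res$ok))
    }
    h <- nrow(L); w <- ncol(L)
    wide <- cfg@wideStripPx; narrow <- cfg@narrowStripPx
    mp <- cfg@maxPerpendicularShiftPx
    stopIfNot(wide <= w, "wide strip exceeds the tile width")
    stopIfNot(h > 2 * mp, "perpendicular search range exceeds the tile height")
    wideStrip <- L[, (w - wide + 1):w, drop = FALSE]
    narrowStrip <- R[(1 + mp):(h - mp), 1:narrow, drop = FALSE]
    surf <- nccSurface(narrowStrip, wideStrip)
    ## placement (i, j): trailing origin offsets relative to leading origin
    dxs <- w - wide + col(surf) - 1     # along-axis step
    dys <- row(surf) - 1 - mp           # perpendicular drift
    peak <- max(surf)
    cand <- which(surf >= peak - 1e-12)
    ## tie-break: closest to nominal overlap, then smallest |drift|
    pref <- abs(dxs[cand] - (w - nominalOverlapPx)) * 1000 + abs(dys[cand])
    best <- cand[which.min(pref)]
    list(dx = as.integer(dxs[best]), dy = as.integer(dys[best]),
         peakNcc = peak, ok = peak >= cfg@confidenceFloor)
}

#' Estimate global translation parameters from a section's tiles
#'
#' Runs [estimatePairShift()] over a sampling plan of adjacent tile pairs
#' and aggregates each direction by the median over the confident pairs —
#' robust to up to half the pairs being corrupted. Since the stage
#' displacements are consistent across sections and scans, one estimate
#' (from a texture-rich section) serves the whole acquisition series.
#'
#' @param tiles list of [Tile-class] objects or matrices in raster order
#'   (row-major: index `row * tilesPerRow + col + 1`).
#' @param tilesPerCol,tilesPerRow tile grid shape (rows, columns).
#' @param cfg a [StripConfig-class] for horizontal pairs.
#' @param cfgVertical a [StripConfig-class] for vertical pairs (defaults to
#'   `cfg`; the two axes may have different overlaps).
#' @param nominalOverlapPx nominal overlap for tie-breaking.
#' @param pairs optional data.frame with columns `row`, `col`, `direction`
#'   selecting the leading tile of each pair; default is every adjacent
#'   pair in the grid.
#' @return A [TranslationParams-class].
#' @export
estimateTranslationParams <- function(tiles, tilesPerCol, tilesPerRow,
                                      cfg = stripConfig(), cfgVertical = cfg,
                                      nominalOverlapPx = 100L, pairs = NULL) {
    stopIfNot(length(tiles) == tilesPerCol * tilesPerRow,
              "tiles must cover the full grid in raster order")
    at <- function(r, c) tiles[[r * tilesPerRow + c + 1]]
    if (is.null(pairs)) {
        pairs <- data.frame(row = integer(), col = integer(), direction = character())
        for (r in seq_len(tilesPerCol) - 1L) for (c in seq_len(tilesPerRow) - 1L) {
            if (c < tilesPerRow - 1)
                pairs <- rbind(pairs, data.frame(row = r, col = c, direction = "horizontal"))
            if (r < tilesPerCol - 1)
                pairs <- rbind(pairs, data.frame(row = r, col = c, direction = "vertical"))
        }
    }
    hx <- integer(); hy <- integer(); vx <- integer(); vy <- integer()
    peaks <- numeric()
    for (k in seq_len(nrow(pairs))) {
        r <- pairs$row[k]; c <- pairs$col[k]; dir <- pairs$direction[k]
        lead <- at(r, c)
        trail <- if (dir == "horizontal") at(r, c + 1) else at(r + 1, c)
        est <- estimatePairShift(lead, trail, dir,
                                 if (dir == "horizontal") cfg else cfgVertical,
                                 nominalOverlapPx)
        if (!est$ok) next
        peaks <- c(peaks, est$peakNcc)
        if (dir == "horizontal") { hx <- c(hx, est$dx); hy <- c(hy, est$dy) }
        else { vx <- c(vx, est$dx); vy <- c(vy, est$dy) }
    }
    if (length(hx) == 0)
        stop("no confident horizontal pairs; try a different (more textured) section",
             call. = FALSE)
    if (length(vy) == 0 && tilesPerCol > 1)
        stop("no confident vertical pairs; try a different (more textured) section",
             call. = FALSE)
    translationParams(
        stepXPx = as.integer(round(stats::median(hx))),
        stepYPx = if (length(vy)) as.integer(round(stats::median(vy)))
                  else as.integer(round(stats::median(hx))),
        dyAtHorizontalPx = as.integer(round(stats::median(hy))),
        dxAtVerticalPx = if (length(vx)) as.integer(round(stats::median(vx))) else 0L,
        nPairsUsed = length(peaks), meanNcc = mean(peaks))
}

#' Serialize translation parameters to JSON
#'
#' @param params a [TranslationParams-class].
#' @param path JSON file path.
#' @return The path (save) or the restored object (load).
#' @export
saveTranslationParams <- function(params, path) {
    jsonWrite(list(step_x_px = params@stepXPx, step_y_px = params@stepYPx,
                   dy_at_horizontal_px = params@dyAtHorizontalPx,
                   dx_at_vertical_px = params@dxAtVerticalPx,
                   n_pairs_used = params@nPairsUsed,
                   mean_ncc = params@meanNcc), path)
}

#' @rdname saveTranslationParams
#' @export
loadTranslationParams <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    translationParams(stepXPx = j$step_x_px, stepYPx = j$step_y_px,
                      dyAtHorizontalPx = j$dy_at_horizontal_px,
                      dxAtVerticalPx = j$dx_at_vertical_px,
                      nPairsUsed = j$n_pairs_used, meanNcc = j$mean_ncc)
}
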