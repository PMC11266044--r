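## Internal numeric helpers shared across modules.

#' @importFrom stats spline rnorm runif rpois median quantile
NULL

## Evaluate an expression under a temporary RNG seed, restoring global state.
withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

isCount <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x == round(x)

## Bilinear sampling of `img` at fractional (y, x) positions (1-based),
## out-of-range coordinates clamped to the nearest edge pixel.
bilinearSample <- function(img, y, x) {
    h <- nrow(img); w <- ncol(img)
    y <- pmin(pmax(as.vector(y), 1), h)
    x <- pmin(pmax(as.vector(x), 1), w)
    y0 <- floor(y); x0 <- floor(x)
    y0 <- pmin(y0, h - 1L); x0 <- pmin(x0, w - 1L)
    y0[h == 1] <- 1; x0[w == 1] <- 1
    fy <- y - y0; fx <- x - x0
    y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
    v00 <- img[cbind(y0, x0)]; v01 <- img[cbind(y0, x1)]
    v10 <- img[cbind(y1, x0)]; v11 <- img[cbind(y1, x1)]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

## Natural bicubic interpolation of a node-value matrix V over its index grid.
## Queries (u, v) are fractional (row, col) indices into V, clamped to the
## grid hull; evaluation is separable (columns first, then rows).
bicubicAt <- function(V, u, v) {
    n <- nrow(V); m <- ncol(V)
    u <- pmin(pmax(u, 1), n)
    v <- pmin(pmax(v, 1), m)
    if (m == 1) {
        if (n == 1) return(rep(V[1, 1], length(u)))
        return(spline(seq_len(n), V[, 1], method = "natural", xout = u)$y)
    }
    q <- length(u)
    rowVals <- matrix(0, n, q)
    for (i in seq_len(n))
        rowVals[i, ] <- spline(seq_len(m), V[i, ], method = "natural", xout = v)$y
    if (n == 1) return(rowVals[1, ])
    out <- numeric(q)
    for (k in seq_len(q))
        out[k] <- spline(seq_len(n), rowVals[, k], method = "natural", xout = u[k])$y
    out
}

## Dense separable bicubic evaluation on a full query grid (uGrid x vGrid).
## Returns a length(uGrid) x length(vGrid) matrix.
bicubicGrid <- function(V, uGrid, vGrid) {
    n <- nrow(V); m <- ncol(V)
    uGrid <- pmin(pmax(uGrid, 1), n)
    vGrid <- pmin(pmax(vGrid, 1), m)
    if (m == 1) {
        col1 <- if (n == 1) rep(V[1, 1], length(uGrid))
                else spline(seq_len(n), V[, 1], method = "natural", xout = uGrid)$y
        return(matrix(col1, length(uGrid), length(vGrid)))
    }
    tmp <- matrix(0, n, length(vGrid))
    for (i in seq_len(n))
        tmp[i, ] <- spline(seq_len(m), V[i, ], method = "natural", xout = vGrid)$y
    if (n == 1)
        return(matrix(tmp[1, ], length(uGrid), length(vGrid), byrow = TRUE))
    out <- matrix(0, length(uGrid), length(vGrid))
    for (j in seq_along(vGrid))
        out[, j] <- spline(seq_len(n), tmp[, j], method = "natural", xout = uGrid)$y
    out
}

## 16-bit grayscale TIFF I/O used for tiles and stitched sections.
writeImageTiff <- function(pixels, path, bits = 16L) {
    maxv <- 2^bits - 1
    m <- round(pixels)
    m[m < 0] <- 0
    m[m > maxv] <- maxv
    tiff::writeTIFF(m / maxv, path, bits.per.sample = as.integer(bits))
    invisible(path)
}

readImageTiff <- function(path) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    storage.mode(m) <- "double"
    m
}

jsonWrite <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
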