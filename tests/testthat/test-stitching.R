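test_that("tile positions follow the placement arithmetic", {
    ## 1 x 1 grid, margin 0 -> single placement at the origin
    s1 <- sectionMetadata(0, 64, 64, 1, 1, 64, 64)
    p1 <- computeTilePositions(s1, translationParams(50, 50))
    expect_equal(nrow(p1), 1)
    expect_equal(c(p1$y0, p1$x0), c(0, 0))

    ## 2 x 2 grid, steps (788, 800), no drift
    s2 <- sectionMetadata(0, 832 + 788, 832 + 800, 2, 2, 832, 832)
    p2 <- computeTilePositions(s2, translationParams(800, 788))
    expect_equal(sort(unique(p2$y0)), c(0, 788))
    expect_equal(sort(unique(p2$x0)), c(0, 800))

    ## whole-brain geometry: 11 x 14 tiles of 832 px, steps (788, 800),
    ## margin 2 per side -> the printed 8,716 x 11,236 canvas, all 154
    ## placements inside, the farthest tile flush with the canvas edge
    s3 <- sectionMetadata(0, 8716, 11236, 14, 11, 832, 832, marginPx = 2)
    p3 <- computeTilePositions(s3, translationParams(800, 788))
    expect_equal(nrow(p3), 154)
    expect_true(all(p3$y0 >= 0 & p3$x0 >= 0))
    expect_true(all(p3$y0 + 832 <= 8716 & p3$x0 + 832 <= 11236))
    expect_equal(max(p3$y0) + 832 + 2, 8716)
    expect_equal(max(p3$x0) + 832 + 2, 11236)

    ## drifts shear the placements
    s4 <- sectionMetadata(0, 832 + 788 + 4, 832 + 800 + 4, 2, 2, 832, 832,
                          marginPx = 2)
    p4 <- computeTilePositions(s4, translationParams(800, 788,
                                                     dyAtHorizontalPx = -1,
                                                     dxAtVerticalPx = 2))
    expect_equal(p4$y0[p4$row == 0 & p4$col == 1], 2 - 1)   # margin + dy_h
    expect_equal(p4$x0[p4$row == 1 & p4$col == 0], 2 + 2)   # margin + dx_v

    ## canvas metadata disagreement warns; overflow errors
    expect_warning(computeTilePositions(
        sectionMetadata(0, 2000, 2000, 2, 2, 832, 832),
        translationParams(800, 788)), "canvas")
    expect_error(suppressWarnings(computeTilePositions(
        sectionMetadata(0, 900, 900, 2, 2, 832, 832),
        translationParams(800, 788))), "exceeds")
})

test_that("stitching blends convexly and reconstructs sliced phantoms", {
    ## two overlapping constant tiles -> overlap is exactly the constant
    tiles <- list(matrix(100, 64, 64), matrix(100, 64, 64))
    pl <- data.frame(row = c(0, 0), col = c(0, 1), y0 = c(0, 0), x0 = c(0, 40))
    for (blend in c("feather", "mean")) {
        out <- pixels(stitchSection(tiles, pl, c(64, 104), blend = blend))
        expect_lt(max(abs(out - 100)), 1e-9)
    }

    ## single tile on a larger canvas: values at the placement, zeros outside
    single <- pixels(stitchSection(list(matrix(7, 32, 32)),
                                   data.frame(row = 0, col = 0, y0 = 10, x0 = 20),
                                   c(64, 64)))
    expect_true(all(single[11:42, 21:52] == 7))
    expect_true(all(single[1:10, ] == 0))

    ## slice -> restitch at ground truth reproduces the phantom (float path)
    ph <- pixels(generatePhantomSection(phantomSpec(500, 560, cellDensity = 300,
                                                    seed = 3)))
    sl <- sliceIntoTiles(ph, 2, 2, 180, 200, 256, 256)
    for (blend in c("feather", "mean")) {
        sec <- pixels(stitchSection(sl$tiles, sl$positions, c(436, 456),
                                    blend = blend))
        expect_lte(max(abs(sec - ph[1:436, 1:456])), 1e-6)
    }

    ## convexity: blended values stay within the covering tiles' range
    set.seed(44)
    a <- matrix(runif(64 * 64, 0, 100), 64, 64)
    b <- matrix(runif(64 * 64, 50, 200), 64, 64)
    out <- pixels(stitchSection(list(a, b), pl, c(64, 104)))
    ov <- out[, 41:64]
    lo <- pmin(a[, 41:64], b[, 1:24]); hi <- pmax(a[, 41:64], b[, 1:24])
    expect_true(all(ov >= lo - 1e-9 & ov <= hi + 1e-9))

    expect_error(stitchSection(tiles[1], pl, c(64, 104)), "placement")
})

test_that("feathering keeps seams no sharper than the image content", {
    ## smooth phantom with a brightness step between the tiles' acquisitions
    ## would show a seam under naive pasting; with feathering the cross-seam
    ## first difference stays within 2x the intra-tile first difference
    y <- matrix(seq(0, 1, length.out = 300), 300, 300)
    x <- matrix(seq(0, 1, length.out = 300), 300, 300, byrow = TRUE)
    smooth <- 1000 + 4000 * (sin(4 * y) + cos(3 * x))
    sl <- sliceIntoTiles(smooth, 1, 2, 100, 120, 300, 180)
    ## perturb one tile by a small multiplicative illumination mismatch
    sl$tiles[[2]]@pixels <- sl$tiles[[2]]@pixels * 1.02
    sec <- pixels(stitchSection(sl$tiles, sl$positions, c(300, 300),
                                blend = "feather"))
    dx <- abs(sec[, -1] - sec[, -300])
    ## overlap spans columns 121-180; compare against gradients away from it
    intra <- max(dx[, setdiff(seq_len(299), 115:185)])
    expect_lte(max(dx), 2 * intra)
})

test_that("section writing clips, counts and round-trips", {
    img <- matrix(c(-5, 100.4, 70000, 42), 2, 2)
    f <- withr::local_tempfile(fileext = ".tif")
    res <- writeSection(sectionImage(img), f)
    expect_equal(res$clippedPixels, 2)   # -5 below, 70000 above
    back <- readSection(f)
    expect_equal(dim(back), c(2, 2))
    expect_equal(back[1, 1], 0)          # clipped low
    expect_equal(back[1, 2], 65535)      # clipped high
    expect_equal(back[2, 1], 100)        # rounded
    expect_equal(back[2, 2], 42)

    ## rescale multiplies before conversion
    f2 <- withr::local_tempfile(fileext = ".tif")
    writeSection(matrix(0.5, 4, 4), f2, rescale = 2000)
    expect_true(all(readSection(f2) == 1000))
})
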