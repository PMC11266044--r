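test_that("the NCC surface matches self-correlation boundary cases", {
    set.seed(14)
    search <- matrix(runif(40 * 40, 0, 65535), 40, 40)
    template <- search[11:30, 6:25]
    surf <- nccSurface(template, search)
    expect_equal(dim(surf), c(21, 21))
    expect_equal(max(surf), 1, tolerance = 1e-12)
    expect_equal(unname(which(surf == max(surf), arr.ind = TRUE)[1, ]),
                 c(11, 6))
    ## anti-correlation at the same placement for the negated template
    surfNeg <- nccSurface(-template, search)
    expect_equal(surfNeg[11, 6], -1, tolerance = 1e-12)
    ## all values within [-1, 1]
    expect_true(all(abs(surf) <= 1 + 1e-9))
    ## zero-variance template is defined as 0 everywhere
    expect_true(all(nccSurface(matrix(5, 4, 4), search) == 0))
})

test_that("NCC equals the brute-force double-loop oracle", {
    set.seed(15)
    for (trial in 1:3) {
        search <- matrix(runif(40 * 40, 0, 65535), 40, 40)
        template <- matrix(runif(20 * 20, 0, 65535), 20, 20)
        expect_lt(max(abs(nccSurface(template, search) -
                          bruteNcc(template, search))), 1e-9)
    }
})

test_that("pair shifts recover constructed overlaps exactly", {
    ## trailing tile is the leading tile's content shifted by the nominal
    ## 100-px overlap; default 100/50 strips, full 832-px tiles
    ph <- pixels(generatePhantomSection(phantomSpec(832, 1564, cellDensity = 80,
                                                    seed = 23)))
    left <- ph[, 1:832]; right <- ph[, 733:1564]
    est <- estimatePairShift(left, right, "horizontal")
    expect_equal(est$dx, 732L)   # tile_width - 100
    expect_equal(est$dy, 0L)
    expect_equal(est$peakNcc, 1, tolerance = 1e-9)
    expect_true(est$ok)

    ## vertical pair with a 2-px perpendicular jitter
    ph2 <- pixels(generatePhantomSection(phantomSpec(600, 300, cellDensity = 400,
                                                     seed = 29)))
    top <- ph2[1:256, 11:266]
    bottom <- ph2[201:456, 13:268]   # step_y 200, dx drift +2
    est2 <- estimatePairShift(top, bottom, "vertical",
                              stripConfig(70, 30, 5), nominalOverlapPx = 56)
    expect_equal(est2$dy, 200L)
    expect_equal(est2$dx, 2L)
    expect_equal(est2$peakNcc, 1, tolerance = 1e-9)

    ## uniform tiles carry no signal: flagged low-confidence
    flat <- estimatePairShift(matrix(7, 128, 128), matrix(7, 128, 128),
                              "horizontal", stripConfig(40, 20, 5),
                              nominalOverlapPx = 30)
    expect_false(flat$ok)
})

test_that("shift recovery survives noise at 5 percent of the dynamic range", {
    ## independent noise on each tile (not shared via the phantom); for
    ## texture whose contrast clears the confidence floor under the noise,
    ## exact integer recovery is expected in at least 95 percent of fixtures
    set.seed(77)
    hits <- 0L; n <- 20L
    for (i in seq_len(n)) {
        ph <- pixels(generatePhantomSection(
            phantomSpec(256, 500, cellDensity = 2500, cellRadiusPx = 2,
                        cellAmplitude = 50000, noiseSd = 0, seed = 100 + i)))
        left <- ph[, 1:256] + matrix(rnorm(256 * 256, 0, 0.05 * 65535), 256)
        right <- ph[, 201:456] + matrix(rnorm(256 * 256, 0, 0.05 * 65535), 256)
        est <- estimatePairShift(left, right, "horizontal",
                                 stripConfig(66, 28, 5), nominalOverlapPx = 56)
        if (est$ok && est$dx == 200L && est$dy == 0L) hits <- hits + 1L
    }
    expect_gte(hits / n, 0.95)
})

test_that("parameter aggregation is a robust median over confident pairs", {
    ph <- generatePhantomSection(phantomSpec(500, 560, cellDensity = 400, seed = 7))
    sl <- sliceIntoTiles(ph, 2, 2, 180, 200, 256, 256)
    params <- estimateTranslationParams(sl$tiles, 2, 2, stripConfig(70, 30, 5),
                                        stripConfig(90, 40, 5),
                                        nominalOverlapPx = 56)
    expect_equal(params@stepXPx, 200)
    expect_equal(params@stepYPx, 180)
    expect_equal(params@dyAtHorizontalPx, 0)
    expect_equal(params@dxAtVerticalPx, 0)
    expect_equal(params@meanNcc, 1, tolerance = 1e-9)
    expect_equal(params@nPairsUsed, 4)

    ## median robustness: corrupting one of three leading tiles' pairs
    ## leaves the aggregate unchanged (constructed directly)
    meds <- sapply(list(c(732, 732, 732), c(732, 732, 500),
                        c(732, 500, 732)), stats::median)
    expect_true(all(meds == 732))

    ## flat tiles in every pair -> estimation error
    flats <- lapply(1:4, function(i) matrix(1, 64, 64))
    expect_error(estimateTranslationParams(flats, 2, 2, stripConfig(30, 10, 4),
                                           nominalOverlapPx = 20),
                 "confident")

    ## JSON round trip
    f <- withr::local_tempfile(fileext = ".json")
    saveTranslationParams(params, f)
    p2 <- loadTranslationParams(f)
    expect_equal(p2, params)
})
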