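test_that("phantom generation is deterministic and honors its spec", {
    ## no cells, no noise -> constant background
    flat <- generatePhantomSection(phantomSpec(50, 60, cellDensity = 0,
                                               noiseSd = 0, backgroundLevel = 100))
    expect_equal(dim(pixels(flat)), c(50, 60))
    expect_true(all(pixels(flat) == 100))

    ## determinism: same spec twice -> bit-identical
    s <- phantomSpec(120, 150, seed = 42)
    expect_identical(pixels(generatePhantomSection(s)),
                     pixels(generatePhantomSection(s)))

    ## cell count reproduces the documented sampling procedure
    big <- generatePhantomSection(phantomSpec(1000, 1000, cellDensity = 50, seed = 7))
    expected <- local({
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(7)
        rpois(1, 50 * 1000 * 1000 / 1e6)
    })
    expect_identical(big@provenance$nCells, expected)

    expect_error(generatePhantomSection(phantomSpec(0, 10)), "positive")
})

test_that("vignette gain hits its boundary values and is radially monotone", {
    ## flat field
    expect_true(all(makeVignetteGain(vignetteModel(64, 64, 1, 1)) == 1))

    ## corner pixel carries the edge gain exactly (both shapes)
    for (shape in c("radial_quadratic", "radial_gaussian")) {
        g <- makeVignetteGain(vignetteModel(101, 101, centerGain = 1,
                                            edgeGain = 0.5, profileShape = shape))
        expect_equal(g[1, 1], 0.5, tolerance = 1e-9)
        expect_equal(g[101, 101], 0.5, tolerance = 1e-9)
        expect_equal(g[51, 51], 1)
        ## brute-force scan of the whole image
        expect_equal(min(g), 0.5, tolerance = 1e-9)
        expect_equal(max(g), 1, tolerance = 1e-9)
        expect_true(all(g > 0 & g <= 1))
        ## radial monotonicity along the main diagonal toward the corner
        diagVals <- g[cbind(51:101, 51:101)]
        expect_true(all(diff(diagVals) <= 1e-12))
    }

    expect_error(vignetteModel(64, 64, centerGain = 0.5, edgeGain = 0.9),
                 "edgeGain")
})

test_that("slicing produces exact crops with identical overlap strips", {
    ph <- generatePhantomSection(phantomSpec(400, 400, cellDensity = 300, seed = 1))
    img <- pixels(ph)

    ## 1 x 1 layout is the identity crop
    one <- sliceIntoTiles(img, 1, 1, 100, 100, 300, 300)
    expect_identical(one$tiles[[1]]@pixels, img[1:300, 1:300])
    expect_equal(one$positions$y0, 0)

    ## adjacent tiles share an identical strip as wide as the overlap
    sl <- sliceIntoTiles(img, 2, 2, 150, 140, 250, 250)
    left <- sl$tiles[[1]]@pixels; right <- sl$tiles[[2]]@pixels
    expect_identical(left[, 141:250], right[, 1:110])
    top <- sl$tiles[[1]]@pixels; bottom <- sl$tiles[[3]]@pixels
    expect_identical(top[151:250, ], bottom[1:100, ])

    ## gain-only slicing: dividing by the gain reconstructs the crop
    gm <- makeVignetteGain(vignetteModel(250, 250, edgeGain = 0.6))
    slg <- sliceIntoTiles(img, 2, 2, 150, 140, 250, 250, gain = gm)
    for (k in seq_along(slg$tiles)) {
        p <- slg$positions[k, ]
        crop <- img[(p$y0 + 1):(p$y0 + 250), (p$x0 + 1):(p$x0 + 250)]
        expect_lt(max(abs(slg$tiles[[k]]@pixels / gm - crop)), 1e-6)
    }

    expect_error(sliceIntoTiles(img, 3, 3, 150, 150, 250, 250), "bounds")
    expect_error(sliceIntoTiles(img, 2, 2, 260, 150, 250, 250), "overlap")
})

test_that("synthetic warps are bounded, smooth and deterministic", {
    w <- makeSyntheticWarp(200, 220, amplitudePx = 3, smoothnessScalePx = 50,
                           seed = 9)
    mag <- sqrt(w@dy^2 + w@dx^2)
    expect_lte(max(mag), 3 + 1e-9)
    expect_equal(max(mag), 3, tolerance = 1e-12)  # rescaled to the amplitude
    ## smoothness: finite differences on the order of amplitude / scale
    expect_lt(max(abs(diff(w@dy))), 3 / 50 * 3)
    w2 <- makeSyntheticWarp(200, 220, 3, 50, seed = 9)
    expect_identical(w@dy, w2@dy)

    ## zero amplitude -> warpImage is a no-op
    w0 <- makeSyntheticWarp(60, 60, 0, 30, seed = 1)
    img <- matrix(runif(3600), 60, 60)
    expect_equal(warpImage(img, w0), img)
})

test_that("grid images carry an exact analytic corner lattice", {
    g <- generateGridImage(20, 4, 200, 200)
    expect_equal(dim(g$corners@y), c(9, 9))
    expect_equal(g$corners@y[, 1], seq(20, 180, by = 20))
    expect_equal(g$corners@x[1, ], seq(20, 180, by = 20))

    ## warped truth equals unwarped corner plus the displacement at the
    ## warped location (fixed point of p = q + d(p))
    w <- makeSyntheticWarp(200, 200, 3, 60, seed = 3)
    gw <- generateGridImage(20, 4, 200, 200, warp = w)
    q <- list(y = as.vector(g$corners@y), x = as.vector(g$corners@x))
    ## independent fixed-point solve against the dense displacement maps
    py <- q$y; px <- q$x
    for (it in 1:60) {
        iy <- pmin(pmax(py + 1, 1), 200); ix <- pmin(pmax(px + 1, 1), 200)
        y0 <- pmin(floor(iy), 199); x0 <- pmin(floor(ix), 199)
        fy <- iy - y0; fx <- ix - x0
        g00 <- cbind(y0, x0); g01 <- cbind(y0, x0 + 1)
        g10 <- cbind(y0 + 1, x0); g11 <- cbind(y0 + 1, x0 + 1)
        dy <- (1 - fy) * ((1 - fx) * w@dy[g00] + fx * w@dy[g01]) +
              fy * ((1 - fx) * w@dy[g10] + fx * w@dy[g11])
        dx <- (1 - fy) * ((1 - fx) * w@dx[g00] + fx * w@dx[g01]) +
              fy * ((1 - fx) * w@dx[g10] + fx * w@dx[g11])
        py <- q$y + dy; px <- q$x + dx
    }
    expect_equal(as.vector(gw$corners@y), py, tolerance = 1e-6)
    expect_equal(as.vector(gw$corners@x), px, tolerance = 1e-6)

    ## hole pixel fraction by brute-force count: pure-hole pixels (outside
    ## the 1-px antialias ramp) occupy exactly ((pitch - bar - 1) / pitch)^2,
    ## approximating the analytic hole-area ratio ((pitch - bar) / pitch)^2
    fracPure <- mean(g$image == 45000)
    expect_equal(fracPure, ((20 - 4 - 1) / 20)^2)
    expect_equal(fracPure, ((20 - 4) / 20)^2, tolerance = 0.15)

    expect_error(generateGridImage(10, 12, 100, 100), "bar")
})

test_that("fixture trees enumerate completely and round-trip", {
    root <- withr::local_tempdir()
    fx <- makeSmallBrain(root, nSections = 2, channels = c("a", "b", "c", "d"))
    files <- list.files(file.path(root, "TB01", "0000"))
    expect_equal(sum(grepl("\\.tif$", files)), 16)  # 2x2 grid x 4 channels
    expect_equal(length(list.files(file.path(root, "TB01"),
                                   pattern = "^\\d{4}$")), 2)
    rec <- enumerateTiles(root, fx$meta)
    expect_equal(nrow(rec), 32)
    expect_false(any(rec$missing))
})
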