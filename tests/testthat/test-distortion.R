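test_that("grid corners are detected at the analytic lattice", {
    g <- generateGridImage(20, 4, 200, 200)
    det <- detectGridCorners(g$image, 20)
    expect_equal(dim(det@y), dim(g$corners@y))
    expect_lt(max(abs(det@y - g$corners@y)), 0.5)
    expect_lt(max(abs(det@x - g$corners@x)), 0.5)

    ## partial border cells are excluded: shrinking the image cuts the last
    ## hole column/row, so the corner lattice loses one column and row
    gSmall <- generateGridImage(20, 4, 195, 195)
    detSmall <- detectGridCorners(gSmall$image, 20)
    expect_equal(dim(detSmall@y), dim(det@y) - c(1, 1))

    ## warped grid: corners within 1 px RMS of the fixture's truth (the warp
    ## can push border holes out, so match each detection to its nearest
    ## true corner)
    w <- makeSyntheticWarp(200, 200, 3, 70, seed = 21)
    gw <- generateGridImage(20, 4, 200, 200, warp = w)
    dw <- detectGridCorners(gw$image, 20)
    expect_gte(length(dw@y), 36)
    d2 <- vapply(seq_along(dw@y), function(k)
        min((dw@y[k] - gw$corners@y)^2 + (dw@x[k] - gw$corners@x)^2),
        numeric(1))
    expect_lt(sqrt(mean(d2)), 1)
    expect_lt(sqrt(max(d2)), 1)

    expect_error(detectGridCorners(matrix(0, 50, 50), 20), "calibration")
})

test_that("template lattices are exactly regular", {
    t3 <- buildTemplateLattice(3, 3, 10, origin = c(0, 0))
    expect_equal(t3@y[, 1], c(0, 10, 20))
    expect_equal(t3@x[1, ], c(0, 10, 20))
    expect_true(all(diff(t3@y[, 2]) == 10))
    expect_identical(t3@source, "template")

    g <- generateGridImage(20, 4, 200, 200)
    det <- detectGridCorners(g$image, 20)
    tmpl <- templateLatticeFor(det, 20)
    expect_equal(dim(tmpl@y), dim(det@y))
    expect_equal(diff(tmpl@y[, 1])[1], 20)
})

test_that("homography fitting recovers exact projective relations", {
    lat <- buildTemplateLattice(5, 5, 25, origin = c(10, 15))
    ## identity
    h <- fitHomography(lat, lat)
    expect_equal(homographyMatrix(h), diag(3), tolerance = 1e-9)
    ## pure translation
    shifted <- new("CornerLattice", y = lat@y + 5, x = lat@x - 3,
                   source = "truth")
    ht <- fitHomography(lat, shifted)
    expect_equal(homographyMatrix(ht)[1, 3], 5, tolerance = 1e-8)
    expect_equal(homographyMatrix(ht)[2, 3], -3, tolerance = 1e-8)
    expect_equal(homographyMatrix(ht)[1:2, 1:2], diag(2), tolerance = 1e-8)
    ## synthesize-and-recover: random invertible projective map
    set.seed(5)
    M <- diag(3) + matrix(rnorm(9, 0, 0.01), 3, 3)
    M[3, 3] <- 1
    p <- applyHomographyPoints(M / M[3, 3], as.vector(lat@y), as.vector(lat@x))
    dst <- new("CornerLattice", y = matrix(p$y, 5, 5), x = matrix(p$x, 5, 5),
               source = "truth")
    hr <- fitHomography(lat, dst)
    expect_equal(homographyMatrix(hr), M / M[3, 3], tolerance = 1e-6)
    ## residual on exact data is at numerical precision
    back <- applyHomographyPoints(hr, as.vector(lat@y), as.vector(lat@x))
    expect_lt(max(abs(back$y - p$y), abs(back$x - p$x)), 1e-6)
    ## collinear points are rejected
    line <- new("CornerLattice", y = matrix(1:8, 4, 2),
                x = matrix(2 * (1:8), 4, 2), source = "truth")
    expect_error(fitHomography(line, line), "degenerate")
})

test_that("the residual spline interpolates node displacements exactly", {
    tmpl <- buildTemplateLattice(6, 6, 30, origin = c(5, 5))
    ## projected == template -> zero field
    z <- fitResidualSpline(tmpl, tmpl)
    ev <- evalResidualField(z, c(5, 50, 100), c(5, 42, 99))
    expect_true(all(ev$dy == 0) && all(ev$dx == 0))

    ## node exactness for an arbitrary displacement pattern
    set.seed(12)
    proj <- new("CornerLattice", y = tmpl@y + matrix(rnorm(36, 0, 2), 6, 6),
                x = tmpl@x + matrix(rnorm(36, 0, 2), 6, 6), source = "truth")
    f <- fitResidualSpline(proj, tmpl)
    ev <- evalResidualField(f, as.vector(tmpl@y), as.vector(tmpl@x))
    expect_equal(matrix(ev$dy, 6, 6), tmpl@y - proj@y, tolerance = 1e-10)
    expect_equal(matrix(ev$dx, 6, 6), tmpl@x - proj@x, tolerance = 1e-10)

    ## a smooth warp sampled at the nodes is recovered mid-cell to 0.25 px
    w <- makeSyntheticWarp(200, 200, 3, 120, seed = 4)
    nodeY <- seq(10, 170, by = 40); nodeX <- seq(10, 170, by = 40)
    tmpl2 <- buildTemplateLattice(length(nodeY), length(nodeX), 40,
                                  origin = c(10, 10))
    dyN <- matrix(BrainMosaic:::bilinearSample(w@dy, rep(nodeY, length(nodeX)) + 1,
                  rep(nodeX, each = length(nodeY)) + 1), length(nodeY))
    dxN <- matrix(BrainMosaic:::bilinearSample(w@dx, rep(nodeY, length(nodeX)) + 1,
                  rep(nodeX, each = length(nodeY)) + 1), length(nodeY))
    proj2 <- new("CornerLattice", y = tmpl2@y - dyN, x = tmpl2@x - dxN,
                 source = "truth")
    f2 <- fitResidualSpline(proj2, tmpl2)
    midY <- seq(30, 150, by = 40); midX <- seq(30, 150, by = 40)
    qy <- rep(midY, length(midX)); qx <- rep(midX, each = length(midY))
    ev2 <- evalResidualField(f2, qy, qx)
    trueDy <- BrainMosaic:::bilinearSample(w@dy, qy + 1, qx + 1)
    trueDx <- BrainMosaic:::bilinearSample(w@dx, qy + 1, qx + 1)
    expect_lt(max(abs(ev2$dy - trueDy)), 0.25)
    expect_lt(max(abs(ev2$dx - trueDx)), 0.25)

    expect_error(fitResidualSpline(tmpl, buildTemplateLattice(3, 3, 10)),
                 "shapes")
})

test_that("the correction lookup is exact for the identity and serializes bit-exactly", {
    tmpl <- buildTemplateLattice(4, 4, 20, origin = c(0, 0))
    res <- fitResidualSpline(tmpl, tmpl)
    idH <- new("Homography", mat = diag(3))
    m <- buildCorrectionLut(idH, res, c(64, 64))
    expect_true(all(m@lutY == matrix(seq_len(64), 64, 64)))
    expect_true(all(m@lutX == matrix(seq_len(64), 64, 64, byrow = TRUE)))

    g <- generateGridImage(20, 4, 200, 200,
                           warp = makeSyntheticWarp(200, 200, 3, 70, seed = 2))
    model <- calibrateDeformation(g$image, 20)
    f <- withr::local_tempfile()
    saveDeformationModel(model, f)
    m2 <- loadDeformationModel(f)
    expect_identical(m2@lutY, model@lutY)
    expect_identical(m2@lutX, model@lutX)
    expect_identical(m2@homography@mat, model@homography@mat)
    expect_identical(m2@tileShape, model@tileShape)
})

test_that("calibration corrects a warped grid to sub-half-pixel corner error", {
    w <- makeSyntheticWarp(200, 200, 4, 70, seed = 13)
    g <- generateGridImage(20, 4, 200, 200, warp = w)
    model <- calibrateDeformation(g$image, 20)
    corrected <- applyCorrection(g$image, model)
    det <- detectGridCorners(corrected, 20)
    tmpl <- templateLatticeFor(detectGridCorners(g$image, 20), 20)
    ## correction can cut or reveal border cells, so measure against the
    ## ideal grid extended periodically
    expect_gte(length(det@y), 30)
    expect_lte(latticeRmsToTemplate(det, tmpl), 0.5)

    ## reusability: recalibrating from the same grid gives identical results
    model2 <- calibrateDeformation(g$image, 20)
    expect_identical(model2@lutY, model@lutY)
    ph <- matrix(runif(200 * 200, 0, 60000), 200, 200)
    expect_identical(applyCorrection(ph, model), applyCorrection(ph, model2))
})

test_that("applying a correction preserves constants and recovers warped phantoms", {
    w <- makeSyntheticWarp(200, 200, 3, 70, seed = 17)
    g <- generateGridImage(20, 4, 200, 200, warp = w)
    model <- calibrateDeformation(g$image, 20)

    ## identity model is a bit-exact no-op; constants stay constant
    idm <- identityDeformationModel(c(200, 200))
    img <- matrix(runif(200 * 200, 0, 65535), 200, 200)
    expect_identical(applyCorrection(img, idm), img)
    expect_true(all(applyCorrection(matrix(42, 200, 200), model) == 42))

    ## warp a phantom, correct with the model calibrated from the grid:
    ## interior mean error at most 1 percent of the dynamic range
    ph <- pixels(generatePhantomSection(phantomSpec(200, 200, cellDensity = 300,
                                                    seed = 6)))
    warped <- warpImage(ph, w)
    rec <- applyCorrection(warped, model)
    interior <- 6:195
    mae <- mean(abs(rec[interior, interior] - ph[interior, interior]))
    expect_lt(mae / 65535, 0.01)

    expect_error(applyCorrection(matrix(0, 10, 10), model), "shape")
})
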