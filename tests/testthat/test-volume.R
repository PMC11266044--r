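test_that("stacking orders sections by index, not arrival", {
    m <- lapply(1:3, function(i) matrix(i * 10, 100, 120))
    vol <- stackSections(m)
    expect_equal(dim(voxels(vol)), c(3, 100, 120))
    expect_equal(voxels(vol)[2, , ], m[[2]])
    expect_equal(spacingUm(vol), c(50, 1.25, 1.25))

    ## permuted SectionImage input gives the identical volume
    secs <- lapply(0:2, function(i) sectionImage(matrix(i, 10, 12),
                                                 sectionIndex = i))
    volA <- stackSections(secs)
    volB <- stackSections(secs[c(3, 1, 2)])
    expect_identical(voxels(volA), voxels(volB))

    ## shape mismatch names the section; gaps error unless allowed
    bad <- list(sectionImage(matrix(0, 5, 5), 0), sectionImage(matrix(0, 6, 5), 1))
    expect_error(stackSections(bad), "section 1")
    gap <- list(sectionImage(matrix(1, 5, 5), 0), sectionImage(matrix(1, 5, 5), 2))
    expect_error(stackSections(gap), "gap")
    volG <- stackSections(gap, allowGaps = TRUE)
    expect_equal(dim(voxels(volG))[1], 3)
    expect_true(all(voxels(volG)[2, , ] == 0))
})

test_that("NIfTI export carries the physical spacing and round-trips", {
    vol <- stackSections(lapply(1:3, function(i)
        matrix(sample(0:65535, 64 * 80, TRUE), 64, 80)))
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeNiftiVolume(vol, f)
    img <- RNifti::readNifti(f)
    ## header zooms in mm, (x, y, z) slots
    expect_equal(RNifti::pixdim(img), c(0.00125, 0.00125, 0.05),
                 tolerance = 1e-6)
    back <- readNiftiVolume(f)
    expect_equal(voxels(back), voxels(vol))
    expect_equal(spacingUm(back), c(50, 1.25, 1.25), tolerance = 1e-6)
    ## affine is the scaled identity: determinant = product of spacings
    aff <- RNifti::xform(img)
    expect_equal(det(aff[1:3, 1:3]), prod(c(0.00125, 0.00125, 0.05)),
                 tolerance = 1e-6)
})

test_that("block-mean downsampling matches the direct loop", {
    vol <- stackSections(lapply(1:2, function(i) matrix(i, 8, 8)))
    ## factor 1 everywhere is the identity
    same <- downsampleVolume(vol, c(50, 1.25, 1.25))
    expect_identical(voxels(same), voxels(vol))
    ## constants stay constant under any factor
    const <- downsampleVolume(vol, c(50, 5, 5))
    expect_true(all(voxels(const)[1, , ] == 1))
    expect_equal(spacingUm(const), c(50, 5, 5))

    ## checkerboard, factors (1, 2, 2): every output is its 2x2 block mean
    cb <- array(0, c(1, 4, 4))
    cb[1, , ] <- outer(1:4, 1:4, function(i, j) (i + j) %% 2) * 100
    volCb <- new("Volume", voxels = cb, spacingUm = c(1, 1, 1),
                 channel = "", brainId = "")
    ds <- downsampleVolume(volCb, c(1, 2, 2))
    manual <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2)
        manual[i, j] <- mean(cb[1, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    expect_equal(voxels(ds)[1, , ], manual)

    expect_error(downsampleVolume(vol, c(10, 1.25, 1.25)), "at least")
})

test_that("OME-Zarr stores a faithful multiscale pyramid", {
    set.seed(9)
    vox <- array(sample(0:65535, 4 * 64 * 48, TRUE), c(4, 64, 48))
    vox[1] <- 0; vox[2] <- 65535   # span the dtype range exactly
    vol <- new("Volume", voxels = vox, spacingUm = c(50, 1.25, 1.25),
               channel = "red", brainId = "ZT")
    store <- file.path(withr::local_tempdir(), "vol.zarr")
    writeOmeZarr(vol, store, nLevels = 3, chunkShape = c(1, 32, 32),
                 exposure = c(0, 100))

    ## exposure (0, 100) on range-spanning data is a no-op at level 0
    lv0 <- readOmeZarr(store, 0)
    expect_equal(voxels(lv0), vox)
    expect_equal(spacingUm(lv0), c(50, 1.25, 1.25))

    ## level shapes halve in y/x per level
    expect_equal(dim(voxels(readOmeZarr(store, 1))), c(4, 32, 24))
    expect_equal(dim(voxels(readOmeZarr(store, 2))), c(4, 16, 12))

    ## level 1 equals the direct 2x2 block mean of level 0 (then rounding)
    lv1 <- voxels(readOmeZarr(store, 1))
    manual <- array(0, c(4, 32, 24))
    for (z in 1:4) for (i in 1:32) for (j in 1:24)
        manual[z, i, j] <- round(mean(vox[z, (2 * i - 1):(2 * i),
                                          (2 * j - 1):(2 * j)]))
    expect_equal(lv1, manual)

    ## NGFF metadata: axes in micrometres, per-level scales
    attrs <- jsonlite::read_json(file.path(store, ".zattrs"))
    ms <- attrs$multiscales[[1]]
    expect_equal(ms$version, "0.4")
    expect_equal(vapply(ms$axes, `[[`, "", "name"), c("z", "y", "x"))
    expect_equal(unlist(ms$datasets[[2]]$coordinateTransformations[[1]]$scale),
                 c(50, 2.5, 2.5))

    ## raw-chunk zarr round trip on awkward (non-divisible) shapes
    arr <- array(stats::runif(5 * 7 * 11) * 65535, c(5, 7, 11))
    arr <- round(arr)
    d <- file.path(withr::local_tempdir(), "raw")
    zarrWriteArray(arr, d, chunkShape = c(2, 3, 4), dtype = "<u2")
    expect_equal(zarrReadArray(d), arr)
    d2 <- file.path(withr::local_tempdir(), "rawf")
    arrF <- array(stats::rnorm(60), c(3, 4, 5))
    zarrWriteArray(arrF, d2, chunkShape = c(2, 2, 2), dtype = "<f8")
    expect_identical(zarrReadArray(d2), arrF)
})

test_that("exposure rescale maps the stated percentiles onto the dtype range", {
    vox <- array(seq(1000, 2000, length.out = 3 * 20 * 20), c(3, 20, 20))
    vol <- new("Volume", voxels = vox, spacingUm = c(1, 1, 1),
               channel = "", brainId = "")
    store <- file.path(withr::local_tempdir(), "exp.zarr")
    writeOmeZarr(vol, store, nLevels = 1, exposure = c(0, 100))
    lv0 <- voxels(readOmeZarr(store, 0))
    expect_equal(min(lv0), 0)
    expect_equal(max(lv0), 65535)
    ## monotone: ordering of voxel values is preserved
    expect_true(all(diff(lv0[order(vox)]) >= 0))
})

test_that("viewer URLs are deterministic, well-formed and point at the store", {
    store <- file.path(withr::local_tempdir(), "u.zarr")
    vol <- new("Volume", voxels = array(0, c(1, 4, 4)),
               spacingUm = c(1, 1, 1), channel = "", brainId = "")
    writeOmeZarr(vol, store, nLevels = 1)
    u1 <- viewerUrl(store, host = "http://example.org:9000")
    u2 <- viewerUrl(store, host = "http://example.org:9000")
    expect_identical(u1, u2)
    expect_match(u1, "^https://[^#]+/#!")
    ## the fragment decodes to JSON whose layer source ends with the store
    state <- jsonlite::fromJSON(utils::URLdecode(sub("^[^!]*!", "", u1)),
                                simplifyVector = FALSE)
    src <- state$layers[[1]]$source
    expect_match(src, "^zarr://http://example.org:9000/")
    expect_true(endsWith(src, "u.zarr"))
    expect_error(viewerUrl(file.path(tempdir(), "absent.zarr")), "not found")
})
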