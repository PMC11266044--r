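#' Accessors
#'
#' Accessor generics for the core classes: `pixels()` returns the 2D
#' intensity matrix of a [Tile-class], [Profile-class] or
#' [SectionImage-class]; `voxels()` and `spacingUm()` the array and physical
#' spacing of a [Volume-class]; `channelNames()` the channel labels;
#' `brainId()` the acquisition identifier; `tilesPerSection()` and
#' `tilesPerChannel()` the per-section tile-file counts implied by the grid;
#' `latticePoints()` the (y, x) node coordinates of a [CornerLattice-class]
#' as an n x 2 matrix; `homographyMatrix()` the 3x3 matrix of a
#' [Homography-class].
#'
#' @param x the object.
#' @return See the description per generic.
#' @examples
#' meta <- brainVolumeMetadata("demo", nSections = 2)
#' tilesPerSection(meta)  # 11 * 14 * 4 = 616
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setMethod("pixels", "Tile", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "Profile", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "SectionImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setMethod("voxels", "Volume", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("spacingUm", function(x) standardGeneric("spacingUm"))

#' @rdname accessors
#' @export
setMethod("spacingUm", "Volume", function(x) x@spacingUm)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setMethod("channelNames", "BrainVolumeMetadata", function(x) x@channelNames)

#' @rdname accessors
#' @export
setGeneric("brainId", function(x) standardGeneric("brainId"))

#' @rdname accessors
#' @export
setMethod("brainId", "BrainVolumeMetadata", function(x) x@brainId)

#' @rdname accessors
#' @export
setMethod("brainId", "Volume", function(x) x@brainId)

#' @rdname accessors
#' @export
setGeneric("tilesPerSection", function(x) standardGeneric("tilesPerSection"))

#' @rdname accessors
#' @export
setMethod("tilesPerSection", "BrainVolumeMetadata", function(x)
    as.integer(x@tilesPerRow * x@tilesPerCol * x@nChannels))

#' @rdname accessors
#' @export
setGeneric("tilesPerChannel", function(x) standardGeneric("tilesPerChannel"))

#' @rdname accessors
#' @export
setMethod("tilesPerChannel", "BrainVolumeMetadata", function(x)
    as.integer(x@tilesPerRow * x@tilesPerCol))

#' @rdname accessors
#' @export
setGeneric("latticePoints", function(x) standardGeneric("latticePoints"))

#' @rdname accessors
#' @export
setMethod("latticePoints", "CornerLattice", function(x)
    cbind(y = as.vector(x@y), x = as.vector(x@x)))

#' @rdname accessors
#' @export
setGeneric("homographyMatrix", function(x) standardGeneric("homographyMatrix"))

#' @rdname accessors
#' @export
setMethod("homographyMatrix", "Homography", function(x) x@mat)
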