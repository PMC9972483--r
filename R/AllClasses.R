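#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t Diagonal
NULL

#' MultiplexImage: a multi-channel marker image
#'
#' Container for an H x W x B stack of marker channels (one channel per
#' fluorescent marker), intensities in `[0, 1]`.
#'
#' @slot data numeric array, H x W x B.
#' @slot markers character vector of B marker names.
#' @export
setClass("MultiplexImage",
  representation(data = "array", markers = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("data must be an H x W x B array")
    if (dim(d)[3] != length(object@markers))
      return("number of channels must match number of marker names")
    if (anyNA(d)) return("image contains NA values")
    TRUE
  })

#' @describeIn MultiplexImage Constructor.
#' @param data H x W x B numeric array.
#' @param markers character vector of marker names; defaults to Mk1..MkB.
#' @export
MultiplexImage <- function(data, markers = NULL) {
  if (is.null(markers)) markers <- paste0("Mk", seq_len(dim(data)[3]))
  new("MultiplexImage", data = data, markers = markers)
}

#' @describeIn MultiplexImage Extract the raw H x W x B array.
#' @param x a MultiplexImage.
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))
#' @rdname MultiplexImage-class
#' @aliases imageArray,MultiplexImage-method
setMethod("imageArray", "MultiplexImage", function(x) x@data)

#' @describeIn MultiplexImage Marker names.
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname MultiplexImage-class
setMethod("markerNames", "MultiplexImage", function(x) x@markers)

setMethod("show", "MultiplexImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultiplexImage: %d x %d px, %d markers (%s)\n",
              d[1], d[2], d[3], paste(object@markers, collapse = ", ")))
})

#' GroundTruth: simulated-tissue annotation masks
#'
#' Ground truth emitted with every simulated tissue: pixel-level phenotype
#' and neighborhood label masks (0 = background) and the cell table used to
#' render the image.
#'
#' @slot phenotypeMask integer H x W matrix of phenotype ids.
#' @slot neighborhoodMask integer H x W matrix of neighborhood ids.
#' @slot cellTable data.frame with one row per rendered cell
#'   (cell, phenotype, neighborhood, y, x, radius).
#' @export
setClass("GroundTruth",
  representation(phenotypeMask = "matrix", neighborhoodMask = "matrix",
                 cellTable = "data.frame"),
  validity = function(object) {
    if (!identical(dim(object@phenotypeMask), dim(object@neighborhoodMask)))
      return("phenotype and neighborhood masks must have identical shape")
    bad <- object@phenotypeMask > 0 & object@neighborhoodMask == 0
    if (any(bad))
      return("phenotype pixels must lie inside a neighborhood region")
    TRUE
  })

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d x %d px, %d cells, %d phenotypes, %d neighborhoods\n",
              nrow(object@phenotypeMask), ncol(object@phenotypeMask),
              nrow(object@cellTable),
              length(setdiff(unique(as.vector(object@phenotypeMask)), 0L)),
              length(setdiff(unique(as.vector(object@neighborhoodMask)), 0L))))
})

#' @describeIn GroundTruth Phenotype label mask.
#' @param x a GroundTruth.
#' @export
setGeneric("phenotypeMask", function(x) standardGeneric("phenotypeMask"))
#' @rdname GroundTruth-class
setMethod("phenotypeMask", "GroundTruth", function(x) x@phenotypeMask)

#' @describeIn GroundTruth Neighborhood label mask.
#' @export
setGeneric("neighborhoodMask", function(x) standardGeneric("neighborhoodMask"))
#' @rdname GroundTruth-class
setMethod("neighborhoodMask", "GroundTruth", function(x) x@neighborhoodMask)

#' @describeIn GroundTruth Cell table.
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname GroundTruth-class
setMethod("cellTable", "GroundTruth", function(x) x@cellTable)

#' EmbeddedImage: patch embeddings on a regular grid
#'
#' The result of tiling an image into non-overlapping S_L x S_L patches and
#' passing each through a trained contrastive encoder: an L x g matrix of
#' patch embeddings plus the patch-grid geometry needed to map embeddings
#' back onto pixels.
#'
#' @slot embeddings numeric L x g matrix (row-major patch order).
#' @slot gridShape integer length-2 (rows, cols), rows * cols == L.
#' @slot patchSize integer patch side in pixels.
#' @slot imageId character identifier.
#' @export
setClass("EmbeddedImage",
  representation(embeddings = "matrix", gridShape = "integer",
                 patchSize = "integer", imageId = "character"),
  validity = function(object) {
    if (prod(object@gridShape) != nrow(object@embeddings))
      return("gridShape inconsistent with number of embeddings")
    if (any(!is.finite(object@embeddings)))
      return("embeddings contain non-finite values")
    TRUE
  })

#' @describeIn EmbeddedImage The L x g embedding matrix.
#' @param x an EmbeddedImage.
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))
#' @rdname EmbeddedImage-class
setMethod("embeddingMatrix", "EmbeddedImage", function(x) x@embeddings)

#' @describeIn EmbeddedImage Patch-grid shape (rows, cols).
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname EmbeddedImage-class
setMethod("gridShape", "EmbeddedImage", function(x) x@gridShape)

setMethod("show", "EmbeddedImage", function(object) {
  cat(sprintf("EmbeddedImage '%s': %d patches (%d x %d grid, S_L = %d), g = %d\n",
              object@imageId, nrow(object@embeddings), object@gridShape[1],
              object@gridShape[2], object@patchSize, ncol(object@embeddings)))
})

#' PatchGraph: sparse spatial graph of patch embeddings
#'
#' Nodes are patch embeddings; edges connect spatially adjacent patches
#' (4-connectivity on the patch grid by default). Edges are stored as a
#' directed edge list with both orientations present.
#'
#' @slot Z numeric L x g node-feature matrix.
#' @slot edges integer E x 2 matrix of directed edges (1-based node ids).
#' @slot patientId character.
#' @slot label character patient-level label (may be NA).
#' @slot coords integer L x 2 matrix of (row, col) patch-grid coordinates;
#'   images merged into one patient graph keep per-image coordinates.
#' @slot imageId character vector, one entry per node block (merged graphs).
#' @slot nodeImage integer vector mapping each node to its image block.
#' @export
setClass("PatchGraph",
  representation(Z = "matrix", edges = "matrix", patientId = "character",
                 label = "character", coords = "matrix",
                 imageId = "character", nodeImage = "integer"),
  validity = function(object) {
    L <- nrow(object@Z)
    e <- object@edges
    if (ncol(e) != 2L) return("edges must be an E x 2 matrix")
    if (nrow(e) > 0) {
      if (max(e) > L || min(e) < 1) return("edge endpoint out of range")
      if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
      key <- paste(e[, 1], e[, 2])
      rev <- paste(e[, 2], e[, 1])
      if (!all(rev %in% key)) return("edge list must contain both orientations")
    }
    if (nrow(e) > L * 8) return("more edges than the densest (8-neighbor) grid")
    TRUE
  })

#' @describeIn PatchGraph Directed edge list (E x 2).
#' @param x a PatchGraph.
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))
#' @rdname PatchGraph-class
setMethod("edgeMatrix", "PatchGraph", function(x) x@edges)

#' @rdname PatchGraph-class
setMethod("embeddingMatrix", "PatchGraph", function(x) x@Z)

#' @describeIn PatchGraph Patient identifier.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname PatchGraph-class
setMethod("patientId", "PatchGraph", function(x) x@patientId)

#' @describeIn PatchGraph Patient label.
#' @export
setGeneric("patientLabel", function(x) standardGeneric("patientLabel"))
#' @rdname PatchGraph-class
setMethod("patientLabel", "PatchGraph", function(x) x@label)

setMethod("show", "PatchGraph", function(object) {
  cat(sprintf("PatchGraph patient '%s' (label %s): %d nodes, %d directed edges, %d image(s)\n",
              object@patientId, object@label, nrow(object@Z),
              nrow(object@edges), length(object@imageId)))
})

#' PCLEncoder: trained patch contrastive encoder
#'
#' Holds the dense residual encoder and projection-head weights learned by
#' patch contrastive training, together with the per-channel normalization
#' statistics and the configuration used.
#'
#' @slot params list of weight matrices.
#' @slot channelMean numeric per-channel mean used for normalization.
#' @slot channelSd numeric per-channel sd.
#' @slot config list, the `pclConfig()` used.
#' @slot trained logical.
#' @export
setClass("PCLEncoder",
  representation(params = "list", channelMean = "numeric",
                 channelSd = "numeric", config = "list", trained = "logical"))

setMethod("show", "PCLEncoder", function(object) {
  cat(sprintf("PCLEncoder (%s): S_L = %d, g = %d, projection = %d, %s\n",
              object@config$encoder_depth, object@config$patch_size,
              object@config$embedding_dim, object@config$projection_dim,
              if (object@trained) "trained" else "untrained"))
})

#' TMEModel: trained microenvironment discovery model
#'
#' The trained two-stage network: f1 assigns patches to phenotypes,
#' neighborhoods and areas (soft assignment matrices), max-sum pooling turns
#' assignments into per-patient abundance vectors, and f2 maps abundances to
#' class probabilities.
#'
#' @slot params list of weight matrices for f1P, f1N, f1A and f2.
#' @slot config list, the `modelConfig()` used.
#' @slot classes character vector of outcome class labels.
#' @slot featureMean numeric embedding-feature means (training cohort).
#' @slot featureSd numeric embedding-feature sds.
#' @slot history data.frame per-epoch training log.
#' @export
setClass("TMEModel",
  representation(params = "list", config = "list", classes = "character",
                 featureMean = "numeric", featureSd = "numeric",
                 history = "data.frame"))

setMethod("show", "TMEModel", function(object) {
  cfg <- object@config
  cat(sprintf("TMEModel: P = %s, N = %s, A = %s, K = %d, classes: %s\n",
              if (cfg$use_phenotypes) cfg$P else "off",
              if (cfg$use_neighborhoods) cfg$N else "off",
              if (cfg$use_areas) cfg$A else "off",
              cfg$K, paste(object@classes, collapse = ", ")))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, best val accuracy %.3f\n",
                max(object@history$epoch),
                max(object@history$val_acc, na.rm = TRUE)))
})

#' @describeIn TMEModel Names of all TME abundance features (P*, N*, A*).
#' @param x a TMEModel.
#' @export
setGeneric("tmeNames", function(x) standardGeneric("tmeNames"))
#' @rdname TMEModel-class
setMethod("tmeNames", "TMEModel", function(x) {
  cfg <- x@config
  c(if (cfg$use_phenotypes) paste0("P", seq_len(cfg$P)),
    if (cfg$use_neighborhoods) paste0("N", seq_len(cfg$N)),
    if (cfg$use_areas) paste0("A", seq_len(cfg$A)))
})
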