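## Accessor generics and show methods.

#' @name accessors
#' @title Accessors for retveseg result objects
#' @description Slot accessors; user code should use these rather than
#'   \code{@}.
#' @param x a retveseg object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("odMask", function(x) standardGeneric("odMask"))
#' @rdname accessors
#' @export
setMethod("odMask", "ODResult", function(x) x@odMask)
#' @rdname accessors
#' @export
setMethod("odMask", "RetinaSegmentation", function(x) x@od@odMask)

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setMethod("vesselMask", "VesselResult", function(x) x@vesselMask)
#' @rdname accessors
#' @export
setMethod("vesselMask", "RetinaSegmentation", function(x) x@vessel@vesselMask)

#' @rdname accessors
#' @export
setGeneric("fovMask", function(x) standardGeneric("fovMask"))
#' @rdname accessors
#' @export
setMethod("fovMask", "FovMasks", function(x) x@fov)
#' @rdname accessors
#' @export
setMethod("fovMask", "RetinaSegmentation", function(x) x@fov@fov)

#' @rdname accessors
#' @export
setGeneric("maxResponse", function(x) standardGeneric("maxResponse"))
#' @rdname accessors
#' @export
setMethod("maxResponse", "VesselResult", function(x) x@maxResponse)
#' @rdname accessors
#' @export
setMethod("maxResponse", "RetinaSegmentation", function(x) x@vessel@maxResponse)

#' @rdname accessors
#' @export
setGeneric("odCentroid", function(x) standardGeneric("odCentroid"))
#' @rdname accessors
#' @export
setMethod("odCentroid", "ODResult", function(x) x@centroid)
#' @rdname accessors
#' @export
setMethod("odCentroid", "RetinaSegmentation", function(x) x@od@centroid)

#' @rdname accessors
#' @export
setGeneric("odArea", function(x) standardGeneric("odArea"))
#' @rdname accessors
#' @export
setMethod("odArea", "ODResult", function(x) x@area)

#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname accessors
#' @export
setMethod("thresholdUsed", "ThresholdResult", function(x) x@threshold)
#' @rdname accessors
#' @export
setMethod("thresholdUsed", "ODResult", function(x) x@thresholdUsed)
#' @rdname accessors
#' @export
setMethod("thresholdUsed", "VesselResult", function(x) x@thresholdUsed)

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setMethod("imageData", "FundusImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("imageData", "ChannelImage", function(x) x@.Data)
#' @rdname accessors
#' @export
setMethod("imageData", "BinaryMask", function(x) x@.Data)
#' @rdname accessors
#' @export
setMethod("imageData", "PhantomSample", function(x) x@image@pixels)

#' @rdname accessors
#' @export
setGeneric("vesselTruth", function(x) standardGeneric("vesselTruth"))
#' @rdname accessors
#' @export
setMethod("vesselTruth", "PhantomSample", function(x) x@vesselTruth)
#' @rdname accessors
#' @export
setGeneric("odTruth", function(x) standardGeneric("odTruth"))
#' @rdname accessors
#' @export
setMethod("odTruth", "PhantomSample", function(x) x@odTruth)
#' @rdname accessors
#' @export
setGeneric("fovTruth", function(x) standardGeneric("fovTruth"))
#' @rdname accessors
#' @export
setMethod("fovTruth", "PhantomSample", function(x) x@fovTruth)

#' @rdname accessors
#' @param ... ignored.
#' @export
setMethod("as.matrix", "ChannelImage", function(x, ...) {
  m <- x@.Data
  attr(m, "class") <- NULL
  m
})
#' @rdname accessors
#' @export
setMethod("as.matrix", "BinaryMask", function(x, ...) {
  m <- x@.Data
  attr(m, "class") <- NULL
  m
})

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage %d x %d, 3 channels, range [%d, %d]\n",
              d[1], d[2], min(object@pixels), max(object@pixels)))
})

setMethod("show", "ChannelImage", function(object) {
  cat(sprintf("ChannelImage %d x %d, range [%.6g, %.6g]\n",
              nrow(object), ncol(object), min(object), max(object)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d, %d foreground pixels (%.1f%%)\n",
              nrow(object), ncol(object), sum(object),
              100 * mean(object)))
})

setMethod("show", "StructuringElement", function(object) {
  d <- object@descriptor
  what <- if (identical(d$shape, "disc")) {
    sprintf("disc, radius %d", d$radius)
  } else if (identical(d$shape, "line")) {
    sprintf("line, length %d at %g deg", d$length, d$angle)
  } else "free-form"
  cat(sprintf("StructuringElement (%s): %d x %d footprint, %d cells\n",
              what, nrow(object@footprint), ncol(object@footprint),
              sum(object@footprint)))
})

setMethod("show", "DiffusionParams", function(object) {
  cat(sprintf("DiffusionParams: psi = %g, kappa = %g grey levels, %d iterations\n",
              object@psi, object@kappa, object@iterations))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf(
    "ThresholdResult: T = %.4f after %d iterations%s; %d pixels above\n",
    object@threshold, object@iterationsRun,
    if (object@degenerate) " (degenerate: constant input)" else "",
    sum(object@mask)))
})

setMethod("show", "ODResult", function(object) {
  if (object@area == 0L) {
    cat("ODResult: empty (no optic disc found)\n")
  } else {
    cat(sprintf(
      "ODResult: area %d px, centroid (%.1f, %.1f), threshold %.2f\n",
      object@area, object@centroid[1], object@centroid[2],
      object@thresholdUsed))
  }
})

setMethod("show", "VesselResult", function(object) {
  cat(sprintf(
    "VesselResult: %d vessel pixels, threshold %.2f%s\n",
    sum(object@vesselMask), object@thresholdUsed,
    if (object@empty) " (threshold stage found no foreground)" else ""))
})

setMethod("show", "RetinaSegmentation", function(object) {
  cat("RetinaSegmentation\n")
  cat(sprintf("  FOV: %d px\n", sum(object@fov@fov)))
  cat(sprintf("  OD:  %d px at (%.1f, %.1f)\n", object@od@area,
              object@od@centroid[1], object@od@centroid[2]))
  cat(sprintf("  vessels: %d px in %s\n", sum(object@vessel@vesselMask),
              paste(dim(object@vessel@vesselMask), collapse = " x ")))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %d  FP %d  TN %d  FN %d\n",
              object@tp, object@fp, object@tn, object@fn))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport [%s]: Se %.4f  Sp %.4f  Acc %.4f\n",
              object@imageId, object@sensitivity, object@specificity,
              object@accuracy))
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf(
    "PhantomSample %d x %d (seed %d): vessels %d px, OD %d px, FOV %d px\n",
    object@spec@height, object@spec@width, object@spec@seed,
    sum(object@vesselTruth), sum(object@odTruth), sum(object@fovTruth)))
})
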