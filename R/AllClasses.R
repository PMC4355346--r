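## Central S4 data model. Raster convention throughout the package:
## row-major matrices, origin at top-left, (row, col) indexing, 1-based in R.

#' ChannelImage: a single-channel intensity raster
#'
#' A numeric H x W matrix of grey levels (integer on load, real during
#' processing). All pipeline stages operate on this unit.
#'
#' @slot .Data numeric matrix of finite grey-level values.
#' @export
setClass("ChannelImage", contains = "matrix",
  validity = function(object) {
    if (length(dim(object)) != 2L) return("a ChannelImage must be a 2-D matrix")
    if (!is.numeric(object@.Data)) return("values must be numeric")
    if (any(!is.finite(object@.Data))) return("values must be finite")
    TRUE
  })

#' @param values numeric matrix of grey levels.
#' @return A \code{ChannelImage}.
#' @rdname ChannelImage-class
#' @export
ChannelImage <- function(values) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  new("ChannelImage", m)
}

#' BinaryMask: a boolean raster
#'
#' Logical H x W matrix marking a region (field of view, optic disc,
#' vessels) on an image of the same shape.
#'
#' @slot .Data logical matrix.
#' @export
setClass("BinaryMask", contains = "matrix",
  validity = function(object) {
    if (length(dim(object)) != 2L) return("a BinaryMask must be a 2-D matrix")
    if (!is.logical(object@.Data)) return("values must be logical")
    if (anyNA(object@.Data)) return("mask values must not be NA")
    TRUE
  })

#' @param values logical (or coercible) matrix.
#' @return A \code{BinaryMask}.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(values) {
  m <- as.matrix(values)
  if (!is.logical(m)) {
    m2 <- m != 0
    dim(m2) <- dim(m)
    m <- m2
  }
  new("BinaryMask", m)
}

#' FundusImage: an 8-bit RGB fundus photograph
#'
#' @slot pixels integer H x W x 3 array, intensities in [0, 255].
#' @export
setClass("FundusImage", representation(pixels = "array"),
  validity = function(object) {
    p <- object@pixels
    d <- dim(p)
    if (length(d) != 3L || d[3] != 3L) return("pixels must be an H x W x 3 array")
    if (d[1] < 3L || d[2] < 3L) return("image must be at least 3 x 3")
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      return("intensities must lie in [0, 255]")
    TRUE
  })

#' @param pixels H x W x 3 array of intensities in [0, 255].
#' @return A \code{FundusImage}.
#' @rdname FundusImage-class
#' @export
FundusImage <- function(pixels) {
  a <- round(pixels)
  storage.mode(a) <- "integer"
  new("FundusImage", pixels = a)
}

#' DiffusionParams: parameters of the eight-neighbour diffusion scheme
#'
#' @slot psi update rate in (0, 1]; 1/8 keeps the explicit scheme stable
#'   for eight neighbours.
#' @slot kappa edge-sensitivity scale k_a in grey levels.
#' @slot iterations number of explicit update steps.
#' @export
setClass("DiffusionParams",
  representation(psi = "numeric", kappa = "numeric", iterations = "integer"),
  validity = function(object) {
    if (length(object@psi) != 1L || !is.finite(object@psi) ||
        object@psi <= 0 || object@psi > 1)
      return("psi must be a single value in (0, 1]")
    if (length(object@kappa) != 1L || !is.finite(object@kappa) || object@kappa <= 0)
      return("kappa must be a single positive value")
    if (length(object@iterations) != 1L || object@iterations < 1L)
      return("iterations must be a positive integer")
    TRUE
  })

#' @param psi update rate in (0, 1].
#' @param kappa positive edge scale in grey levels.
#' @param iterations positive integer.
#' @return A \code{DiffusionParams}.
#' @rdname DiffusionParams-class
#' @export
diffusionParams <- function(psi = 1 / 8, kappa = 30, iterations = 15) {
  new("DiffusionParams", psi = as.numeric(psi), kappa = as.numeric(kappa),
      iterations = as.integer(iterations))
}

#' DirectionalKernel: a 3 x 3 first-difference template
#'
#' Centre entry -1, exactly one +1 at the neighbour the kernel points to,
#' zeros elsewhere; correlation with it yields neighbour minus centre.
#'
#' @slot direction one of N, S, E, W, NE, NW, SE, SW.
#' @slot weights integer 3 x 3 matrix.
#' @export
setClass("DirectionalKernel",
  representation(direction = "character", weights = "matrix"),
  validity = function(object) {
    w <- object@weights
    if (!all(dim(w) == c(3L, 3L))) return("weights must be 3 x 3")
    if (sum(w) != 0) return("weights must sum to 0")
    if (w[2, 2] != -1) return("centre weight must be -1")
    if (sum(w == 1) != 1L || sum(w == 0) != 7L)
      return("weights must contain exactly one +1 and seven 0s")
    if (!object@direction %in% c("N", "S", "E", "W", "NE", "NW", "SE", "SW"))
      return("unknown direction")
    TRUE
  })

#' StructuringElement: a binary footprint with an origin
#'
#' Discs contain exactly the integer offsets at Euclidean distance <= r
#' from the origin; lines contain exactly L rasterised collinear cells
#' through the origin at a given angle (degrees counterclockwise from the
#' +col axis).
#'
#' @slot footprint logical matrix.
#' @slot origin integer (row, col) of the centre within the footprint.
#' @slot descriptor list describing the shape (disc radius or line
#'   length/angle), or empty for free-form footprints.
#' @export
setClass("StructuringElement",
  representation(footprint = "matrix", origin = "integer", descriptor = "list"),
  validity = function(object) {
    fp <- object@footprint
    o <- object@origin
    if (!is.logical(fp)) return("footprint must be logical")
    if (length(o) != 2L) return("origin must be (row, col)")
    if (o[1] < 1L || o[1] > nrow(fp) || o[2] < 1L || o[2] > ncol(fp))
      return("origin must lie inside the footprint")
    if (!any(fp)) return("footprint must contain at least one true cell")
    TRUE
  })

#' ThresholdResult: outcome of iterative mean-split thresholding
#'
#' @slot threshold converged threshold T in grey levels.
#' @slot mask BinaryMask of pixels strictly above T (restricted to the
#'   analysis region when one was supplied).
#' @slot t0 initial threshold actually used (after range clamping).
#' @slot tol convergence tolerance in grey levels.
#' @slot iterationsRun number of update iterations performed.
#' @slot degenerate TRUE when the input was constant (threshold equals the
#'   constant, mask empty).
#' @export
setClass("ThresholdResult",
  representation(threshold = "numeric", mask = "BinaryMask", t0 = "numeric",
                 tol = "numeric", iterationsRun = "integer",
                 degenerate = "logical"),
  validity = function(object) {
    if (object@iterationsRun < 1L) return("iterationsRun must be >= 1")
    TRUE
  })

#' FovMasks: field-of-view mask triple
#'
#' @slot fov the field-of-view mask built from the green channel.
#' @slot fovDilated fov dilated by a 15-px disc (used to clean the raw
#'   optic-disc candidates).
#' @slot fovEroded fov eroded by a 10-px disc (used to trim the outer
#'   circle from the vessel mask).
#' @export
setClass("FovMasks",
  representation(fov = "BinaryMask", fovDilated = "BinaryMask",
                 fovEroded = "BinaryMask"),
  validity = function(object) {
    d <- dim(object@fov)
    if (!all(dim(object@fovDilated) == d) || !all(dim(object@fovEroded) == d))
      return("the three masks must share one shape")
    TRUE
  })

#' ODResult: segmented optic disc
#'
#' @slot odMask BinaryMask of the optic-disc region (possibly empty).
#' @slot thresholdUsed threshold applied to the diffused channel.
#' @slot centroid (row, col) of the disc, NA when empty.
#' @slot area number of true pixels.
#' @export
setClass("ODResult",
  representation(odMask = "BinaryMask", thresholdUsed = "numeric",
                 centroid = "numeric", area = "integer"),
  validity = function(object) {
    if (object@area != sum(object@odMask))
      return("area must equal the number of true pixels")
    if (length(object@centroid) != 2L) return("centroid must be (row, col)")
    TRUE
  })

#' OrientationBank: the twelve oriented line structuring elements
#'
#' @slot angles twelve angles, 15 to 180 degrees in 15-degree steps.
#' @slot length number of pixels analysed along each direction.
#' @slot elements list of twelve line StructuringElements.
#' @export
setClass("OrientationBank",
  representation(angles = "numeric", length = "integer", elements = "list"),
  validity = function(object) {
    if (length(object@angles) != 12L ||
        any(object@angles != seq(15, 180, by = 15)))
      return("angles must be 15, 30, ..., 180 degrees")
    if (length(object@elements) != 12L) return("twelve elements required")
    n <- vapply(object@elements, function(e) sum(e@footprint), integer(1))
    if (any(n != object@length))
      return("each element must contain exactly `length` true cells")
    TRUE
  })

#' VesselResult: the segmented vessel tree with stage intermediates
#'
#' @slot maxResponse pixelwise maximum over the twelve oriented openings.
#' @slot thresholdMask the thresholded maximum-response image G.
#' @slot vesselMask the final vessel segmentation.
#' @slot thresholdUsed threshold applied to the maximum-response image.
#' @slot intermediates named list of stage rasters (raw top-hat, trimmed,
#'   denoised, optionally the twelve per-orientation responses).
#' @slot empty TRUE when thresholding produced no foreground.
#' @export
setClass("VesselResult",
  representation(maxResponse = "ChannelImage", thresholdMask = "BinaryMask",
                 vesselMask = "BinaryMask", thresholdUsed = "numeric",
                 intermediates = "list", empty = "logical"))

#' RetinaSegmentation: full pipeline output for one image
#'
#' @slot vessel VesselResult.
#' @slot od ODResult.
#' @slot fov FovMasks.
#' @slot config the fully resolved configuration the run used.
#' @export
setClass("RetinaSegmentation",
  representation(vessel = "VesselResult", od = "ODResult", fov = "FovMasks",
                 config = "list"))

#' ConfusionCounts: pixel-wise confusion tallies (vessel = positive class)
#'
#' @slot tp,fp,tn,fn non-negative pixel counts over the evaluated region.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (length(v) != 4L || anyNA(v) || any(v < 0) || any(v != round(v)))
      return("counts must be non-negative integers")
    TRUE
  })

#' MetricReport: Se/Sp/Acc for one image
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/all; a zero denominator yields NA with \code{undefined} listing
#' which metrics were undefined.
#'
#' @slot sensitivity,specificity,accuracy reals in [0, 1] or NA.
#' @slot counts the underlying ConfusionCounts.
#' @slot imageId identifier used in reports.
#' @slot undefined character vector naming undefined metrics.
#' @export
setClass("MetricReport",
  representation(sensitivity = "numeric", specificity = "numeric",
                 accuracy = "numeric", counts = "ConfusionCounts",
                 imageId = "character", undefined = "character"))

#' PhantomSpec: parameters of the synthetic fundus phantom
#'
#' Defaults emulate a DRIVE/STARE-like geometry at 256 x 256: a bright
#' circular field of view on a dark surround, a bright optic disc
#' (brightest in red), and a dark branching vessel tree radiating from the
#' disc rim (highest contrast in green), plus additive Gaussian noise.
#'
#' @slot height,width raster size in pixels.
#' @slot fovRadiusFrac FOV radius as a fraction of min(height, width).
#' @slot odCenter (row, col) of the optic disc, or NA to draw it uniformly
#'   inside the FOV from the sample's random stream.
#' @slot odRadius optic-disc radius in pixels.
#' @slot odRed,odGreen,odBlue optic-disc intensities per channel.
#' @slot bgRed,bgGreen,bgBlue retinal background intensities per channel.
#' @slot nRoots number of vessel roots on the optic-disc rim.
#' @slot branchProb probability of spawning a branch at each walk step.
#' @slot stepLen random-walk step length in pixels.
#' @slot initWidth initial vessel width in pixels.
#' @slot widthDecay multiplicative width decay per branching event.
#' @slot minWidth lower bound on vessel width in pixels.
#' @slot vesselContrast green-channel darkening under vessels, grey levels.
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @slot seed integer seed of the sample's private random stream.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer",
                 fovRadiusFrac = "numeric", odCenter = "numeric",
                 odRadius = "numeric", odRed = "numeric", odGreen = "numeric",
                 odBlue = "numeric", bgRed = "numeric", bgGreen = "numeric",
                 bgBlue = "numeric", nRoots = "integer", branchProb = "numeric",
                 stepLen = "numeric", initWidth = "numeric",
                 widthDecay = "numeric", minWidth = "numeric",
                 vesselContrast = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@height < 32L || object@width < 32L)
      return("phantom must be at least 32 x 32")
    if (object@fovRadiusFrac <= 0 || object@fovRadiusFrac > 0.5)
      return("fovRadiusFrac must lie in (0, 0.5]")
    fovR <- object@fovRadiusFrac * min(object@height, object@width)
    if (!anyNA(object@odCenter)) {
      ctr <- c((object@height + 1) / 2, (object@width + 1) / 2)
      if (sqrt(sum((object@odCenter - ctr)^2)) + object@odRadius > fovR)
        return("optic disc must lie entirely inside the field of view")
    }
    if (object@odRadius < 2) return("odRadius must be >= 2")
    if (object@initWidth < object@minWidth || object@minWidth < 1)
      return("widths must satisfy initWidth >= minWidth >= 1")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    ints <- c(object@odRed, object@odGreen, object@odBlue,
              object@bgRed, object@bgGreen, object@bgBlue)
    if (any(ints < 0 | ints > 255)) return("intensities must lie in [0, 255]")
    TRUE
  })

#' PhantomSample: one generated phantom with exact ground truth
#'
#' @slot image the rendered FundusImage.
#' @slot vesselTruth,odTruth,fovTruth exact BinaryMask ground truth,
#'   rendered before noise.
#' @slot odCenterRealized the (row, col) optic-disc centre actually used.
#' @slot spec the generating PhantomSpec (echo).
#' @export
setClass("PhantomSample",
  representation(image = "FundusImage", vesselTruth = "BinaryMask",
                 odTruth = "BinaryMask", fovTruth = "BinaryMask",
                 odCenterRealized = "numeric", spec = "PhantomSpec"),
  validity = function(object) {
    if (any(object@vesselTruth & !object@fovTruth))
      return("vessel truth must lie inside the FOV")
    if (any(object@odTruth & !object@fovTruth))
      return("optic-disc truth must lie inside the FOV")
    TRUE
  })
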