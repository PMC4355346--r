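## Vessel detection core: twelve-orientation line-opening enhancement,
## maximum response, isodata thresholding, disc top-hat extraction, FOV
## trimming, small-component removal and optic-disc exclusion.

#' The twelve-orientation line bank
#'
#' Angles 15 to 180 degrees in 15-degree increments (180 coincides with
#' horizontal), each a line structuring element analysing \code{length}
#' pixels along its direction. At 15-degree resolution the bank covers
#' orientation space, so a vessel segment of at least \code{length}
#' pixels survives the opening in its best-aligned element.
#'
#' @param length line length in pixels (default 10).
#' @return An \code{\link{OrientationBank-class}} object.
#' @export
orientationBank <- function(length = 10) {
  angles <- seq(15, 180, by = 15)
  new("OrientationBank", angles = angles, length = as.integer(length),
      elements = lapply(angles, function(a) makeLine(length, a)))
}

#' Per-orientation opened responses
#'
#' The working image is the inverted channel (vessels are dark in green,
#' openings preserve bright structures) restricted to the FOV; each bank
#' element yields one greyscale opening. Responses are anti-extensive:
#' each is pixelwise at most the working image.
#'
#' @param greenNoOD \code{ChannelImage}: the optic-disc-eliminated green
#'   plane (8-bit range).
#' @param bank an \code{\link{orientationBank}}.
#' @param fov optional \code{BinaryMask}; outside pixels are zeroed
#'   before opening.
#' @return List of 12 \code{ChannelImage} responses (named by angle).
#' @export
orientationResponses <- function(greenNoOD, bank = orientationBank(),
                                 fov = NULL) {
  g <- as.matrix(greenNoOD)
  v <- 255 - g
  if (!is.null(fov)) v[!as.matrix(fov)] <- 0
  out <- lapply(bank@elements, function(s) openImage(ChannelImage(v), s))
  names(out) <- sprintf("%ddeg", bank@angles)
  out
}

#' Pixelwise maximum over the orientation responses
#'
#' Enhances vessels regardless of local direction: each vessel pixel
#' keeps the response of its best-aligned line element.
#'
#' @param responses list of same-shape \code{ChannelImage}s.
#' @return A \code{ChannelImage}.
#' @export
maximumResponse <- function(responses) {
  stopifnot(length(responses) >= 1L)
  d <- dim(as.matrix(responses[[1]]))
  for (r in responses)
    if (!all(dim(as.matrix(r)) == d)) stop("response shapes differ")
  acc <- Reduce(function(a, b) pmax(a, as.matrix(b)),
                responses[-1], as.matrix(responses[[1]]))
  dim(acc) <- d
  ChannelImage(acc)
}

#' Extract the vessel mask from the maximum-response image
#'
#' Stages: (1) isodata threshold of the maximum response (class means over
#' the eroded-FOV pixels) giving the binary image G; (2) top-hat
#' \code{G - open(G, disc(sSize))}, which keeps structures thinner than
#' the disc (vessels) and removes bulk regions; (3) AND with the eroded
#' FOV to cut the bright outer circle; (4) removal of components with
#' fewer than \code{minComponent} pixels; (5) AND with the complement of
#' the optic-disc mask. The as-printed alternative
#' \code{G - (G - erode(G, disc(sSize)))}, which reduces to plain erosion
#' and erases every structure thinner than the disc, is available as
#' \code{eq10 = "literal"} for audit.
#'
#' @param maxResponse \code{ChannelImage} from
#'   \code{\link{maximumResponse}}.
#' @param fovEroded \code{BinaryMask}: the eroded field of view.
#' @param od an \code{\link{ODResult-class}} object.
#' @param sSize disc radius of the top-hat structuring element
#'   (default 15).
#' @param minComponent minimum component size in pixels (default 50).
#' @param t0,tol threshold stage parameters.
#' @param eq10 \code{"tophat"} (default) or \code{"literal"}.
#' @param connectivity component connectivity, 4 or 8.
#' @return A \code{\link{VesselResult-class}} object. An empty threshold
#'   stage yields an empty result with \code{empty = TRUE}, not an error.
#' @export
extractVessels <- function(maxResponse, fovEroded, od, sSize = 15,
                           minComponent = 50, t0 = 15, tol = 0.5,
                           eq10 = c("tophat", "literal"), connectivity = 8) {
  eq10 <- match.arg(eq10)
  mr <- as.matrix(maxResponse)
  fovE <- as.matrix(fovEroded)
  odM <- as.matrix(od@odMask)
  if (!all(dim(mr) == dim(fovE)) || !all(dim(mr) == dim(odM)))
    stop("maximum response, FOV and OD mask shapes differ")
  th <- iterativeThreshold(mr, t0 = t0, tol = tol,
                           mask = BinaryMask(fovE))
  G <- as.matrix(th@mask)
  isEmpty <- !any(G)
  if (isEmpty) warning("vessel threshold stage found no foreground")
  disc <- makeDisc(sSize)
  raw <- if (eq10 == "tophat") {
    G & !as.matrix(openImage(BinaryMask(G), disc))
  } else {
    as.matrix(erodeImage(BinaryMask(G), disc))
  }
  trimmed <- raw & fovE
  denoised <- as.matrix(removeSmallComponents(trimmed, minComponent,
                                              connectivity))
  vessel <- denoised & !odM
  new("VesselResult", maxResponse = ChannelImage(mr),
      thresholdMask = BinaryMask(G), vesselMask = BinaryMask(vessel),
      thresholdUsed = th@threshold,
      intermediates = list(raw = BinaryMask(raw),
                           trimmed = BinaryMask(trimmed),
                           denoised = BinaryMask(denoised)),
      empty = isEmpty)
}

#' Segment the retinal vessel tree in a fundus image
#'
#' Deterministic composition of the full pipeline: channel extraction,
#' FOV mask construction from the green plane, optic-disc segmentation on
#' the diffused red plane, optic-disc elimination from the green plane,
#' twelve-orientation line-opening enhancement of the inverted image,
#' maximum response, isodata thresholding, top-hat extraction, FOV
#' trimming, small-component removal and optic-disc exclusion. Every
#' intermediate is retrievable from the returned object.
#'
#' @param img a \code{FundusImage} (or a path, which is read with
#'   \code{\link{readFundus}}).
#' @param config resolved configuration list from
#'   \code{\link{loadConfig}}/\code{\link{defaultConfig}}.
#' @param keepResponses keep the 12 per-orientation responses in the
#'   result (memory-hungry on large images).
#' @return A \code{\link{RetinaSegmentation-class}} object.
#' @export
segmentVessels <- function(img, config = defaultConfig(),
                           keepResponses = FALSE) {
  if (is.character(img)) img <- readFundus(img)
  stopifnot(is(img, "FundusImage"))
  green <- extractChannel(img, "green")
  fov <- withStage("fov-mask", buildFovMask(
    green,
    greenThreshold = config$mask$green_threshold,
    openRadius = config$mask$open_radius,
    dilateRadius = config$mask$dilate_radius,
    erodeRadius = config$mask$erode_radius,
    holeFill = config$mask$fill_holes))
  od <- withStage("od-segment", segmentOD(
    img, fov,
    params = diffusionParams(config$diffusion$psi, config$diffusion$kappa,
                             config$diffusion$iterations),
    channel = config$od$channel, t0 = config$threshold$t0,
    tol = config$threshold$tol, fovOnly = config$threshold$fov_only))
  src <- if (identical(config$vessel$source, "green")) green
         else withStage("od-eliminate",
                        eliminateOD(green, od, fill = config$od$fill,
                                    fov = fov@fov))
  bank <- orientationBank(config$vessel$line_length)
  resp <- withStage("orientation-open",
                    orientationResponses(src, bank, fov = fov@fov))
  mr <- maximumResponse(resp)
  vessel <- withStage("vessel-extract", extractVessels(
    mr, fov@fovEroded, od,
    sSize = config$postprocess$s_size,
    minComponent = config$postprocess$min_component,
    t0 = config$threshold$t0, tol = config$threshold$tol,
    eq10 = config$postprocess$eq10,
    connectivity = config$postprocess$connectivity))
  if (keepResponses) vessel@intermediates$responses <- resp
  new("RetinaSegmentation", vessel = vessel, od = od, fov = fov,
      config = config)
}

## wrap a stage so every error names where it happened
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}
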