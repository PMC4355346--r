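## Seeded synthetic fundus phantom: circular bright field of view on a
## dark surround, a bright optic disc (brightest in red) with a blurred
## rim, and a dark branching vessel tree radiating outward from the disc
## rim (highest contrast in green), plus additive Gaussian noise. Exact
## vessel/OD/FOV masks are rendered before noise, so every pipeline stage
## can be validated without external data.
##
## Each sample consumes one private random stream in a fixed, documented
## order: optic-disc placement (when drawn), then the vessel tree, then
## the noise field. Adding or removing noise therefore never reshuffles
## the tree geometry, and regeneration under the same spec and seed is
## bit-identical.

#' Construct a phantom specification
#'
#' See \code{\link{PhantomSpec-class}} for the meaning of every
#' parameter. Defaults render a 256 x 256 phantom with an FOV radius of
#' 0.47 of the image side, an 18-px optic disc (red 230 / green 180 on a
#' 90 / 70 background), six vessel roots with a 0.02 per-step branching
#' probability, 3-px steps, initial width 4 px decaying by 0.7 per branch
#' (floor 1 px), a 45-grey-level green-channel vessel contrast, and noise
#' with a standard deviation of 3 grey levels.
#'
#' @param height,width raster size.
#' @param fovRadiusFrac FOV radius as a fraction of \code{min(height,
#'   width)}.
#' @param odCenter (row, col) or \code{NA} to draw the centre uniformly
#'   inside the FOV from the sample's stream.
#' @param odRadius disc radius in pixels.
#' @param odRed,odGreen,odBlue,bgRed,bgGreen,bgBlue channel intensities.
#' @param nRoots,branchProb,stepLen,initWidth,widthDecay,minWidth vessel
#'   tree parameters.
#' @param vesselContrast green-channel darkening in grey levels.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed integer seed of the sample's private stream.
#' @return A \code{\link{PhantomSpec-class}} object.
#' @export
phantomSpec <- function(height = 256, width = 256, fovRadiusFrac = 0.47,
                        odCenter = c(128, 170), odRadius = 18,
                        odRed = 230, odGreen = 180, odBlue = 60,
                        bgRed = 90, bgGreen = 70, bgBlue = 25,
                        nRoots = 6, branchProb = 0.02, stepLen = 3,
                        initWidth = 4, widthDecay = 0.7, minWidth = 1,
                        vesselContrast = 45, noiseSd = 3, seed = 1) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      fovRadiusFrac = fovRadiusFrac,
      odCenter = if (anyNA(odCenter)) NA_real_ else as.numeric(odCenter),
      odRadius = as.numeric(odRadius), odRed = as.numeric(odRed),
      odGreen = as.numeric(odGreen), odBlue = as.numeric(odBlue),
      bgRed = as.numeric(bgRed), bgGreen = as.numeric(bgGreen),
      bgBlue = as.numeric(bgBlue), nRoots = as.integer(nRoots),
      branchProb = branchProb, stepLen = as.numeric(stepLen),
      initWidth = as.numeric(initWidth), widthDecay = widthDecay,
      minWidth = as.numeric(minWidth),
      vesselContrast = as.numeric(vesselContrast),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

## separable Gaussian blur with edge replication
gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  out <- 0
  for (i in -r:r) out <- out + k[i + r + 1L] * shiftReplicate(m, i, 0L)
  m2 <- out
  out <- 0
  for (j in -r:r) out <- out + k[j + r + 1L] * shiftReplicate(m2, 0L, j)
  out
}

## run expr under a private RNG stream, leaving the caller's untouched
withPrivateSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

## grow the vessel tree as a seeded random walk from the disc rim.
## Returns a matrix of strokes (r0, c0, r1, c1, width).
growTree <- function(spec, center, fovR, imgCenter) {
  segs <- matrix(numeric(0), ncol = 5)
  if (spec@nRoots < 1L) return(segs)
  stack <- vector("list", 0)
  for (i in seq_len(spec@nRoots)) {
    phi <- 2 * pi * (i - 1) / spec@nRoots + stats::runif(1, -0.2, 0.2)
    pos <- center + spec@odRadius * c(-sin(phi), cos(phi))
    stack[[length(stack) + 1L]] <-
      list(pos = pos, phi = phi, wd = spec@initWidth)
  }
  ## per-step heading jitter (radians). Retinal vessels are locally
  ## straight at the scale of the 10-px line templates; 0.05 rad/step
  ## (~3 deg) gives gently curving paths whose heading drifts ~5 deg over
  ## a template length, matching that precondition.
  headingJitterSd <- 0.05
  maxSegs <- 20000L
  while (length(stack) > 0L && nrow(segs) < maxSegs) {
    br <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    pos <- br$pos; phi <- br$phi; wd <- br$wd
    for (step in seq_len(500L)) {
      phi <- phi + stats::rnorm(1, 0, headingJitterSd)
      nxt <- pos + spec@stepLen * c(-sin(phi), cos(phi))
      segs <- rbind(segs, c(pos, nxt, wd))
      pos <- nxt
      if (sqrt(sum((pos - imgCenter)^2)) > fovR) break
      if (stats::runif(1) < spec@branchProb) {
        side <- if (stats::runif(1) < 0.5) -1 else 1
        childPhi <- phi + side * stats::runif(1, 0.4, 0.9)
        wd <- max(spec@minWidth, wd * spec@widthDecay)
        stack[[length(stack) + 1L]] <-
          list(pos = pos, phi = childPhi, wd = wd)
      }
    }
  }
  segs
}

## rasterise stroked polyline segments with round caps: the truth set is
## exactly the pixels within width/2 of the stroked path (plus the
## nearest pixel per sample point, so 1-px strokes stay connected)
strokeSegments <- function(segs, H, W) {
  m <- matrix(FALSE, H, W)
  if (nrow(segs) == 0L) return(m)
  for (i in seq_len(nrow(segs))) {
    p0 <- segs[i, 1:2]; p1 <- segs[i, 3:4]; rad <- segs[i, 5] / 2
    len <- sqrt(sum((p1 - p0)^2))
    nPts <- max(2L, as.integer(ceiling(len / 0.5)) + 1L)
    ts <- seq(0, 1, length.out = nPts)
    w <- as.integer(ceiling(rad))
    for (t in ts) {
      p <- p0 + t * (p1 - p0)
      rc <- as.integer(round(p))
      rs <- max(1L, rc[1] - w):min(H, rc[1] + w)
      cs <- max(1L, rc[2] - w):min(W, rc[2] + w)
      dr <- rs - p[1]
      dc <- cs - p[2]
      hit <- outer(dr^2, dc^2, "+") <= rad^2
      if (rc[1] >= 1L && rc[1] <= H && rc[2] >= 1L && rc[2] <= W)
        m[rc[1], rc[2]] <- TRUE
      m[rs, cs] <- m[rs, cs] | hit
    }
  }
  m
}

#' Generate one synthetic fundus phantom
#'
#' Rendering order: FOV disc, optic disc (edge softened with a 2-px
#' Gaussian), vessel tree grown by a seeded random walk from the disc rim
#' outward (strokes darken the green channel by the configured contrast;
#' masks are the exact stroked sets, anti-aliasing is applied only to the
#' intensity image), additive Gaussian noise, clamped to [0, 255].
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return A \code{\link{PhantomSample-class}} with the image, the exact
#'   vessel/OD/FOV truth masks, and the realised optic-disc centre.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  validObject(spec)
  H <- spec@height; W <- spec@width
  imgCenter <- c((H + 1) / 2, (W + 1) / 2)
  fovR <- spec@fovRadiusFrac * min(H, W)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  fovDist2 <- (rows - imgCenter[1])^2 + (cols - imgCenter[2])^2
  fov <- fovDist2 <= fovR^2

  withPrivateSeed(spec@seed, {
    ## 1. optic-disc placement
    odCenter <- if (anyNA(spec@odCenter)) {
      maxR <- fovR - spec@odRadius - 6
      rr <- maxR * sqrt(stats::runif(1))
      aa <- stats::runif(1, 0, 2 * pi)
      imgCenter + rr * c(-sin(aa), cos(aa))
    } else spec@odCenter
    odDist2 <- (rows - odCenter[1])^2 + (cols - odCenter[2])^2
    odMask <- odDist2 <= spec@odRadius^2

    ## 2. vessel tree, then exact truth rasters (before noise)
    segs <- growTree(spec, odCenter, fovR, imgCenter)
    vessel <- strokeSegments(segs, H, W) & fov

    ## 3. intensity rendering
    odSoft <- gaussianBlur(odMask * 1, 2)
    chR <- spec@bgRed + (spec@odRed - spec@bgRed) * odSoft
    chG <- spec@bgGreen + (spec@odGreen - spec@bgGreen) * odSoft
    chB <- spec@bgBlue + (spec@odBlue - spec@bgBlue) * odSoft
    vSoft <- gaussianBlur(vessel * 1, 0.5)  # anti-aliased stroke rendering
    chG <- chG - spec@vesselContrast * vSoft
    chB <- chB - 0.25 * spec@vesselContrast * vSoft
    chR[!fov] <- 0; chG[!fov] <- 0; chB[!fov] <- 0

    ## 4. noise last
    if (spec@noiseSd > 0) {
      chR <- chR + stats::rnorm(H * W, 0, spec@noiseSd)
      chG <- chG + stats::rnorm(H * W, 0, spec@noiseSd)
      chB <- chB + stats::rnorm(H * W, 0, spec@noiseSd)
    }
    px <- array(0, dim = c(H, W, 3))
    px[, , 1] <- chR; px[, , 2] <- chG; px[, , 3] <- chB
    px <- pmin(pmax(round(px), 0), 255)

    new("PhantomSample", image = FundusImage(px),
        vesselTruth = BinaryMask(vessel), odTruth = BinaryMask(odMask & fov),
        fovTruth = BinaryMask(fov), odCenterRealized = odCenter, spec = spec)
  })
}

#' Generate a suite of phantoms with varying optic-disc positions
#'
#' Sample \code{i} uses seed \code{baseSeed + i - 1}. Unless the template
#' fixes \code{odCenter}, disc centres are drawn uniformly inside the FOV
#' per sample.
#'
#' @param n number of samples.
#' @param baseSeed integer seed of the first sample.
#' @param spec template \code{\link{phantomSpec}} (default: random disc
#'   placement).
#' @return List of \code{\link{PhantomSample-class}} objects.
#' @export
generatePhantomSuite <- function(n, baseSeed = 1,
                                 spec = phantomSpec(odCenter = NA)) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    s <- spec
    s@seed <- as.integer(baseSeed + i - 1)
    generatePhantom(s)
  })
}
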