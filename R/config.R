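## Layered run configuration: documented defaults < YAML file < explicit
## overrides. Unknown keys and out-of-range values are rejected by name,
## and the fully resolved configuration is echoed into every run
## manifest.

#' Default pipeline configuration
#'
#' @return Nested named list of every tunable parameter:
#' \describe{
#'   \item{diffusion}{\code{psi} (0,1], \code{kappa} > 0 grey levels,
#'     \code{iterations} >= 1.}
#'   \item{threshold}{\code{t0} initial threshold, \code{tol} > 0
#'     convergence tolerance in grey levels, \code{fov_only} restrict
#'     histograms to the FOV.}
#'   \item{mask}{\code{green_threshold} (numeric or \code{"auto"}),
#'     \code{open_radius}, \code{dilate_radius}, \code{erode_radius},
#'     \code{fill_holes}.}
#'   \item{od}{\code{channel} red|green, \code{fill} zero|mean.}
#'   \item{vessel}{\code{line_length} pixels per oriented template,
#'     \code{source} od_eliminated|green.}
#'   \item{postprocess}{\code{s_size} top-hat disc radius,
#'     \code{min_component} pixels, \code{connectivity} 4|8, \code{eq10}
#'     tophat|literal.}
#' }
#' @export
defaultConfig <- function() {
  list(
    diffusion = list(psi = 1 / 8, kappa = 30, iterations = 15L),
    threshold = list(t0 = 15, tol = 0.5, fov_only = TRUE),
    mask = list(green_threshold = 10, open_radius = 1L, dilate_radius = 15L,
                erode_radius = 10L, fill_holes = TRUE),
    od = list(channel = "red", fill = "zero"),
    vessel = list(line_length = 10L, source = "od_eliminated"),
    postprocess = list(s_size = 15L, min_component = 50L,
                       connectivity = 8L, eq10 = "tophat")
  )
}

validateConfig <- function(cfg) {
  chk <- function(cond, key, what) {
    if (!cond) stop("config error: ", key, " ", what, call. = FALSE)
  }
  d <- cfg$diffusion
  chk(is.numeric(d$psi) && d$psi > 0 && d$psi <= 1,
      "diffusion.psi", "must lie in (0, 1]")
  chk(is.numeric(d$kappa) && d$kappa > 0, "diffusion.kappa", "must be > 0")
  chk(is.numeric(d$iterations) && d$iterations >= 1,
      "diffusion.iterations", "must be >= 1")
  t <- cfg$threshold
  chk(is.numeric(t$t0), "threshold.t0", "must be numeric")
  chk(is.numeric(t$tol) && t$tol > 0, "threshold.tol", "must be > 0")
  chk(is.logical(t$fov_only), "threshold.fov_only", "must be logical")
  m <- cfg$mask
  chk(identical(m$green_threshold, "auto") ||
      (is.numeric(m$green_threshold) && m$green_threshold >= 0),
      "mask.green_threshold", "must be >= 0 or 'auto'")
  for (k in c("open_radius", "dilate_radius", "erode_radius"))
    chk(is.numeric(m[[k]]) && m[[k]] >= 1, paste0("mask.", k), "must be >= 1")
  chk(is.logical(m$fill_holes), "mask.fill_holes", "must be logical")
  chk(cfg$od$channel %in% c("red", "green"),
      "od.channel", "must be 'red' or 'green'")
  chk(cfg$od$fill %in% c("zero", "mean"), "od.fill", "must be 'zero' or 'mean'")
  chk(is.numeric(cfg$vessel$line_length) && cfg$vessel$line_length >= 1,
      "vessel.line_length", "must be >= 1")
  chk(cfg$vessel$source %in% c("od_eliminated", "green"),
      "vessel.source", "must be 'od_eliminated' or 'green'")
  p <- cfg$postprocess
  chk(is.numeric(p$s_size) && p$s_size >= 1, "postprocess.s_size",
      "must be >= 1")
  chk(is.numeric(p$min_component) && p$min_component >= 1,
      "postprocess.min_component", "must be >= 1")
  chk(p$connectivity %in% c(4, 8), "postprocess.connectivity",
      "must be 4 or 8")
  chk(p$eq10 %in% c("tophat", "literal"), "postprocess.eq10",
      "must be 'tophat' or 'literal'")
  cfg
}

mergeConfig <- function(base, upd, prefix = "") {
  for (k in names(upd)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% names(base))
      stop("config error: unknown key '", key, "'", call. = FALSE)
    if (is.list(base[[k]])) {
      if (!is.list(upd[[k]]))
        stop("config error: '", key, "' must be a section", call. = FALSE)
      base[[k]] <- mergeConfig(base[[k]], upd[[k]], key)
    } else {
      base[[k]] <- upd[[k]]
    }
  }
  base
}

#' Load and resolve a run configuration
#'
#' Resolution order: \code{\link{defaultConfig}}, then the YAML file (if
#' given), then \code{overrides}. Overrides use dotted keys, e.g.
#' \code{list("diffusion.kappa" = 50)}. Unknown keys raise a config
#' error naming the key; out-of-range values raise one naming key and
#' range.
#'
#' @param path optional path to a YAML configuration file whose structure
#'   mirrors \code{\link{defaultConfig}}.
#' @param overrides named list of dotted-key overrides.
#' @return The fully resolved, validated configuration list.
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  }
  if (length(overrides)) {
    for (key in names(overrides)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      upd <- overrides[[key]]
      for (p in rev(parts)) upd <- stats::setNames(list(upd), p)
      cfg <- mergeConfig(cfg, upd)
    }
  }
  validateConfig(cfg)
}
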