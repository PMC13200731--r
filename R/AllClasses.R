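#' @import methods
NULL

SWC_SOMA <- 1L
SWC_DENDRITE <- 3L

#' NeuriteTree: a rooted 3D dendritic reconstruction
#'
#' Container for a single-cell dendritic reconstruction with SWC semantics:
#' a node table (id, parent, xyz in micrometres, radius in micrometres, kind)
#' rooted at a single soma node. SACs are axonless, so every non-soma node is
#' a dendrite node.
#'
#' Class validity checks only the shape of the node table (columns and types);
#' full structural validation (single root, acyclic connectivity, radii,
#' finite coordinates) is performed by [validateTree()], which returns
#' violations instead of raising, so that defective reconstructions can be
#' inspected.
#'
#' @slot nodes data.frame with columns `id`, `parent` (`NA` for the root),
#'   `x`, `y`, `z`, `radius`, `kind` (`"soma"` or `"dendrite"`).
#' @slot somaId integer id of the soma (root) node.
#' @slot metadata free-form list (cell label, layer `"GCL"`/`"INL"`,
#'   genotype, generator parameters, ...).
#' @seealso [readSWC()], [validateTree()], [genArbor()]
#' @export
setClass("NeuriteTree",
  representation(nodes = "data.frame", somaId = "integer", metadata = "list"),
  prototype(nodes = data.frame(), somaId = NA_integer_, metadata = list())
)

setValidity("NeuriteTree", function(object) {
  need <- c("id", "parent", "x", "y", "z", "radius", "kind")
  if (!all(need %in% names(object@nodes)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (length(object@somaId) != 1L)
    return("somaId must be a single integer")
  if (!is.numeric(object@nodes$id) || anyDuplicated(object@nodes$id))
    return("node ids must be unique numbers")
  TRUE
})

#' Construct a NeuriteTree
#'
#' @param nodes data.frame with columns `id`, `parent`, `x`, `y`, `z`,
#'   `radius`, `kind`. `parent` is `NA` (or `-1`) for the root.
#' @param somaId id of the soma node; defaults to the root of `nodes`.
#' @param metadata free-form list.
#' @param validate if `TRUE` (default), raise an error when
#'   [validateTree()] reports structural violations. Set to `FALSE` to
#'   construct intentionally defective trees for inspection.
#' @return A [NeuriteTree-class] object.
#' @examples
#' nd <- data.frame(id = 1:3, parent = c(NA, 1, 2), x = c(0, 10, 20),
#'                  y = 0, z = 0, radius = c(4, 0.3, 0.3),
#'                  kind = c("soma", "dendrite", "dendrite"))
#' tr <- NeuriteTree(nd)
#' @export
NeuriteTree <- function(nodes, somaId = NULL, metadata = list(),
                        validate = TRUE) {
  nodes <- as.data.frame(nodes)
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$parent[!is.na(nodes$parent) & nodes$parent < 0L] <- NA_integer_
  for (cc in c("x", "y", "z", "radius")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  nodes$kind <- as.character(nodes$kind)
  if (is.null(somaId)) {
    root <- nodes$id[is.na(nodes$parent)]
    somaId <- if (length(root) == 1L) root else NA_integer_
  }
  obj <- new("NeuriteTree", nodes = nodes, somaId = as.integer(somaId),
             metadata = metadata)
  if (validate) {
    v <- validateTree(obj)
    if (length(v))
      stop("invalid NeuriteTree: ", paste(v, collapse = "; "))
  }
  obj
}

#' PointPattern: soma centroids in a rectangular window
#'
#' A planar point pattern of cell-soma xy coordinates (micrometres) together
#' with the rectangular sampling window, for density and mosaic-spacing
#' statistics.
#'
#' @slot x,y numeric coordinates in micrometres.
#' @slot window numeric length-4 `(xmin, xmax, ymin, ymax)` in micrometres.
#' @seealso [genMosaic()], [cellDensity()], [densityRecoveryProfile()],
#'   [regularityIndexRatio()]
#' @export
setClass("PointPattern",
  representation(x = "numeric", y = "numeric", window = "numeric")
)

setValidity("PointPattern", function(object) {
  w <- object@window
  if (length(w) != 4L || !all(is.finite(w)))
    return("window must be finite (xmin, xmax, ymin, ymax)")
  if (w[2] <= w[1] || w[4] <= w[3])
    return("window must have positive area")
  if (length(object@x) != length(object@y))
    return("x and y must have equal length")
  if (length(object@x)) {
    if (any(object@x < w[1] | object@x > w[2] |
            object@y < w[3] | object@y > w[4]))
      return("all points must lie inside the window")
    if (anyDuplicated(round(cbind(object@x, object@y), 9)))
      return("duplicate points (within 1e-9 um)")
  }
  TRUE
})

#' Construct a PointPattern
#'
#' @param x,y numeric coordinates (micrometres).
#' @param window numeric `(xmin, xmax, ymin, ymax)` in micrometres.
#' @return A [PointPattern-class] object.
#' @export
PointPattern <- function(x, y, window) {
  new("PointPattern", x = as.numeric(x), y = as.numeric(y),
      window = as.numeric(window))
}

#' UnitResponse: per-unit spike counts over 12 stimulus directions
#'
#' Spike counts of one sorted unit in response to gratings moving in the 12
#' standard directions (0, 30, ..., 330 degrees, counter-clockwise,
#' 0 = +x), over repeated epochs.
#'
#' @slot unitId character unit label.
#' @slot counts integer matrix, `n_epochs x 12`, column `j` holding counts for
#'   direction `30*(j-1)` degrees.
#' @slot directions the 12 direction angles in degrees.
#' @slot epochDuration stimulus epoch duration in seconds (3 s in the study
#'   design emulated here).
#' @slot meta free-form list (e.g. simulation ground truth).
#' @seealso [readUnitTable()], [genUnitResponses()], [classifyDSGC()]
#' @export
setClass("UnitResponse",
  representation(unitId = "character", counts = "matrix",
                 directions = "numeric", epochDuration = "numeric",
                 meta = "list"),
  prototype(epochDuration = 3, meta = list())
)

setValidity("UnitResponse", function(object) {
  if (!identical(object@directions, seq(0, 330, by = 30)))
    return("directions must be 0, 30, ..., 330 degrees")
  cm <- object@counts
  if (ncol(cm) != 12L) return("counts must have 12 columns")
  if (nrow(cm) < 1L) return("at least one epoch required")
  if (any(!is.finite(cm)) || any(cm < 0) || any(cm != round(cm)))
    return("counts must be non-negative integers")
  if (length(object@epochDuration) != 1L || object@epochDuration <= 0)
    return("epochDuration must be a positive scalar")
  TRUE
})

#' Construct a UnitResponse
#'
#' @param unitId unit label.
#' @param counts `n_epochs x 12` matrix of non-negative integer spike counts;
#'   columns correspond to directions 0, 30, ..., 330 degrees.
#' @param epochDuration epoch duration in seconds.
#' @param meta free-form list.
#' @return A [UnitResponse-class] object.
#' @export
UnitResponse <- function(unitId, counts, epochDuration = 3, meta = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("UnitResponse", unitId = as.character(unitId), counts = counts,
      directions = seq(0, 330, by = 30),
      epochDuration = as.numeric(epochDuration), meta = meta)
}

#' DepthProfile: IPL stratification profile in 20 depth bins
#'
#' Fluorescence mass per depth bin across the inner plexiform layer (IPL),
#' the depth axis divided into 20 equal sections to normalise variance in IPL
#' thickness. Depth 0 is the inner IPL boundary (adjacent to the GCL).
#'
#' @slot bins numeric length-20 intensity fractions, non-negative, summing
#'   to 1.
#' @slot iplBounds the (inner, outer) IPL boundary positions in the source
#'   coordinate system.
#' @slot label free-form label (genotype / retina id).
#' @seealso [binIplProfile()], [bandCompactness()]
#' @export
setClass("DepthProfile",
  representation(bins = "numeric", iplBounds = "numeric", label = "character"),
  prototype(label = "")
)

setValidity("DepthProfile", function(object) {
  if (length(object@bins) != 20L) return("exactly 20 bins required")
  if (any(object@bins < 0)) return("bins must be non-negative")
  if (abs(sum(object@bins) - 1) > 1e-9) return("bins must sum to 1")
  if (length(object@iplBounds) != 2L ||
      object@iplBounds[1] == object@iplBounds[2])
    return("iplBounds must be two distinct positions")
  TRUE
})

#' DSResult: per-unit direction-selectivity metrics and DSGC call
#'
#' All intermediate metrics of the direction-selective ganglion cell (DSGC)
#' classification pipeline for one unit, reported regardless of whether the
#' unit passes the filters.
#'
#' @slot unitId unit label.
#' @slot meanTuning 12 mean spike counts (one per direction).
#' @slot totalSpikes total spike count over all epochs and directions.
#' @slot dsi direction-selective index in `[0, 1]`.
#' @slot vmMu fitted von Mises preferred direction (degrees in `[0, 360)`).
#' @slot vmKappa fitted concentration (>= 0).
#' @slot vmAmplitude,vmBaseline fitted modulation amplitude and baseline
#'   (spikes per epoch).
#' @slot vmFit goodness of fit (R-squared on the 12 mean responses;
#'   `-Inf` sentinel when the fit is undefined or fails).
#' @slot fwhm tuning width (degrees; 360 sentinel when wider than the circle).
#' @slot preferredMeanSpikes mean spikes per epoch at the sampled direction
#'   nearest the fitted preferred direction.
#' @slot spikesPerEpoch mean spikes per (epoch, direction) presentation.
#' @slot isDSGC logical DSGC call.
#' @slot filters named logical vector of the four filter outcomes.
#' @seealso [classifyDSGC()], [dsgcTable()]
#' @export
setClass("DSResult",
  representation(unitId = "character", meanTuning = "numeric",
                 totalSpikes = "numeric", dsi = "numeric", vmMu = "numeric",
                 vmKappa = "numeric", vmAmplitude = "numeric",
                 vmBaseline = "numeric", vmFit = "numeric", fwhm = "numeric",
                 preferredMeanSpikes = "numeric", spikesPerEpoch = "numeric",
                 isDSGC = "logical", filters = "logical")
)
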