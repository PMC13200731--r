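# Accessor generics. Slot access stays behind these everywhere downstream.

#' @rdname NeuriteTree-class
#' @param object,x an object.
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))
#' @rdname NeuriteTree-class
#' @export
setGeneric("somaId", function(x) standardGeneric("somaId"))
#' @rdname NeuriteTree-class
#' @export
setGeneric("treeMetadata", function(x) standardGeneric("treeMetadata"))

#' @rdname PointPattern-class
#' @export
setGeneric("patternCoords", function(x) standardGeneric("patternCoords"))
#' @rdname PointPattern-class
#' @export
setGeneric("patternWindow", function(x) standardGeneric("patternWindow"))
#' @rdname PointPattern-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname UnitResponse-class
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname UnitResponse-class
#' @export
setGeneric("unitCounts", function(x) standardGeneric("unitCounts"))
#' @rdname UnitResponse-class
#' @export
setGeneric("unitDirections", function(x) standardGeneric("unitDirections"))
#' @rdname UnitResponse-class
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))

#' @rdname DepthProfile-class
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))
#' @rdname DepthProfile-class
#' @export
setGeneric("iplBounds", function(x) standardGeneric("iplBounds"))

#' @rdname NeuriteTree-class
#' @export
setMethod("treeNodes", "NeuriteTree", function(x) x@nodes)
#' @rdname NeuriteTree-class
#' @export
setMethod("somaId", "NeuriteTree", function(x) x@somaId)
#' @rdname NeuriteTree-class
#' @export
setMethod("treeMetadata", "NeuriteTree", function(x) x@metadata)

#' @rdname PointPattern-class
#' @export
setMethod("patternCoords", "PointPattern",
          function(x) data.frame(x = x@x, y = x@y))
#' @rdname PointPattern-class
#' @export
setMethod("patternWindow", "PointPattern", function(x) x@window)
#' @rdname PointPattern-class
#' @export
setMethod("nPoints", "PointPattern", function(x) length(x@x))

#' @rdname UnitResponse-class
#' @export
setMethod("unitId", "UnitResponse", function(x) x@unitId)
#' @rdname UnitResponse-class
#' @export
setMethod("unitCounts", "UnitResponse", function(x) x@counts)
#' @rdname UnitResponse-class
#' @export
setMethod("unitDirections", "UnitResponse", function(x) x@directions)
#' @rdname UnitResponse-class
#' @export
setMethod("epochDuration", "UnitResponse", function(x) x@epochDuration)

#' @rdname DepthProfile-class
#' @export
setMethod("profileBins", "DepthProfile", function(x) x@bins)
#' @rdname DepthProfile-class
#' @export
setMethod("iplBounds", "DepthProfile", function(x) x@iplBounds)

setMethod("show", "NeuriteTree", function(object) {
  nd <- object@nodes
  cat("NeuriteTree:", nrow(nd), "nodes, soma id", object@somaId, "\n")
  md <- object@metadata
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PointPattern", function(object) {
  w <- object@window
  cat(sprintf("PointPattern: %d points in [%g, %g] x [%g, %g] um\n",
              length(object@x), w[1], w[2], w[3], w[4]))
})

setMethod("show", "UnitResponse", function(object) {
  cat(sprintf("UnitResponse '%s': %d epochs x 12 directions, %d spikes\n",
              object@unitId, nrow(object@counts), sum(object@counts)))
})

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile (20 bins)",
      if (nzchar(object@label)) paste0("'", object@label, "'") else "", "\n")
  cat("  peak bin:", which.max(object@bins), "\n")
})

setMethod("show", "DSResult", function(object) {
  cat(sprintf(
    "DSResult '%s': DSI %.3f, vmFit %.3f, mu %.1f deg, FWHM %.1f deg, %s\n",
    object@unitId, object@dsi, object@vmFit, object@vmMu, object@fwhm,
    if (object@isDSGC) "DSGC" else "not DSGC"))
})
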