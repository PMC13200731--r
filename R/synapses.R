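# Synaptophysin puncta filtering and compartmentalization along the arbor.

#' Filter raw puncta
#'
#' Keeps puncta that passed the membrane-GFP mask (`in_mask`) and whose
#' largest surface diameter is at least `minSize` micrometres (puncta smaller
#' than 0.5 um are imaging noise and are excluded). Idempotent.
#'
#' @param puncta data.frame with columns `size_um` and `in_mask` (see
#'   [genPuncta()] / [readPuncta()]).
#' @param minSize minimum diameter in micrometres.
#' @return the filtered data.frame.
#' @export
filterPuncta <- function(puncta, minSize = 0.5) {
  puncta[puncta$in_mask & puncta$size_um >= minSize, , drop = FALSE]
}

#' Spatial distribution of puncta along the arbor
#'
#' Computes, for filtered puncta, the distance from the soma (3D Euclidean by
#' default, or geodesic along the arbor via the nearest reconstruction node),
#' the distribution over 10 equal bins of normalized radius (distance divided
#' by the arbor radius, the maximum node distance from the soma), and the
#' fraction in the outer third of the arbor (normalized radius > 2/3) - the
#' compartment holding SAC synaptic outputs. Puncta farther than 1.1x the
#' arbor radius trigger a warning and are clipped into the last bin.
#'
#' Puncta diameters are also summarized as equivalent sphere volumes,
#' `(pi/6) * size^3`.
#'
#' @param puncta filtered puncta data.frame (`x_um`, `y_um`, `z_um`,
#'   `size_um`).
#' @param tree a valid [NeuriteTree-class].
#' @param distanceMode `"euclidean"` (straight-line from the soma) or
#'   `"geodesic"` (path length along the arbor via the nearest node).
#' @return list (a synapse report): `nPuncta`, `meanSize`, `meanVolume`,
#'   `distances`, `meanDistance`, `normalizedDistribution` (10 fractions),
#'   `outerThirdFraction`.
#' @export
punctaDistribution <- function(puncta, tree,
                               distanceMode = c("euclidean", "geodesic")) {
  distanceMode <- match.arg(distanceMode)
  n <- nrow(puncta)
  R <- max(nodeRadialDist(tree))
  if (n == 0)
    return(list(nPuncta = 0L, meanSize = NA_real_, meanVolume = NA_real_,
                distances = numeric(), meanDistance = NA_real_,
                normalizedDistribution = rep(0, 10),
                outerThirdFraction = NA_real_))
  s <- somaXYZ(tree)
  if (distanceMode == "euclidean") {
    d <- sqrt((puncta$x_um - s["x"])^2 + (puncta$y_um - s["y"])^2 +
              (puncta$z_um - s["z"])^2)
  } else {
    d <- geodesicDistances(puncta, tree)
    R <- maxGeodesicRadius(tree)
  }
  nr <- d / R
  if (any(nr > 1.1)) {
    warning(sum(nr > 1.1), " puncta farther than 1.1x the arbor radius; ",
            "clipped to the last bin")
  }
  nrClip <- pmin(nr, 1)
  idx <- pmax(1L, pmin(10L, ceiling(nrClip * 10)))
  distr <- tabulate(idx, 10) / n
  list(nPuncta = n,
       meanSize = mean(puncta$size_um),
       meanVolume = mean(pi / 6 * puncta$size_um^3),
       distances = d,
       meanDistance = mean(d),
       normalizedDistribution = distr,
       outerThirdFraction = mean(nr > 2 / 3))
}

# path length from every node to the soma
nodePathLength <- function(tree) {
  nd <- treeNodes(tree)
  ed <- treeEdges(tree)
  plen <- stats::setNames(rep(NA_real_, nrow(nd)), nd$id)
  plen[as.character(somaId(tree))] <- 0
  # node table from readSWC/genArbor is topologically ordered in practice,
  # but do not rely on it
  remaining <- ed
  while (nrow(remaining)) {
    ready <- !is.na(plen[as.character(remaining$parentId)])
    if (!any(ready)) stop("tree is not connected")
    done <- remaining[ready, , drop = FALSE]
    plen[as.character(done$childId)] <-
      plen[as.character(done$parentId)] + done$length
    remaining <- remaining[!ready, , drop = FALSE]
  }
  plen
}

maxGeodesicRadius <- function(tree) max(nodePathLength(tree))

geodesicDistances <- function(puncta, tree) {
  nd <- treeNodes(tree)
  plen <- nodePathLength(tree)
  vapply(seq_len(nrow(puncta)), function(i) {
    d2 <- (nd$x - puncta$x_um[i])^2 + (nd$y - puncta$y_um[i])^2 +
          (nd$z - puncta$z_um[i])^2
    j <- which.min(d2)
    plen[as.character(nd$id[j])] + sqrt(d2[j])
  }, numeric(1))
}
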