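# Single-cell dendritic morphometrics, en-face (xy) conventions throughout:
# SACs are planar and imaged in flat mounts, so Sholl circles and field area
# are evaluated in the xy projection, while lengths and distances are 3D.

#' Total dendrite length
#'
#' Sum of the Euclidean (3D) lengths of all parent-child edges. The soma is a
#' single node, so no edge is internal to it.
#'
#' @param tree a valid [NeuriteTree-class].
#' @return length in micrometres.
#' @export
totalDendriteLength <- function(tree) {
  sum(treeEdges(tree)$length)
}

#' Number of branch points
#'
#' Non-soma nodes with two or more children. The soma is excluded regardless
#' of how many primary dendrites it bears: primary dendrites do not create a
#' branch point.
#'
#' @param tree a valid [NeuriteTree-class].
#' @return integer count.
#' @export
countBranchPoints <- function(tree) {
  nd <- treeNodes(tree)
  par <- nd$parent[!is.na(nd$parent)]
  tab <- table(par)
  bp <- as.integer(names(tab)[tab >= 2L])
  sum(bp != somaId(tree))
}

#' Branch-level histogram
#'
#' A branch is a maximal unbranched path between the soma, a branch point, or
#' a tip; its level is 1 plus the number of branch points strictly between it
#' and the soma (primary dendrites are level 1, the Imaris convention).
#'
#' @param tree a valid [NeuriteTree-class].
#' @return named integer vector: level -> branch count.
#' @export
branchLevelHistogram <- function(tree) {
  br <- branchDecomposition(tree)
  lv <- vapply(br, function(b) b$level, integer(1))
  tab <- table(factor(lv, levels = seq_len(max(lv))))
  stats::setNames(as.integer(tab), names(tab))
}

# crossing count of each edge (xy projection) with a circle of radius r
# centred on the soma: 1 for a transversal in/out edge, 2 for a re-entrant
# edge whose interior dips inside the circle, 0 otherwise.
shollCrossings <- function(d0, d1, dmin, r) {
  transversal <- (d0 < r) != (d1 < r)
  reentrant <- !transversal & d0 >= r & d1 >= r & dmin < r
  as.integer(transversal) + 2L * as.integer(reentrant)
}

#' Sholl analysis (1-micron circles, 10 percent radial normalization)
#'
#' Counts dendrite crossings of concentric circles about the soma in the xy
#' projection (the en-face flat-mount convention), at radii `step, 2*step,
#' ...` strictly inside the arbor radius `R` (the maximum node distance from
#' the soma). A re-entrant edge crossing a circle twice counts each sign
#' change. The normalized profile averages the raw counts over ten equal
#' radial bins `((k-1)R/10, kR/10]`; empty bins contribute 0.
#'
#' @param tree a valid [NeuriteTree-class].
#' @param step circle spacing in micrometres.
#' @return list with `radii`, `raw` (crossings per radius), `normalized`
#'   (10 values), and `arborRadius`.
#' @export
shollAnalysis <- function(tree, step = 1) {
  dists <- nodeRadialDist(tree, xyOnly = TRUE)
  R <- max(dists)
  if (R <= 0) stop("arbor radius is zero: tree has no extent")
  radii <- seq(step, R, by = step)
  radii <- radii[radii < R]
  if (!length(radii))
    stop("no Sholl radii strictly inside the arbor radius; reduce step")
  ed <- treeEdges(tree)
  s <- somaXYZ(tree)
  ax <- ed$x0 - s["x"]; ay <- ed$y0 - s["y"]
  bx <- ed$x1 - s["x"]; by <- ed$y1 - s["y"]
  d0 <- sqrt(ax^2 + ay^2)
  d1 <- sqrt(bx^2 + by^2)
  # min distance from the soma to each segment (xy)
  vx <- bx - ax; vy <- by - ay
  vv <- vx^2 + vy^2
  t <- ifelse(vv > 0, pmax(0, pmin(1, -(ax * vx + ay * vy) / vv)), 0)
  dmin <- sqrt((ax + t * vx)^2 + (ay + t * vy)^2)
  raw <- vapply(radii, function(r) sum(shollCrossings(d0, d1, dmin, r)),
                numeric(1))
  binIdx <- pmin(10L, ceiling(radii / (R / 10)))
  normalized <- vapply(1:10, function(k) {
    v <- raw[binIdx == k]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  list(radii = radii, raw = raw, normalized = normalized, arborRadius = R)
}

#' Dendritic field area (convex hull)
#'
#' Area of the 2D convex hull of all node xy positions, the en-face dendritic
#' field area.
#'
#' @param tree a valid [NeuriteTree-class] with at least 3 non-collinear
#'   nodes.
#' @return area in square micrometres.
#' @export
fieldAreaConvexHull <- function(tree) {
  nd <- treeNodes(tree)
  if (nrow(nd) < 3L) stop("need at least 3 nodes for a convex hull")
  h <- grDevices::chull(nd$x, nd$y)
  if (length(h) < 3L) stop("nodes are collinear: hull is degenerate")
  a <- shoelaceArea(nd$x[h], nd$y[h])
  if (a <= 0) stop("nodes are collinear: hull is degenerate")
  a
}

shoelaceArea <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Count dendritic self-crossings within a z slab
#'
#' Counts unordered pairs of edges that share no node, whose xy projections
#' properly intersect, and whose interpolated z values at the crossing point
#' differ by at most `zTolerance` (the continuous analogue of counting
#' crossings in single z planes of a stack).
#'
#' @param tree a valid [NeuriteTree-class].
#' @param zTolerance z tolerance in micrometres: a crossing is counted when
#'   `|z1 - z2| <= zTolerance` at the xy intersection.
#' @return integer count.
#' @export
countSelfCrossings <- function(tree, zTolerance = 1) {
  ed <- treeEdges(tree)
  n <- nrow(ed)
  if (n < 2L) return(0L)
  total <- 0L
  # bounding-box prefilter then proper-intersection test, vectorised over the
  # partner edges of each edge
  xlo <- pmin(ed$x0, ed$x1); xhi <- pmax(ed$x0, ed$x1)
  ylo <- pmin(ed$y0, ed$y1); yhi <- pmax(ed$y0, ed$y1)
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    j <- j[xlo[j] <= xhi[i] & xhi[j] >= xlo[i] &
           ylo[j] <= yhi[i] & yhi[j] >= ylo[i]]
    if (!length(j)) next
    # exclude pairs sharing a node
    share <- ed$childId[j] == ed$childId[i] |
      ed$childId[j] == ed$parentId[i] |
      ed$parentId[j] == ed$childId[i] |
      ed$parentId[j] == ed$parentId[i]
    j <- j[!share]
    if (!length(j)) next
    d1 <- cross2(ed$x0[i], ed$y0[i], ed$x1[i], ed$y1[i], ed$x0[j], ed$y0[j])
    d2 <- cross2(ed$x0[i], ed$y0[i], ed$x1[i], ed$y1[i], ed$x1[j], ed$y1[j])
    d3 <- cross2(ed$x0[j], ed$y0[j], ed$x1[j], ed$y1[j], ed$x0[i], ed$y0[i])
    d4 <- cross2(ed$x0[j], ed$y0[j], ed$x1[j], ed$y1[j], ed$x1[i], ed$y1[i])
    proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
    k <- j[proper]
    if (!length(k)) next
    # intersection parameter on edge i against each partner, then z gap
    d1k <- d1[proper]; d2k <- d2[proper]
    # parameter along edge k where edge i's line crosses it
    tk <- d1k / (d1k - d2k)
    zk <- ed$z0[k] + tk * (ed$z1[k] - ed$z0[k])
    d3k <- d3[proper]; d4k <- d4[proper]
    ti <- d3k / (d3k - d4k)
    zi <- ed$z0[i] + ti * (ed$z1[i] - ed$z0[i])
    total <- total + sum(abs(zi - zk) <= zTolerance)
  }
  as.integer(total)
}

#' Detect hypertrophic dendrites
#'
#' The caliber of a branch is the median over its nodes of twice the node
#' radius (node diameters); a cell is flagged hypertrophic iff any branch
#' caliber strictly exceeds `caliberThreshold` (a dendrite *greater than*
#' 1 micrometre in caliber is hypertrophic).
#'
#' @param tree a valid [NeuriteTree-class] with radii.
#' @param caliberThreshold caliber threshold in micrometres.
#' @return list with `hypertrophic` (logical) and `branchIds` (terminal node
#'   id of each flagged branch).
#' @export
classifyHypertrophic <- function(tree, caliberThreshold = 1) {
  br <- branchDecomposition(tree)
  nd <- treeNodes(tree)
  cal <- vapply(br, function(b)
    stats::median(2 * nd$radius[match(b$nodeIds, nd$id)]), numeric(1))
  flag <- cal > caliberThreshold
  list(hypertrophic = any(flag),
       branchIds = vapply(br[flag], function(b) b$endId, integer(1)))
}

#' Soma area from an outline polygon
#'
#' Absolute shoelace area of a simple polygon of soma outline vertices.
#'
#' @param polygon matrix or data.frame of xy vertices (>= 3), in order.
#' @return area in square micrometres.
#' @export
somaArea <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- length(x)
  # reject self-intersecting outlines: any proper crossing between
  # non-adjacent edges
  ex0 <- x; ey0 <- y
  ex1 <- x[c(2:n, 1)]; ey1 <- y[c(2:n, 1)]
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      d1 <- cross2(ex0[i], ey0[i], ex1[i], ey1[i], ex0[j], ey0[j])
      d2 <- cross2(ex0[i], ey0[i], ex1[i], ey1[i], ex1[j], ey1[j])
      d3 <- cross2(ex0[j], ey0[j], ex1[j], ey1[j], ex0[i], ey0[i])
      d4 <- cross2(ex0[j], ey0[j], ex1[j], ey1[j], ex1[i], ey1[i])
      if (d1 * d2 < 0 && d3 * d4 < 0)
        stop("polygon is self-intersecting")
    }
  }
  shoelaceArea(x, y)
}

#' Full morphometry report for one cell
#'
#' Bundles every single-cell morphometric: total dendrite length, branch
#' points, branch-level histogram, raw and 10-bin normalized Sholl profiles,
#' convex-hull field area, self-crossing count, soma area (equivalent circle
#' from the soma-node radius) and the hypertrophic-dendrite call.
#'
#' @param tree a valid [NeuriteTree-class].
#' @param shollStep Sholl circle spacing (micrometres).
#' @param zTolerance self-crossing z slab (micrometres).
#' @param caliberThreshold hypertrophic caliber threshold (micrometres).
#' @return named list (a morphometry report).
#' @export
morphometryReport <- function(tree, shollStep = 1, zTolerance = 1,
                              caliberThreshold = 1) {
  sh <- shollAnalysis(tree, step = shollStep)
  hy <- classifyHypertrophic(tree, caliberThreshold = caliberThreshold)
  nd <- treeNodes(tree)
  somaR <- nd$radius[match(somaId(tree), nd$id)]
  list(
    totalLength = totalDendriteLength(tree),
    nBranchPoints = countBranchPoints(tree),
    branchLevelHistogram = branchLevelHistogram(tree),
    shollRadii = sh$radii,
    shollRaw = sh$raw,
    shollNormalized = sh$normalized,
    arborRadius = sh$arborRadius,
    fieldArea = fieldAreaConvexHull(tree),
    nSelfCrossings = countSelfCrossings(tree, zTolerance = zTolerance),
    somaArea = pi * somaR^2,
    hypertrophic = hy$hypertrophic,
    hypertrophicBranchIds = hy$branchIds
  )
}
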