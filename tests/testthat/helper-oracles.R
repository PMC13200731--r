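# Independent oracles: deliberately different algorithms from the package
# implementations, used to cross-check results on small inputs.

# Sholl crossings by explicit quadratic root counting: intersections of each
# segment with the circle of radius r about the soma, counting parameter
# roots strictly inside (0, 1).
oracleSholl <- function(tree, radii) {
  ed <- treeEdges2(tree)
  s <- oracleSoma(tree)
  ax <- ed$x0 - s[1]; ay <- ed$y0 - s[2]
  vx <- ed$x1 - ed$x0; vy <- ed$y1 - ed$y0
  a <- vx^2 + vy^2
  b <- 2 * (ax * vx + ay * vy)
  vapply(radii, function(r) {
    cc <- ax^2 + ay^2 - r^2
    disc <- b^2 - 4 * a * cc
    n <- integer(length(a))
    pos <- which(disc > 0 & a > 0)
    if (length(pos)) {
      sq <- sqrt(disc[pos])
      t1 <- (-b[pos] - sq) / (2 * a[pos])
      t2 <- (-b[pos] + sq) / (2 * a[pos])
      n[pos] <- (t1 > 0 & t1 < 1) + (t2 > 0 & t2 < 1)
    }
    sum(n)
  }, numeric(1))
}

# re-derive the edge table without using package internals
treeEdges2 <- function(tree) {
  nd <- treeNodes(tree)
  ch <- nd[!is.na(nd$parent), ]
  pi <- match(ch$parent, nd$id)
  data.frame(childId = ch$id, parentId = ch$parent,
             x0 = nd$x[pi], y0 = nd$y[pi], z0 = nd$z[pi],
             x1 = ch$x, y1 = ch$y, z1 = ch$z)
}

oracleSoma <- function(tree) {
  nd <- treeNodes(tree)
  i <- match(somaId(tree), nd$id)
  c(nd$x[i], nd$y[i], nd$z[i])
}

# Convex hull area via Andrew's monotone chain (independent of grDevices)
oracleHullArea <- function(x, y) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  n <- length(x)
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(x[h[length(h) - 1]], y[h[length(h) - 1]],
                   x[h[length(h)]], y[h[length(h)]], x[i], y[i]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  hx <- x[hull]; hy <- y[hull]
  m <- length(hx)
  j <- c(m, seq_len(m - 1))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# Self-crossings by parametric 2x2 linear solves over all edge pairs
oracleSelfCrossings <- function(tree, zTol = 1) {
  ed <- treeEdges2(tree)
  n <- nrow(ed)
  if (n < 2) return(0L)
  ux <- ed$x1 - ed$x0; uy <- ed$y1 - ed$y0; uz <- ed$z1 - ed$z0
  total <- 0L
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    adj <- ed$childId[j] == ed$childId[i] |
      ed$childId[j] == ed$parentId[i] |
      ed$parentId[j] == ed$childId[i] |
      ed$parentId[j] == ed$parentId[i]
    j <- j[!adj]
    if (!length(j)) next
    det <- ux[i] * (-uy[j]) - uy[i] * (-ux[j])
    rx <- ed$x0[j] - ed$x0[i]; ry <- ed$y0[j] - ed$y0[i]
    ok <- abs(det) > 1e-12
    t <- (rx * (-uy[j]) - ry * (-ux[j])) / det
    s <- (ux[i] * ry - uy[i] * rx) / det
    hit <- ok & t > 0 & t < 1 & s > 0 & s < 1
    if (any(hit)) {
      zi <- ed$z0[i] + t[hit] * uz[i]
      zj <- ed$z0[j][hit] + s[hit] * uz[j][hit]
      total <- total + sum(abs(zi - zj) <= zTol)
    }
  }
  as.integer(total)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration
oracleFisherP <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Mean of a Gaussian band over each of 20 depth bins, by direct integration
oracleGaussianBins <- function(centers, sigma, amplitudes) {
  v <- vapply(1:20, function(k) {
    lo <- (k - 1) / 20; hi <- k / 20
    sum(amplitudes * sigma * sqrt(2 * pi) *
          (stats::pnorm(hi, centers, sigma) -
           stats::pnorm(lo, centers, sigma))) / (1 / 20)
  }, numeric(1))
  v / sum(v)
}

circularGapDeg <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

# small hand-built trees used across test files
chainTree <- function(n = 5, step = 1) {
  nd <- data.frame(id = 1:(n + 1), parent = c(NA, 1:n),
                   x = seq(0, n * step, by = step), y = 0, z = 0,
                   radius = c(4, rep(0.3, n)),
                   kind = c("soma", rep("dendrite", n)))
  NeuriteTree(nd)
}

# soma with one trunk to (len1, 0), then a symmetric Y whose tips sit
# exactly at radial distance len2 from the soma
yTree <- function(len1 = 50, len2 = 100, tipAngleDeg = 20) {
  a <- tipAngleDeg * pi / 180
  nd <- data.frame(
    id = 1:4, parent = c(NA, 1, 2, 2),
    x = c(0, len1, len2 * cos(a), len2 * cos(a)),
    y = c(0, 0, len2 * sin(a), -len2 * sin(a)),
    z = 0, radius = c(4, 0.3, 0.3, 0.3),
    kind = c("soma", rep("dendrite", 3)))
  NeuriteTree(nd)
}
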