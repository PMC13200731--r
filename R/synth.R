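# Synthetic-data generators. Every generator is a pure function of its
# arguments (seed included) and leaves the caller's RNG stream untouched.

# Effective exponent of the compounding branching law B = n((1+p)^L - 1):
# branching opportunities per soma-to-tip path. Daughter headings diverge
# from the radial direction, so paths take slightly more steps than
# field_radius / segment_length; the constant was fixed once from the growth
# geometry (see vignette).
arborPathSteps <- function(fieldRadius, meanSegmentLength) {
  1.15 * fieldRadius / meanSegmentLength
}

#' Generate a SAC-like radial dendritic arbor
#'
#' Grows a radially symmetric, essentially planar dendritic tree emulating a
#' starburst amacrine cell: `nPrimary` trunks leave the soma at evenly spaced
#' angles (plus jitter), segments of about `meanSegmentLength` micrometres
#' extend outward with small angular noise, every surviving tip bifurcates
#' with probability `branchProb` per segment, and growth stops at
#' `fieldRadius`. Node radii encode a caliber of `baseCaliber` tapering
#' distally.
#'
#' The `"pten_ko"` phenotype multiplies the *expected branch-point count* by
#' `koBranchMultiplier` (the per-segment bifurcation probability is solved
#' from the compounding growth law, so the mean branch-point ratio between
#' phenotypes equals the multiplier) while the field radius is unchanged, and
#' one primary dendrite is made hypertrophic (`koHypertrophicCaliber`).
#' The control default of `branchProb` is calibrated so that mean branch
#' points per cell are close to 115 and mean total dendrite length falls in
#' the 4100-5900 micrometre range typical of reconstructed SACs.
#'
#' @param phenotype `"control"` or `"pten_ko"`.
#' @param nPrimary number of primary dendrites (trunks), typically 3-5.
#' @param fieldRadius arbor radius in micrometres.
#' @param meanSegmentLength mean segment length in micrometres.
#' @param branchProb per-segment bifurcation probability of the control
#'   phenotype.
#' @param koBranchMultiplier factor applied to the expected branch-point
#'   count in the `"pten_ko"` phenotype.
#' @param baseCaliber,koHypertrophicCaliber dendrite calibers (diameters,
#'   micrometres) of normal and hypertrophic dendrites.
#' @param somaRadius equivalent-circle soma radius in micrometres.
#' @param zJitter half-range of the uniform z jitter in micrometres (SAC
#'   arbors are planar; jitter exercises the z-slab self-crossing logic).
#' @param angularNoise s.d. (radians) of the per-segment heading noise.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A validated [NeuriteTree-class] with phenotype, layer and seed in
#'   its metadata.
#' @examples
#' tr <- genArbor(seed = 1)
#' countBranchPoints(tr)
#' @export
genArbor <- function(phenotype = c("control", "pten_ko"),
                     nPrimary = 4, fieldRadius = 120,
                     meanSegmentLength = 12, branchProb = 0.41,
                     koBranchMultiplier = 1.7,
                     baseCaliber = 0.6, koHypertrophicCaliber = 1.4,
                     somaRadius = 4.3, zJitter = 0.4,
                     angularNoise = 0.25, seed = NULL) {
  phenotype <- match.arg(phenotype)
  if (nPrimary < 1) stop("nPrimary must be >= 1")
  if (fieldRadius <= 0) stop("fieldRadius must be positive")
  if (fieldRadius < meanSegmentLength)
    stop("cannot place ", nPrimary, " trunks: fieldRadius smaller than one ",
         "segment")
  if (branchProb < 0 || branchProb > 1)
    stop("branchProb must be a probability")
  if (koBranchMultiplier < 1) stop("koBranchMultiplier must be >= 1")

  L <- arborPathSteps(fieldRadius, meanSegmentLength)
  p <- branchProb
  if (phenotype == "pten_ko" && p > 0) {
    bCtrl <- (1 + p)^L - 1
    p <- (koBranchMultiplier * bCtrl + 1)^(1 / L) - 1
    if (p > 1) stop("koBranchMultiplier too large for this branchProb")
  }

  withSeed(seed, {
    ids <- 1L
    nodes <- list(list(id = 1L, parent = NA_integer_, x = 0, y = 0, z = 0,
                       radius = somaRadius, kind = "soma"))
    taperR <- function(d) {
      (baseCaliber / 2) * (1 - 0.3 * pmin(1, d / fieldRadius))
    }
    trunkAngles <- 2 * pi * (seq_len(nPrimary) - 1) / nPrimary +
      stats::rnorm(nPrimary, 0, 0.08)
    # tips: list of (nodeId of attachment, heading, trunk)
    tips <- lapply(seq_len(nPrimary), function(k)
      list(at = 1L, heading = trunkAngles[k], trunk = k))
    pos <- matrix(0, 1, 3)  # grows with nodes; row i = node i
    while (length(tips)) {
      newTips <- list()
      for (tp in tips) {
        from <- pos[tp$at, ]
        len <- meanSegmentLength * stats::runif(1, 0.85, 1.15)
        # heading pulled back toward the radial direction keeps the arbor
        # radially symmetric without long-range curl
        radial <- if (all(from[1:2] == 0)) tp$heading
                  else atan2(from[2], from[1])
        heading <- radial + stats::rnorm(1, 0, angularNoise)
        nxy <- from[1:2] + len * c(cos(heading), sin(heading))
        nz <- stats::runif(1, -zJitter, zJitter)
        ids <- ids + 1L
        d <- sqrt(sum(nxy^2))
        nodes[[ids]] <- list(id = ids, parent = tp$at,
                             x = nxy[1], y = nxy[2], z = nz,
                             radius = taperR(d), kind = "dendrite")
        pos <- rbind(pos, c(nxy, nz))
        if (d < fieldRadius) {
          if (stats::runif(1) < p) {
            off <- stats::runif(1, 0.25, 0.45)
            newTips[[length(newTips) + 1L]] <-
              list(at = ids, heading = heading + off, trunk = tp$trunk)
            newTips[[length(newTips) + 1L]] <-
              list(at = ids, heading = heading - off, trunk = tp$trunk)
          } else {
            newTips[[length(newTips) + 1L]] <-
              list(at = ids, heading = heading, trunk = tp$trunk)
          }
        }
      }
      tips <- newTips
    }
    nd <- do.call(rbind, lapply(nodes, as.data.frame))
    tree <- NeuriteTree(nd, somaId = 1L,
                        metadata = list(phenotype = phenotype, layer = "GCL",
                                        seed = seed))
    if (phenotype == "pten_ko") {
      # one primary dendrite becomes hypertrophic: constant thick caliber
      # along the first level-1 branch
      br <- branchDecomposition(tree)
      lvl1 <- Filter(function(b) b$level == 1L, br)
      pick <- lvl1[[sample.int(length(lvl1), 1)]]
      nd <- treeNodes(tree)
      nd$radius[nd$id %in% pick$nodeIds] <- koHypertrophicCaliber / 2
      tree <- NeuriteTree(nd, somaId = 1L, metadata = treeMetadata(tree))
    }
    tree
  })
}

#' Generate a soma mosaic (random or exclusion-zone)
#'
#' `mode = "random"` draws a homogeneous Poisson realisation in the window
#' (the point count is Poisson with mean intensity x area). `mode =
#' "exclusion"` draws a simple sequential-inhibition (hard-core) pattern:
#' uniform candidates are rejected when they fall within `exclusionRadius` of
#' an accepted point, until `round(intensity x area)` points are placed.
#'
#' @param mode `"random"` or `"exclusion"`.
#' @param intensity target intensity in cells per mm^2.
#' @param exclusionRadius hard-core distance in micrometres (exclusion mode).
#' @param window `(xmin, xmax, ymin, ymax)` in micrometres.
#' @param maxAttemptsPerPoint proposal budget per requested point before the
#'   packing is declared infeasible.
#' @param seed integer seed.
#' @return A [PointPattern-class].
#' @examples
#' pp <- genMosaic("exclusion", seed = 1)
#' min(dist(patternCoords(pp)))  # >= 25
#' @export
genMosaic <- function(mode = c("random", "exclusion"), intensity = 800,
                      exclusionRadius = 25, window = c(0, 500, 0, 500),
                      maxAttemptsPerPoint = 1000, seed = NULL) {
  mode <- match.arg(mode)
  if (intensity <= 0) stop("intensity must be positive")
  if (exclusionRadius < 0) stop("exclusionRadius must be >= 0")
  areaMm2 <- (window[2] - window[1]) * (window[4] - window[3]) / 1e6
  if (areaMm2 <= 0) stop("window must have positive area")
  withSeed(seed, {
    if (mode == "random") {
      n <- stats::rpois(1, intensity * areaMm2)
      PointPattern(stats::runif(n, window[1], window[2]),
                   stats::runif(n, window[3], window[4]), window)
    } else {
      n <- round(intensity * areaMm2)
      x <- numeric(n); y <- numeric(n)
      placed <- 0L
      attempts <- 0L
      budget <- maxAttemptsPerPoint * n
      r2 <- exclusionRadius^2
      while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > budget)
          stop("exclusion packing infeasible: placed ", placed, " of ", n,
               " points in ", budget, " attempts")
        cx <- stats::runif(1, window[1], window[2])
        cy <- stats::runif(1, window[3], window[4])
        if (placed == 0L ||
            all((x[seq_len(placed)] - cx)^2 +
                (y[seq_len(placed)] - cy)^2 >= r2)) {
          placed <- placed + 1L
          x[placed] <- cx; y[placed] <- cy
        }
      }
      PointPattern(x, y, window)
    }
  })
}

#' Generate a raw IPL fluorescence depth profile
#'
#' Produces dense intensity-versus-position samples emulating a two-band SAC
#' stratification profile: the sum of Gaussian bands centred at the given
#' normalized IPL depths plus non-negative noise.
#'
#' @param bandCenters band centres as IPL-depth fractions in (0, 1); two
#'   bands (S2 and S4) by default.
#' @param bandSigma band width (s.d.) as a depth fraction.
#' @param amplitudes per-band peak amplitudes.
#' @param noiseSd s.d. of the half-normal intensity noise.
#' @param nSamples number of samples across the IPL span.
#' @param iplBounds (inner, outer) IPL boundary positions in source
#'   coordinates; samples are generated across this span.
#' @param seed integer seed.
#' @return list with `samples` (data.frame `position`, `intensity`) and
#'   `iplBounds`.
#' @export
genDepthProfile <- function(bandCenters = c(0.27, 0.62), bandSigma = 0.05,
                            amplitudes = rep(1, length(bandCenters)),
                            noiseSd = 0.03, nSamples = 400,
                            iplBounds = c(0, 50), seed = NULL) {
  if (any(bandCenters <= 0 | bandCenters >= 1))
    stop("bandCenters must lie in (0, 1)")
  if (bandSigma <= 0) stop("bandSigma must be positive")
  withSeed(seed, {
    pos <- seq(iplBounds[1], iplBounds[2], length.out = nSamples)
    depth <- (pos - iplBounds[1]) / (iplBounds[2] - iplBounds[1])
    intensity <- rowSums(vapply(seq_along(bandCenters), function(i)
      amplitudes[i] * exp(-(depth - bandCenters[i])^2 / (2 * bandSigma^2)),
      numeric(nSamples)))
    if (noiseSd > 0)
      intensity <- intensity + abs(stats::rnorm(nSamples, 0, noiseSd))
    list(samples = data.frame(position = pos, intensity = intensity),
         iplBounds = iplBounds)
  })
}

#' Generate MEA unit responses (DS / non-DS mixture)
#'
#' Simulates sorted units responding to gratings moving in the 12 standard
#' directions. A fraction of units is direction selective (DS): their
#' per-epoch counts are Poisson with mean
#' `baseline + (preferred - baseline) * exp(kappa * (cos(theta - mu) - 1))`.
#' Non-DS units are Poisson at a direction-independent rate.
#'
#' @param nUnits number of units.
#' @param dsFraction fraction of DS units.
#' @param kappa von Mises concentration of DS units.
#' @param preferredDeg preferred direction in degrees, or `"uniform"` to draw
#'   one uniformly per DS unit.
#' @param meanPreferredSpikes mean spikes per epoch in the preferred
#'   direction of DS units.
#' @param baselineSpikes DS-unit baseline spikes per epoch.
#' @param nondsMeanSpikes direction-independent mean spikes per epoch of
#'   non-DS units.
#' @param nEpochs epochs per direction.
#' @param epochDuration epoch duration in seconds.
#' @param seed integer seed.
#' @return list of [UnitResponse-class]; each unit's `meta` records the
#'   simulation ground truth (`ds`, `preferredDeg`, `kappa`).
#' @export
genUnitResponses <- function(nUnits = 60, dsFraction = 0.15, kappa = 2,
                             preferredDeg = "uniform",
                             meanPreferredSpikes = 20, baselineSpikes = 2,
                             nondsMeanSpikes = 3, nEpochs = 30,
                             epochDuration = 3, seed = NULL) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (nEpochs < 1) stop("nEpochs must be >= 1")
  if (meanPreferredSpikes < 0 || baselineSpikes < 0 || nondsMeanSpikes < 0)
    stop("rates must be >= 0")
  dirs <- seq(0, 330, by = 30)
  withSeed(seed, {
    nDS <- round(nUnits * dsFraction)
    isDS <- seq_len(nUnits) <= nDS
    lapply(seq_len(nUnits), function(i) {
      if (isDS[i]) {
        mu <- if (identical(preferredDeg, "uniform"))
          stats::runif(1, 0, 360) else as.numeric(preferredDeg)
        lam <- baselineSpikes + (meanPreferredSpikes - baselineSpikes) *
          exp(kappa * (cos((dirs - mu) * pi / 180) - 1))
        meta <- list(ds = TRUE, preferredDeg = mu, kappa = kappa)
      } else {
        lam <- rep(nondsMeanSpikes, 12)
        meta <- list(ds = FALSE)
      }
      cnt <- matrix(stats::rpois(nEpochs * 12, rep(lam, each = nEpochs)),
                    nEpochs, 12)
      UnitResponse(sprintf("u%03d", i), cnt, epochDuration = epochDuration,
                   meta = meta)
    })
  })
}

#' Generate synaptic puncta on a dendritic arbor
#'
#' Places puncta on points of the tree whose radial distance from the soma
#' exceeds `innerExclusionFraction` of the arbor radius, emulating the
#' compartmentalization of SAC synaptic outputs to the outer third of the
#' arbor. A configurable fraction of decoys (off-mask or undersized puncta,
#' placed anywhere on the arbor) exercises the puncta filter.
#'
#' @param tree a valid [NeuriteTree-class].
#' @param n total number of puncta (decoys included).
#' @param innerExclusionFraction inner exclusion zone as a fraction of the
#'   arbor radius, in `[0, 1)`.
#' @param sizeMean,sizeSd punctum diameter distribution (micrometres,
#'   truncated positive).
#' @param decoyFraction fraction of `n` emitted as decoys
#'   (`round(decoyFraction * n)` exactly).
#' @param seed integer seed.
#' @return data.frame with columns `x_um`, `y_um`, `z_um`, `size_um`,
#'   `in_mask`, `decoy`.
#' @export
genPuncta <- function(tree, n = 700, innerExclusionFraction = 2 / 3,
                      sizeMean = 0.8, sizeSd = 0.15, decoyFraction = 0,
                      seed = NULL) {
  if (innerExclusionFraction < 0 || innerExclusionFraction >= 1)
    stop("innerExclusionFraction must be in [0, 1)")
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      size_um = numeric(), in_mask = logical(),
                      decoy = logical())
  if (n == 0) return(empty)
  # dense candidate points along all edges (0.5 um spacing)
  ed <- treeEdges(tree)
  if (!nrow(ed)) stop("tree has no dendritic points")
  step <- 0.5
  cand <- do.call(rbind, lapply(seq_len(nrow(ed)), function(i) {
    k <- max(1L, ceiling(ed$length[i] / step))
    t <- seq_len(k) / k
    cbind(ed$x0[i] + t * (ed$x1[i] - ed$x0[i]),
          ed$y0[i] + t * (ed$y1[i] - ed$y0[i]),
          ed$z0[i] + t * (ed$z1[i] - ed$z0[i]))
  }))
  s <- somaXYZ(tree)
  dist <- sqrt((cand[, 1] - s["x"])^2 + (cand[, 2] - s["y"])^2 +
               (cand[, 3] - s["z"])^2)
  R <- max(nodeRadialDist(tree))
  outer <- which(dist > innerExclusionFraction * R)
  if (!length(outer))
    stop("no tree points beyond the inner exclusion fraction")
  withSeed(seed, {
    nDecoy <- round(decoyFraction * n)
    nReal <- n - nDecoy
    drawSize <- function(k) {
      sz <- stats::rnorm(k, sizeMean, sizeSd)
      while (any(sz <= 0)) sz[sz <= 0] <- stats::rnorm(sum(sz <= 0),
                                                       sizeMean, sizeSd)
      sz
    }
    ri <- sample(outer, nReal, replace = TRUE)
    real <- data.frame(x_um = cand[ri, 1], y_um = cand[ri, 2],
                       z_um = cand[ri, 3], size_um = drawSize(nReal),
                       in_mask = TRUE, decoy = FALSE)
    if (nDecoy > 0) {
      di <- sample(nrow(cand), nDecoy, replace = TRUE)
      undersized <- stats::runif(nDecoy) < 0.5
      # off-mask decoys keep a plausible size; undersized decoys stay in mask
      dec <- data.frame(
        x_um = cand[di, 1], y_um = cand[di, 2], z_um = cand[di, 3],
        size_um = ifelse(undersized, stats::runif(nDecoy, 0.2, 0.45),
                         drawSize(nDecoy)),
        in_mask = undersized, decoy = TRUE)
      out <- rbind(real, dec)
    } else out <- real
    rownames(out) <- NULL
    out
  })
}
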