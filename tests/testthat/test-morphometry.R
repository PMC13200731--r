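test_that("total dendrite length sums parent-child edges", {
  expect_equal(totalDendriteLength(chainTree(5)), 5)
  soma <- NeuriteTree(data.frame(id = 1, parent = NA, x = 0, y = 0, z = 0,
                                 radius = 4, kind = "soma"))
  expect_equal(totalDendriteLength(soma), 0)
  tr <- genArbor(seed = 13)
  nd <- treeNodes(tr)
  pi <- match(nd$parent, nd$id)
  manual <- sum(sqrt((nd$x - nd$x[pi])^2 + (nd$y - nd$y[pi])^2 +
                     (nd$z - nd$z[pi])^2), na.rm = TRUE)
  expect_equal(totalDendriteLength(tr), manual, tolerance = 1e-9)
})

test_that("branch points exclude the soma and count trifurcations once", {
  expect_equal(countBranchPoints(yTree()), 1L)
  trunks <- genArbor(branchProb = 0, nPrimary = 4, seed = 1)
  expect_equal(countBranchPoints(trunks), 0L)
  tri <- NeuriteTree(data.frame(
    id = 1:6, parent = c(NA, 1, 2, 2, 2, 3),
    x = c(0, 10, 20, 20, 20, 30), y = c(0, 0, 5, 0, -5, 5), z = 0,
    radius = 0.3, kind = c("soma", rep("dendrite", 5))))
  expect_equal(countBranchPoints(tri), 1L)
})

test_that("branch levels follow the Imaris convention", {
  expect_equal(branchLevelHistogram(yTree()), c(`1` = 1L, `2` = 2L))
  trunks <- genArbor(branchProb = 0, nPrimary = 4, seed = 2)
  expect_equal(branchLevelHistogram(trunks), c(`1` = 4L))
  # a full binary tree of depth 3 on one trunk: levels 1, 2, 4... and the
  # third generation has 4 branches
  nd <- data.frame(id = 1, parent = NA, x = 0, y = 0, z = 0, radius = 4,
                   kind = "soma")
  addNode <- function(nd, id, parent, x, y)
    rbind(nd, data.frame(id = id, parent = parent, x = x, y = y, z = 0,
                         radius = 0.3, kind = "dendrite"))
  nd <- addNode(nd, 2, 1, 10, 0)
  nd <- addNode(nd, 3, 2, 20, 5);  nd <- addNode(nd, 4, 2, 20, -5)
  nd <- addNode(nd, 5, 3, 30, 8);  nd <- addNode(nd, 6, 3, 30, 2)
  nd <- addNode(nd, 7, 4, 30, -2); nd <- addNode(nd, 8, 4, 30, -8)
  bin <- NeuriteTree(nd)
  expect_equal(branchLevelHistogram(bin), c(`1` = 1L, `2` = 2L, `3` = 4L))
  # with bifurcations only, #branches = #trunks + 2 * #branch points
  tr <- genArbor(seed = 3)
  h <- branchLevelHistogram(tr)
  expect_equal(sum(h), unname(h["1"]) + 2L * countBranchPoints(tr))
})

test_that("Sholl profiles match the stated conventions", {
  trunk <- chainTree(10, step = 10)  # straight trunk, length 100
  sh <- shollAnalysis(trunk)
  expect_equal(sh$radii, 1:99)
  expect_true(all(sh$raw == 1))
  expect_equal(sh$normalized, rep(1, 10))

  y <- yTree(50, 100)
  shy <- shollAnalysis(y)
  expect_true(all(shy$raw[shy$radii < 50] == 1))
  expect_true(all(shy$raw[shy$radii > 50 & shy$radii < 100] == 2))
})

test_that("Sholl matches the quadratic-root oracle on generated arbors", {
  for (s in 4:6) {
    tr <- genArbor(seed = s)
    sh <- shollAnalysis(tr)
    expect_identical(as.integer(sh$raw),
                     as.integer(oracleSholl(tr, sh$radii)))
  }
})

test_that("morphometrics are invariant to pass-through nodes and rotation", {
  tr <- genArbor(seed = 31)
  nd <- treeNodes(tr)
  # split the first non-soma edge by an interior midpoint node
  e <- nd[!is.na(nd$parent), ][1, ]
  par <- nd[match(e$parent, nd$id), ]
  mid <- data.frame(id = max(nd$id) + 1L, parent = par$id,
                    x = (e$x + par$x) / 2, y = (e$y + par$y) / 2,
                    z = (e$z + par$z) / 2,
                    radius = e$radius, kind = "dendrite")
  nd$parent[nd$id == e$id] <- mid$id
  tr2 <- NeuriteTree(rbind(nd, mid), somaId = somaId(tr))
  expect_equal(totalDendriteLength(tr2), totalDendriteLength(tr),
               tolerance = 1e-9)
  expect_equal(countBranchPoints(tr2), countBranchPoints(tr))
  expect_equal(branchLevelHistogram(tr2), branchLevelHistogram(tr))
  expect_equal(fieldAreaConvexHull(tr2), fieldAreaConvexHull(tr),
               tolerance = 1e-9)
  expect_equal(shollAnalysis(tr2)$raw, shollAnalysis(tr)$raw)
  expect_equal(countSelfCrossings(tr2), countSelfCrossings(tr))

  # rigid rotation about the soma
  a <- 33 * pi / 180
  nd <- treeNodes(tr)
  rot <- nd
  rot$x <- cos(a) * nd$x - sin(a) * nd$y
  rot$y <- sin(a) * nd$x + cos(a) * nd$y
  trR <- NeuriteTree(rot, somaId = somaId(tr))
  expect_equal(shollAnalysis(trR)$raw, shollAnalysis(tr)$raw)
  expect_equal(fieldAreaConvexHull(trR), fieldAreaConvexHull(tr),
               tolerance = 1e-6)
  expect_equal(totalDendriteLength(trR), totalDendriteLength(tr),
               tolerance = 1e-9)
})

test_that("convex hull field area matches closed forms and the oracle", {
  sq <- NeuriteTree(data.frame(
    id = 1:4, parent = c(NA, 1, 1, 1),
    x = c(0, 100, 100, 0), y = c(0, 0, 100, 100), z = 0,
    radius = c(4, 0.3, 0.3, 0.3), kind = c("soma", rep("dendrite", 3))))
  expect_equal(fieldAreaConvexHull(sq), 10000)
  tri <- NeuriteTree(data.frame(
    id = 1:3, parent = c(NA, 1, 1), x = c(0, 30, 0), y = c(0, 0, 40),
    z = 0, radius = c(4, 0.3, 0.3), kind = c("soma", rep("dendrite", 2))))
  expect_equal(fieldAreaConvexHull(tri), 600)
  coll <- NeuriteTree(data.frame(
    id = 1:3, parent = c(NA, 1, 2), x = c(0, 1, 2), y = c(0, 1, 2), z = 0,
    radius = 0.3, kind = c("soma", rep("dendrite", 2))))
  expect_error(fieldAreaConvexHull(coll), "collinear")

  set.seed(42)
  nd <- data.frame(id = 1:200, parent = c(NA, rep(1, 199)),
                   x = c(0, rnorm(199, 0, 40)), y = c(0, rnorm(199, 0, 40)),
                   z = 0, radius = 0.3,
                   kind = c("soma", rep("dendrite", 199)))
  cloud <- NeuriteTree(nd)
  expect_equal(fieldAreaConvexHull(cloud), oracleHullArea(nd$x, nd$y),
               tolerance = 1e-6)
})

test_that("self-crossings require proper xy intersection within the z slab", {
  mk <- function(zA, zB) NeuriteTree(data.frame(
    id = 1:4, parent = c(NA, 1, 2, 1),
    x = c(0, 5, 5, 10), y = c(0, -5, 5, 0), z = c(0, zA, zB, 0),
    radius = 0.3, kind = c("soma", rep("dendrite", 3))))
  expect_equal(countSelfCrossings(mk(0, 0)), 1L)      # X at equal z
  expect_equal(countSelfCrossings(mk(5, 5)), 0L)      # separated by 5 um
  expect_equal(countSelfCrossings(mk(5, 5), zTolerance = 6), 1L)
  # sibling edges meeting at their shared branch point do not count
  expect_equal(countSelfCrossings(yTree()), 0L)
})

test_that("self-crossings match the parametric-solve oracle", {
  for (s in 7:9) {
    tr <- genArbor(seed = s)
    expect_identical(countSelfCrossings(tr), oracleSelfCrossings(tr))
  }
})

test_that("hypertrophic dendrites are flagged by strict branch caliber", {
  ctrl <- genArbor(seed = 17)          # all calibers <= 0.6
  expect_false(classifyHypertrophic(ctrl)$hypertrophic)
  ko <- genArbor("pten_ko", seed = 17) # one trunk at caliber 1.4
  hy <- classifyHypertrophic(ko)
  expect_true(hy$hypertrophic)
  # caliber exactly at the threshold is not hypertrophic (strict inequality)
  nd <- treeNodes(chainTree(3))
  nd$radius[nd$kind == "dendrite"] <- 0.5
  expect_false(classifyHypertrophic(NeuriteTree(nd))$hypertrophic)
  nd$radius[nd$kind == "dendrite"] <- 0.51
  expect_true(classifyHypertrophic(NeuriteTree(nd))$hypertrophic)
})

test_that("soma area is the shoelace area of a simple outline", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(somaArea(square), 1)
  hexa <- cbind(5 * cos(2 * pi * (0:5) / 6), 5 * sin(2 * pi * (0:5) / 6))
  expect_equal(somaArea(hexa), 3 * sqrt(3) / 2 * 25, tolerance = 1e-4)
  expect_equal(somaArea(square[4:1, ]), 1)  # orientation invariance
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(somaArea(bowtie), "self-intersecting")
})

test_that("morphometryReport bundles consistent per-cell metrics", {
  tr <- genArbor("pten_ko", seed = 23)
  rep <- morphometryReport(tr)
  expect_equal(rep$nBranchPoints, countBranchPoints(tr))
  expect_equal(rep$totalLength, totalDendriteLength(tr))
  expect_length(rep$shollNormalized, 10L)
  expect_true(rep$hypertrophic)
  expect_equal(sum(rep$branchLevelHistogram), 2 * rep$nBranchPoints +
                 rep$branchLevelHistogram[["1"]])
})
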