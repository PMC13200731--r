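# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

sacLog <- function(stage, ..., verbose = getOption("sacmorph.verbose", FALSE)) {
  if (isTRUE(verbose))
    message(sprintf("[%s] %s", stage, paste0(...)))
}

# Edge table of a tree: one row per non-root node, endpoints in 3D.
# Row order follows the node table; soma-incident edges carry fromSoma = TRUE.
treeEdges <- function(tree) {
  nd <- treeNodes(tree)
  child <- nd[!is.na(nd$parent), , drop = FALSE]
  if (!nrow(child))
    return(data.frame(childId = integer(), parentId = integer(),
                      x0 = numeric(), y0 = numeric(), z0 = numeric(),
                      x1 = numeric(), y1 = numeric(), z1 = numeric(),
                      length = numeric(), fromSoma = logical()))
  pidx <- match(child$parent, nd$id)
  data.frame(
    childId = child$id, parentId = child$parent,
    x0 = nd$x[pidx], y0 = nd$y[pidx], z0 = nd$z[pidx],
    x1 = child$x, y1 = child$y, z1 = child$z,
    length = sqrt((child$x - nd$x[pidx])^2 + (child$y - nd$y[pidx])^2 +
                  (child$z - nd$z[pidx])^2),
    fromSoma = child$parent == somaId(tree)
  )
}

somaXYZ <- function(tree) {
  nd <- treeNodes(tree)
  i <- match(somaId(tree), nd$id)
  c(x = nd$x[i], y = nd$y[i], z = nd$z[i])
}

# Euclidean distance of every node from the soma; xy projection optional.
nodeRadialDist <- function(tree, xyOnly = FALSE) {
  nd <- treeNodes(tree)
  s <- somaXYZ(tree)
  d2 <- (nd$x - s["x"])^2 + (nd$y - s["y"])^2
  if (!xyOnly) d2 <- d2 + (nd$z - s["z"])^2
  stats::setNames(sqrt(d2), nd$id)
}

# children list keyed by node id (as character)
childrenMap <- function(tree) {
  nd <- treeNodes(tree)
  kids <- split(nd$id[!is.na(nd$parent)], nd$parent[!is.na(nd$parent)])
  kids
}

# Decompose the tree into branches: maximal unbranched paths between the
# soma, branch points (>= 2 children, soma excluded) and tips. Returns a list
# with one entry per branch: nodeIds (excluding the start junction), level
# (primary dendrites are level 1), startId, endId.
branchDecomposition <- function(tree) {
  nd <- treeNodes(tree)
  kids <- childrenMap(tree)
  soma <- somaId(tree)
  branches <- list()
  # stack of (startNode, firstChild, level)
  stack <- list()
  for (c0 in kids[[as.character(soma)]])
    stack[[length(stack) + 1L]] <- list(start = soma, child = c0, level = 1L)
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    path <- integer()
    cur <- fr$child
    repeat {
      path <- c(path, cur)
      ch <- kids[[as.character(cur)]]
      if (is.null(ch) || length(ch) >= 2L) break
      cur <- ch
    }
    branches[[length(branches) + 1L]] <- list(
      nodeIds = path, level = fr$level, startId = fr$start, endId = cur)
    ch <- kids[[as.character(cur)]]
    if (!is.null(ch) && length(ch) >= 2L)
      for (c1 in ch)
        stack[[length(stack) + 1L]] <-
          list(start = cur, child = c1, level = fr$level + 1L)
  }
  branches
}

trapezoidAUC <- function(x, y) {
  if (length(x) < 2L) stop("curve needs at least 2 points")
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
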