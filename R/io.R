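#' Read an SWC reconstruction
#'
#' Parses a standard 7-column SWC file (`id type x y z radius parent`) into a
#' [NeuriteTree-class]. Comment lines starting with `#` are ignored; node ids
#' need not be contiguous. SWC type 1 is the soma and type 3 a dendrite;
#' any other type code is accepted but mapped to dendrite with a warning
#' (SACs are axonless, all neurites are treated as dendrites).
#'
#' @param path path to an SWC file.
#' @param metadata optional list attached to the tree.
#' @return A validated [NeuriteTree-class].
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("# toy cell", "1 1 0 0 0 4 -1", "2 3 10 0 0 0.3 1",
#'              "3 3 20 0 0 0.3 2"), f)
#' tr <- readSWC(f)
#' @export
readSWC <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data lines in ", path)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", keep[bad[1]], " in ", path,
         " (expected 7 fields)")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  nas <- which(apply(m, 1L, function(r) any(is.na(r))))
  if (length(nas))
    stop("malformed SWC line ", keep[nas[1]], " in ", path,
         " (non-numeric field)")
  type <- as.integer(m[, 2])
  odd <- !(type %in% c(SWC_SOMA, SWC_DENDRITE))
  if (any(odd)) {
    warning(sum(odd), " node(s) with SWC type other than 1/3 mapped to ",
            "dendrite")
    type[odd] <- SWC_DENDRITE
  }
  nodes <- data.frame(
    id = as.integer(m[, 1]),
    parent = ifelse(m[, 7] < 0, NA_integer_, as.integer(m[, 7])),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    kind = ifelse(type == SWC_SOMA, "soma", "dendrite")
  )
  tr <- NeuriteTree(nodes, metadata = metadata, validate = FALSE)
  v <- validateTree(tr)
  if (length(v))
    stop("structure error in ", path, ": ", paste(v, collapse = "; "))
  tr
}

#' Write a NeuriteTree to SWC
#'
#' @param tree a [NeuriteTree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(tree, path) {
  nd <- treeNodes(tree)
  type <- ifelse(nd$kind == "soma", SWC_SOMA, SWC_DENDRITE)
  parent <- ifelse(is.na(nd$parent), -1L, nd$parent)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   nd$id, type, nd$x, nd$y, nd$z, nd$radius, parent)
  writeLines(c("# SWC exported by sacmorph", lines), path)
  invisible(path)
}

#' Structural validation of a NeuriteTree
#'
#' Checks every container invariant and returns a character vector of
#' violation descriptions (empty when the tree is valid), each naming the
#' node ids involved. Nothing is raised, so defective trees can be examined.
#'
#' Invariants: exactly one root (no parent) and it is the soma; every parent
#' reference resolves; the graph is connected and acyclic; radii are
#' non-negative; coordinates are finite.
#'
#' @param tree a [NeuriteTree-class].
#' @return character vector of violations; `character(0)` if valid.
#' @export
validateTree <- function(tree) {
  nd <- treeNodes(tree)
  out <- character()
  if (!nrow(nd)) return("tree has no nodes")
  roots <- nd$id[is.na(nd$parent)]
  if (length(roots) != 1L)
    out <- c(out, paste0("expected exactly one root, found ",
                         length(roots), " (ids: ",
                         paste(roots, collapse = ", "), ")"))
  if (length(roots) == 1L) {
    if (!identical(as.integer(roots), as.integer(somaId(tree))))
      out <- c(out, paste0("root node ", roots, " is not the soma (somaId ",
                           somaId(tree), ")"))
    if (nd$kind[match(roots, nd$id)] != "soma")
      out <- c(out, paste0("root node ", roots, " is not of kind 'soma'"))
  }
  dangling <- nd$id[!is.na(nd$parent) & !(nd$parent %in% nd$id)]
  if (length(dangling))
    out <- c(out, paste0("parent of node(s) ",
                         paste(dangling, collapse = ", "),
                         " does not exist"))
  bad_r <- nd$id[!is.finite(nd$radius) | nd$radius < 0]
  if (length(bad_r))
    out <- c(out, paste0("negative or non-finite radius at node(s) ",
                         paste(bad_r, collapse = ", ")))
  bad_c <- nd$id[!is.finite(nd$x) | !is.finite(nd$y) | !is.finite(nd$z)]
  if (length(bad_c))
    out <- c(out, paste0("non-finite coordinates at node(s) ",
                         paste(bad_c, collapse = ", ")))
  # reachability from the root: unreached nodes indicate a cycle or a
  # disconnected component
  if (length(roots) >= 1L && !length(dangling)) {
    reached <- rep(FALSE, nrow(nd))
    names(reached) <- nd$id
    frontier <- as.character(roots)
    reached[frontier] <- TRUE
    kids <- split(nd$id[!is.na(nd$parent)], nd$parent[!is.na(nd$parent)])
    while (length(frontier)) {
      nxt <- unlist(kids[frontier], use.names = FALSE)
      nxt <- nxt[!reached[as.character(nxt)]]
      reached[as.character(nxt)] <- TRUE
      frontier <- as.character(nxt)
    }
    if (!all(reached))
      out <- c(out, paste0("cycle or disconnected component involving ",
                           "node(s) ",
                           paste(names(reached)[!reached], collapse = ", ")))
  }
  out
}

#' Read a long-format MEA unit table
#'
#' Reads a CSV with columns `unit_id`, `direction_deg`, `epoch`, `n_spikes`
#' (one row per unit x direction x epoch) and returns one
#' [UnitResponse-class] per unit. All 12 directions (0, 30, ..., 330) must be
#' present for every epoch of every unit.
#'
#' @param path CSV path.
#' @param epochDuration epoch duration in seconds (not stored in the table).
#' @return list of [UnitResponse-class], in order of first appearance.
#' @export
readUnitTable <- function(path, epochDuration = 3) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "direction_deg", "epoch", "n_spikes")
  if (!all(need %in% names(df)))
    stop("unit table must have columns: ", paste(need, collapse = ", "))
  if (any(df$direction_deg %% 30 != 0 | df$direction_deg < 0 |
          df$direction_deg >= 360))
    stop("directions must lie on the 12 x 30 degree grid")
  if (any(df$n_spikes < 0 | df$n_spikes != round(df$n_spikes)))
    stop("spike counts must be non-negative integers")
  dirs <- seq(0, 330, by = 30)
  ids <- unique(df$unit_id)
  lapply(ids, function(uid) {
    d <- df[df$unit_id == uid, , drop = FALSE]
    epochs <- sort(unique(d$epoch))
    cnt <- matrix(NA_real_, length(epochs), 12L)
    ii <- cbind(match(d$epoch, epochs), match(d$direction_deg, dirs))
    if (anyDuplicated(ii))
      stop("duplicate (direction, epoch) cell for unit ", uid)
    cnt[ii] <- d$n_spikes
    if (anyNA(cnt)) {
      miss <- which(is.na(cnt), arr.ind = TRUE)
      stop("unit ", uid, " is missing direction ", dirs[miss[1, 2]],
           " in epoch ", epochs[miss[1, 1]])
    }
    UnitResponse(uid, cnt, epochDuration = epochDuration)
  })
}

#' Write unit responses as a long-format CSV
#'
#' @param units list of [UnitResponse-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeUnitTable <- function(units, path) {
  rows <- lapply(units, function(u) {
    cm <- unitCounts(u)
    expand.grid(epoch = seq_len(nrow(cm)),
                direction_deg = unitDirections(u)) |>
      within({
        unit_id <- unitId(u)
        n_spikes <- as.vector(cm)
      })
  })
  df <- do.call(rbind, rows)[, c("unit_id", "direction_deg", "epoch",
                                 "n_spikes")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write soma point patterns
#'
#' The CSV carries columns `x_um`, `y_um`; the sampling window is stored in a
#' header comment `# window: xmin xmax ymin ymax`.
#'
#' @param path CSV path.
#' @return [PointPattern-class] (read) or `path` invisibly (write).
#' @export
readPointPattern <- function(path) {
  lines <- readLines(path, warn = FALSE)
  wline <- grep("^#\\s*window:", lines, value = TRUE)
  if (!length(wline))
    stop("point pattern file lacks a '# window: ...' header: ", path)
  window <- as.numeric(strsplit(trimws(sub("^#\\s*window:", "", wline[1])),
                                "\\s+")[[1]])
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  PointPattern(df$x_um, df$y_um, window)
}

#' @rdname readPointPattern
#' @param pattern a [PointPattern-class].
#' @export
writePointPattern <- function(pattern, path) {
  w <- patternWindow(pattern)
  xy <- patternCoords(pattern)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window: %.9g %.9g %.9g %.9g", w[1], w[2], w[3], w[4]),
             con)
  utils::write.csv(data.frame(x_um = xy$x, y_um = xy$y), con,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write puncta tables
#'
#' Columns `x_um`, `y_um`, `z_um`, `size_um`, `in_mask`; `size_um` is the
#' largest surface diameter of the punctum and `in_mask` records whether it
#' passed the membrane-GFP mask.
#'
#' @param path CSV path.
#' @return data.frame of puncta (read) or `path` invisibly (write).
#' @export
readPuncta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "z_um", "size_um", "in_mask")
  if (!all(need %in% names(df)))
    stop("puncta table must have columns: ", paste(need, collapse = ", "))
  if (any(df$size_um <= 0)) stop("puncta sizes must be positive")
  df$in_mask <- as.logical(df$in_mask)
  df
}

#' @rdname readPuncta
#' @param puncta data.frame as returned by [genPuncta()] or [readPuncta()].
#' @export
writePuncta <- function(puncta, path) {
  utils::write.csv(
    puncta[, c("x_um", "y_um", "z_um", "size_um", "in_mask")],
    path, row.names = FALSE)
  invisible(path)
}
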