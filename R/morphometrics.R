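#' Validate a morphology node table
#'
#' Nodes follow the SWC convention: columns `index`, `type`, `x`, `y`, `z`,
#' `radius`, `parent` (parent -1 for the root). Orphan parents and cycles
#' raise errors.
#'
#' @param nodes data.frame of nodes.
#' @return Invisibly, the node table (checked).
#' @keywords internal
validateTree <- function(nodes) {
  req <- c("index", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes)))
    stop("node table must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(nodes$index)) stop("duplicate node indices")
  known <- c(-1, nodes$index)
  orphan <- !(nodes$parent %in% known)
  if (any(orphan))
    stop(sprintf("orphan parent reference in row(s): %s",
                 paste(which(orphan), collapse = ", ")))
  # acyclicity: walk each node towards a root, marking resolved depths
  depth <- setNames(rep(NA_integer_, nrow(nodes)), nodes$index)
  pmap <- setNames(nodes$parent, nodes$index)
  for (start in nodes$index) {
    chain <- character(0)
    nd <- as.character(start)
    while (is.na(depth[nd])) {
      if (nd %in% chain) stop("cycle detected in morphology tree")
      chain <- c(chain, nd)
      p <- pmap[[nd]]
      if (p == -1) { depth[nd] <- 0L; break }
      nd <- as.character(p)
    }
    base <- depth[nd]
    for (k in rev(seq_along(chain)))
      if (is.na(depth[chain[k]]))
        depth[chain[k]] <- base + (length(chain) - k + 1L)
  }
  invisible(nodes)
}

#' Morphometrics of a single cell's dendritic trees
#'
#' Each child of the soma roots one dendritic tree. A branch point is a node
#' with exactly two children; tree length is the sum of segment lengths over
#' the tree, excluding the zero-information soma-to-attachment edge.
#'
#' @param nodes SWC-style data.frame for one cell (soma node type 1).
#' @return data.frame with one row per tree: `tree`, `kind` (3 basal /
#'   4 apical), `nBranchPoints`, `totalLength`; per-cell averages as
#'   attributes `meanBranchPoints` and `meanLength`.
#' @examples
#' # a 10-segment unbranched dendrite of unit-length segments
#' nodes <- data.frame(index = 1:11, type = c(1, rep(3, 10)),
#'                     x = c(0, 1:10), y = 0, z = 0, radius = 1,
#'                     parent = c(-1, 1:10))
#' morphometrics(nodes)  # 0 branch points, length 9 after the root edge
#' @export
morphometrics <- function(nodes) {
  validateTree(nodes)
  soma <- nodes$index[nodes$type == 1]
  if (!length(soma)) stop("no soma node (type 1) in node table")
  roots <- nodes$index[nodes$parent %in% soma]
  # propagate tree membership; parents are recorded before children in
  # generated morphologies, otherwise iterate until fixed point
  tree <- setNames(rep(NA_integer_, nrow(nodes)), nodes$index)
  tree[as.character(roots)] <- seq_along(roots)
  repeat {
    unresolved <- is.na(tree) & !(nodes$index %in% soma)
    if (!any(unresolved)) break
    par <- as.character(nodes$parent[unresolved])
    newv <- tree[par]
    if (all(is.na(newv))) stop("disconnected node(s) in morphology tree")
    tree[which(unresolved)] <- newv
  }
  pmap <- setNames(nodes$parent, nodes$index)
  px <- setNames(nodes$x, nodes$index)
  py <- setNames(nodes$y, nodes$index)
  pz <- setNames(nodes$z, nodes$index)
  isSoma <- nodes$index %in% soma
  hasEdge <- !isSoma & !(nodes$parent %in% soma)  # skip soma->attachment
  par <- as.character(nodes$parent[hasEdge])
  segLen <- sqrt((nodes$x[hasEdge] - px[par])^2 +
                 (nodes$y[hasEdge] - py[par])^2 +
                 (nodes$z[hasEdge] - pz[par])^2)
  lenPerTree <- tapply(segLen, tree[which(hasEdge)], sum)
  childCount <- table(factor(as.character(nodes$parent[!isSoma]),
                             levels = as.character(nodes$index)))
  branchNodes <- nodes$index[childCount[as.character(nodes$index)] == 2 &
                               !isSoma]
  bpPerTree <- table(factor(tree[as.character(branchNodes)],
                            levels = seq_along(roots)))
  out <- data.frame(tree = seq_along(roots),
                    kind = nodes$type[match(roots, nodes$index)],
                    nBranchPoints = as.integer(bpPerTree),
                    totalLength = as.numeric(lenPerTree[as.character(seq_along(roots))]))
  out$totalLength[is.na(out$totalLength)] <- 0
  attr(out, "meanBranchPoints") <- mean(out$nBranchPoints)
  attr(out, "meanLength") <- mean(out$totalLength)
  out
}

#' Population-level morphometric summary
#'
#' @param morph full node table with a `cellId` column (as returned by
#'   [runPyramidalCells()]).
#' @return list with `perTree` (rows per cell and tree), `perCell` (per-cell
#'   averages over the 4 trees) and `population` (mean and SD across cells
#'   of the per-cell averages).
#' @export
populationMorphometrics <- function(morph) {
  cells <- sort(unique(morph$cellId))
  perTree <- do.call(rbind, lapply(cells, function(cid) {
    mm <- morphometrics(morph[morph$cellId == cid,
                              c("index", "type", "x", "y", "z", "radius",
                                "parent")])
    cbind(cellId = cid, mm)
  }))
  perCell <- do.call(rbind, lapply(split(perTree, perTree$cellId),
    function(d) data.frame(cellId = d$cellId[1],
                           meanBranchPoints = mean(d$nBranchPoints),
                           meanLength = mean(d$totalLength))))
  list(perTree = perTree, perCell = perCell,
       population = data.frame(
         metric = c("branchPoints", "treeLength"),
         mean = c(mean(perCell$meanBranchPoints), mean(perCell$meanLength)),
         sd = c(sd(perCell$meanBranchPoints), sd(perCell$meanLength))))
}

#' @importFrom stats sd
NULL

# --- SWC I/O ---------------------------------------------------------------

#' Serialize a morphology to SWC text
#'
#' Standard SWC rows `index type x y z radius parent` (type 1 = soma,
#' 3 = basal dendrite, 4 = apical dendrite). Export-import-export is
#' byte-identical; coordinates survive to 1e-6.
#'
#' @param nodes SWC-style data.frame (see [morphometrics()]).
#' @return Character vector of SWC lines.
#' @export
swcLines <- function(nodes) {
  validateTree(nodes)
  sprintf("%d %d %.6f %.6f %.6f %.6f %d",
          as.integer(nodes$index), as.integer(nodes$type),
          nodes$x, nodes$y, nodes$z, nodes$radius,
          as.integer(nodes$parent))
}

#' @rdname swcLines
#' @param path output file path.
#' @export
writeSwc <- function(nodes, path) {
  writeLines(c("# SWC morphology", swcLines(nodes)), path)
  invisible(path)
}

#' Parse SWC text into a morphology node table
#'
#' @param x path to an SWC file, or a character vector of SWC lines.
#' @return data.frame with columns index, type, x, y, z, radius, parent.
#' @export
readSwc <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("malformed SWC row %d: expected 7 fields", bad[1]))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  nodes <- data.frame(index = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  missing <- !(nodes$parent %in% c(-1L, nodes$index))
  if (any(missing))
    stop(sprintf("SWC row %d references missing parent %d",
                 which(missing)[1], nodes$parent[which(missing)[1]]))
  validateTree(nodes)
  nodes
}

#' Extract the SWC node table of one cell from a pyramidal run
#'
#' @param run result of [runPyramidalCells()].
#' @param cellId which cell.
#' @return SWC-style data.frame with indices renumbered from 1.
#' @export
cellMorphology <- function(run, cellId = 1L) {
  nodes <- run$morph[run$morph$cellId == cellId,
                     c("index", "type", "x", "y", "z", "radius", "parent")]
  remap <- setNames(seq_len(nrow(nodes)), nodes$index)
  nodes$index <- as.integer(remap[as.character(nodes$index)])
  nodes$parent <- ifelse(nodes$parent == -1, -1L,
                         as.integer(remap[as.character(nodes$parent)]))
  rownames(nodes) <- NULL
  nodes
}
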