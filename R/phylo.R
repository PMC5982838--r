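## Distance-based gene-tree inference: p-distances with pairwise deletion,
## Poisson correction, Saitou-Nei neighbor joining with documented
## tie-breaking and negative-branch clamping, column-resampling bootstrap,
## midpoint/outgroup rooting.

#' Uncorrected p-distance matrix of an alignment
#'
#' For each pair of rows, gap columns are deleted pairwise and the distance
#' is the fraction of mismatching residues among the compared columns
#' (case-insensitive). A pair with zero comparable columns is an error.
#'
#' @param aln a [StateAlignment-class] with at least two rows.
#' @return Symmetric numeric matrix with zero diagonal, labelled by row ids.
#' @export
pDistanceMatrix <- function(aln) {
  stopifnot(is(aln, "StateAlignment"))
  n <- length(aln@ids)
  if (n < 2L) stop("need at least two rows")
  m <- toupper(alnMatrix(aln))
  isRes <- !matrix(m %in% .GAP_CHARS, nrow(m), ncol(m))
  d <- matrix(0, n, n, dimnames = list(aln@ids, aln@ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- isRes[i, ] & isRes[j, ]
      nc <- sum(both)
      if (nc == 0L)
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     aln@ids[i], aln@ids[j]))
      d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both]) / nc
    }
  }
  d
}

#' Poisson-corrected protein distance
#'
#' Applies the Poisson correction `-log(1 - p)` to proportions of differing
#' sites; saturated values (`p >= 1`) are clamped to `maxDistance` with a
#' warning so that distance matrices stay finite.
#'
#' @param p numeric vector (or matrix) of p-distances in \[0, 1\].
#' @param maxDistance clamp value for saturated pairs.
#' @return Corrected distances, same shape as `p`.
#' @export
poissonDistance <- function(p, maxDistance = 10) {
  if (any(p < 0)) stop("p-distances must be nonnegative")
  sat <- p >= 1
  if (any(sat)) {
    warning(sprintf("%d saturated distance(s) clamped to %g",
                    sum(sat), maxDistance))
    p[sat] <- NA_real_
  }
  out <- -log(1 - p)
  out[sat] <- maxDistance
  if (is.matrix(p)) diag(out) <- 0
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)` is joined,
#' branch lengths follow the standard two-point formulas, and the new node's
#' distances are `(d(i, k) + d(j, k) - d(i, j)) / 2`. Ties are broken by the
#' first minimal pair in row-scan order (smallest index pair), making the
#' result deterministic. Negative branch-length estimates are clamped to
#' zero with the deficit transferred to the sister branch so the pair's
#' summed length is preserved.
#'
#' @param D symmetric numeric matrix with labels and zero diagonal
#'   (at least 3 taxa).
#' @return An unrooted `ape::phylo` (trifurcating root node).
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must be labelled")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")

  nodes <- labels                       # newick fragment per active node
  d <- D
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        if (q < bestQ - 1e-12) { bestQ <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    merged <- sprintf("(%s:%.15g,%s:%.15g)", nodes[i], li, nodes[j], lj)
    newD <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    nodes <- c(nodes[keep], merged)
  }
  v1 <- (d[1L, 2L] + d[1L, 3L] - d[2L, 3L]) / 2
  v2 <- (d[1L, 2L] + d[2L, 3L] - d[1L, 3L]) / 2
  v3 <- (d[1L, 3L] + d[2L, 3L] - d[1L, 2L]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 nodes[1L], v[1L], nodes[2L], v[2L], nodes[3L], v[3L])
  ape::read.tree(text = txt)
}

#' Build an NJ tree from an alignment
#'
#' Convenience pipeline: p-distance with pairwise deletion, Poisson
#' correction, neighbor joining.
#'
#' @param aln a [StateAlignment-class] with at least 3 rows.
#' @param maxDistance Poisson clamp for saturated pairs.
#' @return An unrooted `ape::phylo`.
#' @export
njTree <- function(aln, maxDistance = 10) {
  neighborJoining(poissonDistance(pDistanceMatrix(aln), maxDistance))
}

## canonical bipartition keys of the internal edges of an unrooted tree
.splitKeys <- function(tree, internalOnly = TRUE) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, type = "tips")
  nodes <- seq_along(desc)
  root <- ntip + 1L
  if (internalOnly) nodes <- nodes[nodes > ntip & nodes != root]
  else nodes <- nodes[nodes != root]
  keys <- vapply(nodes, function(nd) {
    side <- tree$tip.label[desc[[nd]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, character(1L))
  names(keys) <- nodes
  ## only informative splits (2+ tips on each side) distinguish topologies,
  ## but pendant-edge keys are harmless: every tree has them
  keys
}

#' Annotate an NJ tree with bootstrap supports
#'
#' The reference tree is built from the full alignment; for each replicate
#' the columns are resampled with replacement (same width) and the tree is
#' rebuilt through the same p-distance / Poisson / NJ pipeline. Each
#' internal edge of the reference tree is annotated with the percentage of
#' replicates whose tree contains the same bipartition. Replicates in which
#' a pair of rows has no comparable columns are skipped, counted and
#' reported with a warning. Fully reproducible for a given seed.
#'
#' @param aln a [StateAlignment-class] with at least 3 rows.
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed integer seed governing all resampling.
#' @param maxDistance Poisson clamp for saturated pairs.
#' @return The reference `ape::phylo` with supports in `node.label`
#'   (read them with [nodeSupports()]); attributes `replicatesUsed` and
#'   `replicatesSkipped` record the bootstrap accounting.
#' @export
bootstrapSupport <- function(aln, replicates = 100, seed = 1,
                             maxDistance = 10) {
  stopifnot(is(aln, "StateAlignment"), replicates >= 1)
  ref <- njTree(aln, maxDistance)
  w <- alnWidth(aln)
  refKeys <- .splitKeys(ref)
  counts <- stats::setNames(rep(0L, length(refKeys)), refKeys)
  set.seed(as.integer(seed))
  used <- 0L; skipped <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(w, w, replace = TRUE)
    rep_aln <- alnSubsetColumns(aln, cols)
    tr <- tryCatch(suppressWarnings(njTree(rep_aln, maxDistance)),
                   error = function(e) NULL)
    if (is.null(tr)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    hit <- intersect(.splitKeys(tr), refKeys)
    counts[hit] <- counts[hit] + 1L
  }
  if (skipped > 0L)
    warning(sprintf("%d bootstrap replicate(s) skipped (undefined distances)",
                    skipped))
  support <- if (used > 0L) 100 * counts / used else counts * NA_real_
  ntip <- length(ref$tip.label)
  labs <- rep("", ref$Nnode)
  nodeIds <- as.integer(names(refKeys))
  labs[nodeIds - ntip] <- as.character(signif(unname(support[refKeys]), 6))
  ref$node.label <- labs
  attr(ref, "replicatesUsed") <- used
  attr(ref, "replicatesSkipped") <- skipped
  ref
}

#' Root a tree at its midpoint or on an outgroup
#'
#' Midpoint rooting places the root halfway along the longest leaf-to-leaf
#' path; outgroup rooting requires the outgroup leaves to form one side of
#' an existing bipartition. Either way, patristic distances between leaves
#' are unchanged.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param mode `"midpoint"` or `"outgroup"`.
#' @param outgroup leaf labels of the outgroup (mode `"outgroup"`).
#' @return A rooted `ape::phylo`.
#' @export
rootTree <- function(tree, mode = c("midpoint", "outgroup"),
                     outgroup = NULL) {
  mode <- match.arg(mode)
  if (mode == "midpoint") {
    if (length(tree$tip.label) == 2L) {
      total <- sum(tree$edge.length)
      tree$edge.length <- rep(total / 2, length(tree$edge.length))
      return(tree)
    }
    return(phangorn::midpoint(tree))
  }
  if (is.null(outgroup) || !length(outgroup))
    stop("outgroup rooting requires outgroup leaves")
  if (!all(outgroup %in% tree$tip.label))
    stop(sprintf("outgroup leaf not in tree: %s",
                 setdiff(outgroup, tree$tip.label)[1L]))
  if (length(outgroup) < length(tree$tip.label) - 1L &&
      !bipartitionPresent(tree, outgroup))
    stop("outgroup does not form a bipartition of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Patristic distances between all leaves
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return Symmetric matrix of path-length distances, labelled by leaf.
#' @export
patristicDistances <- function(tree) {
  stats::cophenetic(tree)
}
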