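## Tree interrogation behind the origin reasoning: monophyly tests, sister
## groups, eubacterial/archaeal origin classification, detection of paralog
## divergences predating eukaryogenesis, and a node-height chronology of
## splits.

.tipSets <- function(tree) {
  ## tip labels below each node (tips included), by ape node id
  desc <- phangorn::Descendants(tree, type = "tips")
  lapply(desc, function(ix) tree$tip.label[ix])
}

#' Is a leaf set one side of a bipartition of the tree?
#'
#' Unrooted monophyly: `TRUE` iff removing some edge splits the leaves into
#' exactly `leafset` versus its complement.
#'
#' @param tree an `ape::phylo`.
#' @param leafset nonempty proper subset of the tree's leaf labels.
#' @return logical.
#' @export
bipartitionPresent <- function(tree, leafset) {
  tips <- tree$tip.label
  if (!all(leafset %in% tips))
    stop(sprintf("leaf not in tree: %s", setdiff(leafset, tips)[1L]))
  if (!length(leafset) || length(leafset) >= length(tips))
    stop("leafset must be a nonempty proper subset of the leaves")
  target <- sort(unique(leafset))
  comp <- sort(setdiff(tips, target))
  sets <- .tipSets(tree)
  root <- length(tips) + 1L
  for (nd in seq_along(sets)) {
    if (nd == root) next
    side <- sort(sets[[nd]])
    if (identical(side, target) || identical(side, comp)) return(TRUE)
  }
  FALSE
}

.mrcaNode <- function(tree, leaves) {
  if (length(leaves) == 1L) return(match(leaves, tree$tip.label))
  ape::getMRCA(tree, leaves)
}

#' Leaves of the sister group of a clade
#'
#' @param tree a rooted `ape::phylo`.
#' @param cladeLeafset leaf labels forming a monophyletic clade.
#' @return Leaf labels under the sibling(s) of the clade's MRCA.
#' @export
sisterLeaves <- function(tree, cladeLeafset) {
  ## interpreted as rooted at the tree's root node (a basal
  ## multifurcation counts as a root)
  tips <- tree$tip.label
  if (!all(cladeLeafset %in% tips))
    stop(sprintf("leaf not in tree: %s", setdiff(cladeLeafset, tips)[1L]))
  sets <- .tipSets(tree)
  mrca <- .mrcaNode(tree, cladeLeafset)
  if (!setequal(sets[[mrca]], cladeLeafset))
    stop("clade is not monophyletic in the rooted tree")
  root <- length(tips) + 1L
  if (mrca == root) stop("clade spans the root; no sister group exists")
  parent <- tree$edge[tree$edge[, 2L] == mrca, 1L]
  sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], mrca)
  sort(unique(unlist(sets[sibs])))
}

.rootForOrigin <- function(tree, taxonomy) {
  ## archaea, when present, root the tree (as the outside reference);
  ## otherwise midpoint. A non-monophyletic archaeal set falls back to its
  ## first leaf so rooting is always defined.
  doms <- taxDomain(taxonomy, tree$tip.label)
  arch <- sort(tree$tip.label[doms == "Archaea"])
  if (length(arch)) {
    og <- if (length(arch) == length(tree$tip.label) - 1L ||
              length(arch) == 1L ||
              bipartitionPresent(tree, arch)) arch else arch[1L]
    return(rootTree(tree, "outgroup", og))
  }
  rootTree(tree, "midpoint")
}

#' Classify the evolutionary origin of a protein family
#'
#' Roots the gene tree (archaeal leaves as outgroup when present, midpoint
#' otherwise), takes the minimal clade containing all eukaryotic family
#' leaves, and inspects the non-eukaryotic leaves inside that clade and its
#' sister group: eubacterial leaves without archaeal ones give an
#' endosymbiotic/eubacterial origin call, the converse gives archaeal,
#' neither gives eukaryote-only, both gives ambiguous. Viral leaves are
#' reported as evidence but never drive the call.
#'
#' @param tree an `ape::phylo` gene tree with branch lengths.
#' @param familyLeaves leaf ids of the family (at least one eukaryotic).
#' @param taxonomy a [TaxonomyMap-class] resolving every leaf.
#' @param family family token used in the report.
#' @param rooted set `TRUE` if `tree` is already rooted as desired.
#' @return An [OriginCall-class].
#' @export
classifyFamilyOrigin <- function(tree, familyLeaves, taxonomy,
                                 family = "family", rooted = FALSE) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(taxonomy@seqSpecies))
  if (length(missing))
    stop(sprintf("taxonomy missing for leaf: %s", missing[1L]))
  if (!all(familyLeaves %in% tips))
    stop(sprintf("family leaf not in tree: %s",
                 setdiff(familyLeaves, tips)[1L]))
  if (!rooted) tree <- .rootForOrigin(tree, taxonomy)
  doms <- stats::setNames(taxDomain(taxonomy, tree$tip.label),
                          tree$tip.label)
  eukFam <- familyLeaves[doms[familyLeaves] == "Eukaryota"]
  if (!length(eukFam))
    stop("familyLeaves must contain at least one eukaryotic leaf")
  sets <- .tipSets(tree)
  mrca <- .mrcaNode(tree, eukFam)
  cladeLeaves <- sets[[mrca]]
  sister <- if (mrca == length(tree$tip.label) + 1L) character()
            else tryCatch(sisterLeaves(tree, cladeLeaves),
                          error = function(e) character())
  hood <- unique(c(cladeLeaves, sister))
  nonEuk <- hood[doms[hood] != "Eukaryota"]
  neighborLeaves <- stats::setNames(nonEuk, doms[nonEuk])
  hasEub <- "Eubacteria" %in% names(neighborLeaves)
  hasArch <- "Archaea" %in% names(neighborLeaves)
  call <- if (hasEub && !hasArch) "eubacterial"
          else if (hasArch && !hasEub) "archaeal"
          else if (!hasEub && !hasArch) "eukaryote_only"
          else "ambiguous"
  new("OriginCall", family = family, call = call,
      cladeLeaves = cladeLeaves, neighborLeaves = neighborLeaves)
}

#' Did two eukaryotic paralog clades diverge before eukaryogenesis?
#'
#' `TRUE` iff each clade is closer to its nearest eubacterial leaf than to
#' the other clade (by mean patristic distance, or by nearest-leaf distance
#' with `method = "nearest"`) *and* the union of the two clades does not
#' form a bipartition excluding all eubacterial leaves. Symmetric in its
#' two clades.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param cladeA,cladeB disjoint sets of eukaryotic leaf ids.
#' @param taxonomy a [TaxonomyMap-class]; the tree must contain at least
#'   one eubacterial leaf or the test is undefined (error).
#' @param method distance summary between a clade and a candidate
#'   eubacterial leaf: `"mean"` (default) or `"nearest"`.
#' @return logical.
#' @export
predatesEukaryogenesis <- function(tree, cladeA, cladeB, taxonomy,
                                   method = c("mean", "nearest")) {
  method <- match.arg(method)
  tips <- tree$tip.label
  if (length(intersect(cladeA, cladeB)))
    stop("cladeA and cladeB must be disjoint")
  if (!all(c(cladeA, cladeB) %in% tips))
    stop(sprintf("leaf not in tree: %s",
                 setdiff(c(cladeA, cladeB), tips)[1L]))
  doms <- stats::setNames(taxDomain(taxonomy, tips), tips)
  if (any(doms[c(cladeA, cladeB)] != "Eukaryota"))
    stop("cladeA and cladeB must be eukaryotic leaf sets")
  eub <- tips[doms == "Eubacteria"]
  if (!length(eub))
    stop("no eubacterial leaves in tree: test undefined")
  pd <- patristicDistances(tree)
  between <- mean(pd[cladeA, cladeB, drop = FALSE])
  toBact <- function(clade) {
    per <- vapply(eub, function(e) {
      v <- pd[clade, e]
      if (method == "mean") mean(v) else min(v)
    }, numeric(1L))
    min(per)
  }
  closer <- toBact(cladeA) < between && toBact(cladeB) < between
  togetherAsClade <-
    length(c(cladeA, cladeB)) < length(tips) &&
    bipartitionPresent(tree, c(cladeA, cladeB))
  closer && !togetherAsClade
}

#' Relative chronology of splits by node height
#'
#' Orders the internal nodes of a rooted tree by decreasing node height,
#' where the height of a node is the mean path length from the node to its
#' descendant leaves; ties are broken by preorder. On clock-like trees this
#' reproduces the relative order of divergence events, oldest first, with
#' the root split leading.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @return A data.frame of class `ChronologyReport`: `node` (ape node id),
#'   `height`, and list columns `clade1`/`clade2` with the two leaf sets of
#'   each split (first child versus the rest).
#' @export
chronology <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths")
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # root-to-node path length
  sets <- phangorn::Descendants(tree, type = "tips")
  internal <- ntip + seq_len(tree$Nnode)
  height <- vapply(internal, function(nd)
    mean(depth[sets[[nd]]]) - depth[nd], numeric(1L))
  ## preorder rank of internal nodes from the cladewise edge table
  eg <- ape::reorder.phylo(tree, "cladewise")$edge
  pre <- unique(c(ntip + 1L, eg[, 2L]))
  prerank <- match(internal, pre)
  ord <- order(-height, prerank)
  clade1 <- vector("list", length(internal))
  clade2 <- vector("list", length(internal))
  for (i in seq_along(internal)) {
    nd <- internal[i]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    c1 <- sets[[kids[1L]]]
    clade1[[i]] <- sort(tree$tip.label[c1])
    clade2[[i]] <- sort(tree$tip.label[setdiff(sets[[nd]], c1)])
  }
  out <- data.frame(node = internal[ord], height = height[ord])
  out$clade1 <- clade1[ord]
  out$clade2 <- clade2[ord]
  class(out) <- c("ChronologyReport", "data.frame")
  out
}
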