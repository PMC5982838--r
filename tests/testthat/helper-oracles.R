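# Independent oracles and fixture builders used across the suite.

# Random gap-free protein sequences
randomProteins <- function(n, len = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("seq%03d", seq_len(n))
  seqs
}

# TaxonomyMap for simple leaf-name -> group fixtures
fixtureTaxonomy <- function(groupsByLeaf) {
  species <- paste0("sp_", names(groupsByLeaf))
  TaxonomyMap(
    seqSpecies = stats::setNames(species, names(groupsByLeaf)),
    speciesGroup = stats::setNames(unname(groupsByLeaf), species))
}

# Tip bitmasks per node computed by fixed-point iteration over the edge
# table (independent of the phangorn-based route in the package).
.nodeTipMasks <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  mask <- integer(nnode)
  mask[seq_len(ntip)] <- bitwShiftL(1L, seq_len(ntip) - 1L)
  repeat {
    m2 <- mask
    for (e in seq_len(nrow(tree$edge)))
      m2[tree$edge[e, 1]] <- bitwOr(m2[tree$edge[e, 1]],
                                    m2[tree$edge[e, 2]])
    if (identical(m2, mask)) break
    mask <- m2
  }
  mask
}

# Exhaustive Dollo oracle: for every possible leaf pattern of the tree,
# the minimal loss count over all single-gain placements and all subsets
# of loss edges, found by explicit enumeration. Returns a lookup:
#   losses[leafmask + 1], gains[[leafmask + 1]] (optimal gain nodes).
dolloBruteForceTable <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  mask <- .nodeTipMasks(tree)
  ne <- nrow(tree$edge)
  stopifnot(ne <= 16)
  nsub <- bitwShiftL(1L, ne)
  edgeMask <- mask[tree$edge[, 2]]
  orMask <- integer(nsub)
  popcnt <- integer(nsub)
  for (s in seq_len(nsub - 1L)) {
    low <- bitwAnd(s, -s)
    rest <- bitwAnd(s, s - 1L)
    orMask[s + 1L] <- bitwOr(orMask[rest + 1L],
                             edgeMask[which(bitwAnd(s, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L)[1]])
    popcnt[s + 1L] <- popcnt[rest + 1L] + 1L
  }
  npat <- bitwShiftL(1L, ntip)
  best <- rep(Inf, npat)
  gains <- vector("list", npat)
  for (g in seq_len(nnode)) {
    lm <- bitwAnd(mask[g], bitwNot(orMask))
    for (s in seq_len(nsub)) {
      pat <- lm[s] + 1L
      if (popcnt[s] < best[pat]) {
        best[pat] <- popcnt[s]
        gains[[pat]] <- g
      } else if (popcnt[s] == best[pat] && !(g %in% gains[[pat]])) {
        gains[[pat]] <- c(gains[[pat]], g)
      }
    }
  }
  list(losses = best, gains = gains)
}

leafMask <- function(tree, presentTips) {
  ix <- match(presentTips, tree$tip.label)
  if (!length(ix)) return(0L)
  sum(bitwShiftL(1L, ix - 1L))
}

# Fixed fixture set of rooted trees with <= 8 leaves (stars, caterpillars,
# balanced shapes) for exhaustive Dollo checks.
dolloFixtureTrees <- function() {
  txts <- c(
    star5 = "(A:1,B:1,C:1,D:1,E:1);",
    cat5 = "((((A:1,B:1):1,C:1):1,D:1):1,E:1);",
    bal6 = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);",
    mix7 = "(((A:2,B:1):1,(C:1,(D:1,E:2):1):1):1,(F:1,G:1):2);",
    bal8 = "((((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1):1);",
    cat8 = "(((((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1):1,G:1):1,H:1);")
  lapply(txts, function(t) ape::collapse.singles(ape::read.tree(text = t)))
}

# Mean-patristic "predates" decision recomputed from first principles:
# path lengths via ape::dist.nodes and split enumeration via ape::prop.part.
predatesOracle <- function(tree, cladeA, cladeB, taxonomy) {
  dn <- ape::dist.nodes(tree)
  tipIx <- stats::setNames(seq_along(tree$tip.label), tree$tip.label)
  pd <- function(x, y) mean(dn[tipIx[x], tipIx[y]])
  doms <- stats::setNames(taxDomain(taxonomy, tree$tip.label),
                          tree$tip.label)
  eub <- names(doms)[doms == "Eubacteria"]
  between <- pd(cladeA, cladeB)
  near <- function(cl) min(vapply(eub, function(e) pd(cl, e), numeric(1)))
  pp <- ape::prop.part(tree)
  sides <- lapply(pp, function(ix) sort(tree$tip.label[ix]))
  target <- sort(c(cladeA, cladeB))
  comp <- sort(setdiff(tree$tip.label, target))
  asClade <- any(vapply(sides, function(s)
    identical(s, target) || identical(s, comp), logical(1)))
  (near(cladeA) < between && near(cladeB) < between) && !asClade
}
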