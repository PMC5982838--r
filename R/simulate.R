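## Generators with known ground truth: Dollo gene-content evolution,
## protein sequence evolution under the 20-state uniform-exchange model,
## and endosymbiotic-transfer gene-tree scenarios.

.preorderEdges <- function(tree) {
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate Dollo gene content along a rooted tree
#'
#' The root carries the character iff `rootPresent`; along each edge a
#' present character is lost independently with probability `lossProb`,
#' and an absent character is never regained.
#'
#' @param tree a rooted `ape::phylo`.
#' @param rootPresent logical root state.
#' @param lossProb per-edge loss probability in \[0, 1).
#' @param seed optional integer seed (bit-reproducible given the seed).
#' @return list with `tipStates` (named logical over leaves) and
#'   `nodeStates` (named logical over tips and internal `node<k>`).
#' @export
simulateGeneContent <- function(tree, rootPresent = TRUE, lossProb = 0.1,
                                seed = NULL) {
  stopifnot(lossProb >= 0, lossProb < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- rep(FALSE, nnode)
  states[ntip + 1L] <- rootPresent
  ord <- .preorderEdges(tree)
  lost <- stats::runif(nrow(ord$edge)) < lossProb
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    states[ch] <- states[p] && !lost[e]
  }
  names(states) <- c(tree$tip.label,
                     paste0("node", ntip + seq_len(tree$Nnode)))
  list(tipStates = states[seq_len(ntip)], nodeStates = states)
}

#' Simulate a protein alignment under the uniform-exchange model
#'
#' Sites evolve independently under the 20-state analogue of the
#' Jukes-Cantor process: branch lengths are expected substitutions per
#' site, the root sequence is uniform over the 20 amino acids, and along an
#' edge of length d each site changes with probability
#' `(19/20) (1 - exp(-(20/19) d))`, moving to one of the 19 other residues
#' uniformly. The expected tip-pair p-distance over a path of total length
#' d follows the same closed form, which the tests exploit.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param length number of alignment columns.
#' @param seed optional integer seed.
#' @return A gap-free all-match [StateAlignment-class] with one row per
#'   leaf.
#' @export
simulateAlignment <- function(tree, length, seed = NULL) {
  stopifnot(length >= 1)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(0L, nnode, length)
  seqs[ntip + 1L, ] <- sample.int(20L, length, replace = TRUE)
  ord <- .preorderEdges(tree)
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    d <- ord$edge.length[e]
    pchange <- (19 / 20) * (1 - exp(-(20 / 19) * d))
    x <- seqs[p, ]
    mut <- stats::runif(length) < pchange
    if (any(mut)) {
      shift <- sample.int(19L, sum(mut), replace = TRUE)
      x[mut] <- ((x[mut] - 1L + shift) %% 20L) + 1L
    }
    seqs[ch, ] <- x
  }
  rows <- vapply(seq_len(ntip), function(i)
    paste(.AA20[seqs[i, ]], collapse = ""), character(1L))
  StateAlignment(tree$tip.label, rows,
                 colStates = rep("match", length))
}

.jitter_lengths <- function(n, lo, hi) stats::runif(n, lo, hi)

.eukCladeNewick <- function(labels, lo = 0.05, hi = 0.15) {
  ## caterpillar over the eukaryotic tips with modest divergences
  node <- sprintf("%s:%.6f", labels[1L], .jitter_lengths(1L, lo, hi))
  for (lab in labels[-1L])
    node <- sprintf("(%s,%s:%.6f):%.6f", node, lab,
                    .jitter_lengths(1L, lo, hi), .jitter_lengths(1L, lo, hi))
  node
}

.wrapWithBacteria <- function(core, bactLabels, lo, hi) {
  for (b in bactLabels)
    core <- sprintf("(%s,%s:%.6f):%.6f", core, b,
                    .jitter_lengths(1L, lo, hi), .jitter_lengths(1L, lo, hi))
  core
}

#' Simulate an endosymbiotic gene-transfer scenario
#'
#' Builds a gene tree in which the eukaryotic family members descend from a
#' eubacterial donor clade: the eukaryotic tips (one per requested
#' supergroup) nest inside a caterpillar of eubacterial tips, optionally
#' with an archaeal outgroup outside the family clade. With
#' `preEukaryoticDuplication = TRUE`, two eukaryotic paralog clades are
#' generated, each sister to a distinct eubacterial lineage, so the paralog
#' split predates eukaryogenesis by construction. Backbone branch lengths
#' are drawn from U(0.1, 0.3) and within-eukaryote lengths from
#' U(0.05, 0.15) (moderate protein divergence, well below saturation).
#'
#' @param nBacterial number of eubacterial tips (>= 2; >= 2 per paralog
#'   clade when duplicated).
#' @param eukGroups nonempty subset of the eukaryotic supergroups.
#' @param preEukaryoticDuplication generate two pre-LECA paralog clades?
#' @param includeArchaeaOutgroup add two archaeal tips outside the family
#'   clade?
#' @param seed optional integer seed.
#' @return list with `tree` (rooted `ape::phylo`), `taxonomy`
#'   ([TaxonomyMap-class]), `familyLeaves` (all eukaryotic tips),
#'   `cladeA`/`cladeB` (paralog leaf sets; `cladeB` empty without
#'   duplication) and `truth` (list: `origin = "eubacterial"`,
#'   `predates`, `ancestral`).
#' @export
simulateEndosymbiosis <- function(nBacterial = 4,
                                  eukGroups = c("Opisthokonta", "SAR"),
                                  preEukaryoticDuplication = FALSE,
                                  includeArchaeaOutgroup = TRUE,
                                  seed = NULL) {
  stopifnot(nBacterial >= 2, length(eukGroups) >= 1)
  if (preEukaryoticDuplication && nBacterial < 4)
    stop("a duplication scenario needs at least 4 eubacterial tips")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lo <- 0.1; hi <- 0.3
  bact <- sprintf("bact_%d", seq_len(nBacterial))
  if (preEukaryoticDuplication) {
    cladeA <- sprintf("euk_%s_p1", eukGroups)
    cladeB <- sprintf("euk_%s_p2", eukGroups)
    half <- ceiling(nBacterial / 2)
    coreA <- .wrapWithBacteria(
      sprintf("(%s):%.6f", .eukCladeNewick(cladeA),
              .jitter_lengths(1L, lo, hi)),
      bact[seq_len(half)], lo, hi)
    coreB <- .wrapWithBacteria(
      sprintf("(%s):%.6f", .eukCladeNewick(cladeB),
              .jitter_lengths(1L, lo, hi)),
      bact[(half + 1L):nBacterial], lo, hi)
    core <- sprintf("(%s:%.6f,%s:%.6f)", coreA,
                    .jitter_lengths(1L, lo, hi), coreB,
                    .jitter_lengths(1L, lo, hi))
  } else {
    cladeA <- sprintf("euk_%s_p1", eukGroups)
    cladeB <- character()
    core <- .wrapWithBacteria(
      sprintf("(%s):%.6f", .eukCladeNewick(cladeA),
              .jitter_lengths(1L, lo, hi)),
      bact, lo, hi)
  }
  if (includeArchaeaOutgroup) {
    arch <- c("arch_1", "arch_2")
    txt <- sprintf("(%s:%.6f,(arch_1:%.6f,arch_2:%.6f):%.6f);",
                   core, .jitter_lengths(1L, lo, hi),
                   .jitter_lengths(1L, lo, hi), .jitter_lengths(1L, lo, hi),
                   .jitter_lengths(1L, lo, hi))
  } else {
    ## without an outgroup, root between the family clade and one extra
    ## eubacterial tip so the tree stays rooted and binary at the top
    arch <- character()
    extraLab <- sprintf("bact_%d", nBacterial + 1L)
    bact <- c(bact, extraLab)
    txt <- sprintf("(%s:%.6f,%s:%.6f);", core, .jitter_lengths(1L, lo, hi),
                   extraLab, .jitter_lengths(1L, lo, hi))
  }
  tree <- ape::collapse.singles(ape::read.tree(text = txt))
  eukTips <- c(cladeA, cladeB)
  ids <- c(eukTips, bact, arch)
  species <- c(sub("^euk_(.*)_p[12]$", "sp_\\1", eukTips),
               paste0("sp_", bact),
               paste0("sp_", arch, recycle0 = TRUE))
  groups <- c(rep(eukGroups, times = if (length(cladeB)) 2L else 1L),
              rep("Eubacteria", length(bact)),
              rep("Archaea", length(arch)))
  taxonomy <- TaxonomyMap(
    seqSpecies = stats::setNames(species, ids),
    speciesGroup = stats::setNames(groups, species)[!duplicated(species)])
  list(tree = tree, taxonomy = taxonomy,
       familyLeaves = eukTips, cladeA = cladeA, cladeB = cladeB,
       truth = list(origin = "eubacterial",
                    predates = preEukaryoticDuplication,
                    ancestral = TRUE))
}
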