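## Ancestral gene-content reconstruction at LECA: collapse family
## membership to a supergroup presence/absence profile, apply the
## multi-supergroup parsimony rule, and run Dollo parsimony (single gain,
## minimal losses) on a supergroup tree.

#' Default five-supergroup star tree rooted at LECA
#'
#' The resolved relationships among the ancient eukaryotic supergroups are
#' contested; the star keeps the reconstruction agnostic about them, and
#' any user-supplied rooted Newick over the same leaf set can be used
#' instead.
#'
#' @param groups supergroup leaf labels.
#' @return A rooted `ape::phylo` star tree with unit branch lengths.
#' @export
supergroupStarTree <- function(groups = .DEFAULT_SUPERGROUPS) {
  txt <- sprintf("(%s);", paste0(groups, ":1", collapse = ","))
  ape::read.tree(text = txt)
}

#' Collapse family membership lists to a presence/absence matrix
#'
#' @param familyMembers named list: family token -> character vector of
#'   member sequence ids (possibly empty).
#' @param taxonomy a [TaxonomyMap-class] resolving every member id.
#' @param groups column order; defaults to the taxonomy's eukaryotic
#'   supergroups followed by Eubacteria, Archaea, Virus.
#' @param categories optional named character vector (family -> category).
#' @return A [PresenceMatrix-class]: cell (f, g) is `TRUE` iff at least one
#'   member of family f maps to group g.
#' @export
collapseToGroups <- function(familyMembers, taxonomy, groups = NULL,
                             categories = character()) {
  stopifnot(is.list(familyMembers))
  if (is.null(groups))
    groups <- c(eukGroups(taxonomy), .NONEUK_GROUPS)
  fams <- names(familyMembers)
  if (is.null(fams)) {
    if (length(familyMembers)) stop("familyMembers must be a named list")
    fams <- character()
  }
  m <- matrix(FALSE, length(fams), length(groups),
              dimnames = list(fams, groups))
  for (f in fams) {
    ids <- familyMembers[[f]]
    if (!length(ids)) next
    g <- taxGroup(taxonomy, ids)
    bad <- setdiff(unique(g), groups)
    if (length(bad))
      stop(sprintf("group '%s' not among the configured groups", bad[1L]))
    m[f, unique(g)] <- TRUE
  }
  PresenceMatrix(m, categories)
}

#' Ancestral-presence call by the multi-supergroup parsimony rule
#'
#' A family is called part of the ancestral machinery iff it is present in
#' at least `k` eukaryotic supergroups, or in Eubacteria, or in Archaea.
#' Viral presence alone never triggers the rule (viral homologs are treated
#' as secondarily acquired).
#'
#' @param row named logical vector over the configured groups (a row of a
#'   [PresenceMatrix-class]).
#' @param k minimum number of eukaryotic supergroups ("several"),
#'   default 2.
#' @param eukGroups which of the row's names are eukaryotic supergroups.
#' @return logical.
#' @export
ancestralByRule <- function(row, k = 2,
                            eukGroups = .DEFAULT_SUPERGROUPS) {
  stopifnot(!is.null(names(row)))
  nEuk <- sum(row[intersect(names(row), eukGroups)])
  prok <- any(row[intersect(names(row), c("Eubacteria", "Archaea"))])
  (nEuk >= k) || isTRUE(prok)
}

#' Dollo parsimony reconstruction of one presence row
#'
#' The character is gained exactly once, at the MRCA of all leaves where it
#' is present (absent everywhere when no leaf has it), and lost on the
#' minimal set of edges covering the absent leaves: an edge is a loss edge
#' iff it leads into a maximal subtree of the gain clade containing no
#' present leaf. A node is reconstructed present iff it lies in the gain
#' clade and has at least one present descendant leaf.
#'
#' @param row named logical vector; names covering (a subset of) the tree's
#'   leaves. Non-leaf names (e.g. prokaryotic columns) are ignored.
#' @param tree a rooted `ape::phylo` whose leaves are the group tokens.
#' @return list with `rootState` (logical), `losses` (count), `nodeStates`
#'   (named logical over tips and internal nodes `node<k>`), and `gainNode`
#'   (ape node id, or `NA` when the character is absent everywhere).
#' @export
dolloReconstruct <- function(row, tree) {
  ## the tree is interpreted as rooted at its root node; a basal
  ## multifurcation (e.g. the supergroup star) is a legitimate root
  tips <- tree$tip.label
  present <- names(row)[row & names(row) %in% tips]
  extraEuk <- setdiff(names(row)[row], c(tips, .NONEUK_GROUPS))
  if (length(extraEuk))
    stop(sprintf("present group '%s' is not a leaf of the tree",
                 extraEuk[1L]))
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  nodeNames <- c(tips, paste0("node", ntip + seq_len(tree$Nnode)))
  states <- stats::setNames(rep(FALSE, nnode), nodeNames)
  if (!length(present))
    return(list(rootState = FALSE, losses = 0L, nodeStates = states,
                gainNode = NA_integer_))
  gain <- .mrcaNode(tree, present)
  sets <- phangorn::Descendants(tree, type = "tips")
  hasPresent <- vapply(sets, function(ix)
    any(tips[ix] %in% present), logical(1L))
  inGain <- rep(FALSE, nnode)
  inGain[c(gain, unlist(phangorn::Descendants(tree, gain, "all")))] <- TRUE
  losses <- sum(inGain[tree$edge[, 1L]] & hasPresent[tree$edge[, 1L]] &
                inGain[tree$edge[, 2L]] & !hasPresent[tree$edge[, 2L]])
  states[] <- inGain & hasPresent
  list(rootState = unname(states[ntip + 1L]),
       losses = as.integer(losses),
       nodeStates = states,
       gainNode = gain)
}

#' Reconstruct the ancestral repertoire of a family set
#'
#' Combines, per family, the multi-supergroup parsimony rule, the Dollo
#' reconstruction on the supergroup tree, and (when supplied) the
#' tree-based origin call, and tallies ancestral families per category.
#'
#' @param pm a [PresenceMatrix-class].
#' @param tree a rooted supergroup tree; default the five-supergroup star.
#' @param originCalls optional named list of [OriginCall-class] (or call
#'   strings) per family.
#' @param k the "several supergroups" threshold (default 2).
#' @return An [AncestralReport-class].
#' @export
reconstructRepertoire <- function(pm, tree = supergroupStarTree(),
                                  originCalls = NULL, k = 2) {
  stopifnot(is(pm, "PresenceMatrix"))
  m <- pmMatrix(pm)
  fams <- rownames(m)
  eg <- intersect(colnames(m), tree$tip.label)
  cats <- pmCategories(pm)
  rows <- lapply(fams, function(f) {
    row <- m[f, ]
    dollo <- dolloReconstruct(row, tree)
    origin <- NA_character_
    if (!is.null(originCalls) && !is.null(originCalls[[f]])) {
      oc <- originCalls[[f]]
      origin <- if (is(oc, "OriginCall")) oc@call else as.character(oc)
    }
    data.frame(
      family = f,
      category = if (f %in% names(cats)) unname(cats[f]) else NA_character_,
      nEukGroups = sum(row[eg]),
      prokaryote = any(row[intersect(colnames(m),
                                     c("Eubacteria", "Archaea"))]),
      ancestral = ancestralByRule(row, k = k, eukGroups = eg),
      dolloRoot = dollo$rootState,
      dolloLosses = dollo$losses,
      origin = origin,
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(family = character(), category = character(),
                        nEukGroups = integer(), prokaryote = logical(),
                        ancestral = logical(), dolloRoot = logical(),
                        dolloLosses = integer(), origin = character(),
                        stringsAsFactors = FALSE)
  cs <- if (nrow(calls) && any(!is.na(calls$category))) {
    agg <- stats::aggregate(
      cbind(nFamilies = rep(1L, nrow(calls)), nAncestral = calls$ancestral),
      by = list(category = calls$category), FUN = sum)
    agg[order(agg$category), , drop = FALSE]
  } else {
    data.frame(category = character(), nFamilies = integer(),
               nAncestral = integer())
  }
  rownames(cs) <- NULL
  new("AncestralReport", calls = calls, categorySummary = cs, k = k)
}

#' Bundled presence/absence matrix of the core apoptosis machinery
#'
#' Phylogenetic profile of the apoptotic DNases (ENDOG, ZEN1, NUC1), the
#' caspase/metacaspase proteases, the fungal- and animal-type OMI/HTRA
#' serine proteases, the four AIF oxidoreductase lineages (AIFM1, AIFM2,
#' AIFM3, NDI1) and the apoptosis inhibitors (BIR/survivin, API5/AAC11),
#' across the five ancient eukaryotic supergroups plus Eubacteria, Archaea
#' and Virus. Each cell is backed by the named organisms listed in
#' [apoptosisEvidence()].
#'
#' @param file optional path to an alternative matrix TSV.
#' @return A [PresenceMatrix-class] with category tags.
#' @export
apoptosisPresence <- function(file = system.file(
    "extdata", "apoptosis_presence.tsv", package = "apoRecon")) {
  tab <- utils::read.delim(file, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  groupCols <- setdiff(names(tab), c("family", "category"))
  m <- as.matrix(tab[, groupCols]) == 1
  rownames(m) <- tab$family
  PresenceMatrix(m, stats::setNames(tab$category, tab$family))
}

#' Per-cell organism evidence for the bundled presence matrix
#'
#' @param file optional path to an alternative evidence TSV.
#' @return data.frame with columns `family`, `group`, `evidence`.
#' @export
apoptosisEvidence <- function(file = system.file(
    "extdata", "apoptosis_evidence.tsv", package = "apoRecon")) {
  utils::read.delim(file, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}
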