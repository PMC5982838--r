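## Central S4 containers. Trees are ape 'phylo' objects (the field standard);
## sequence collections are Biostrings AAStringSet; the classes below cover
## the objects for which no installed container fits.

.COL_STATES <- c("match", "insert", "flank")
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_ALPHABET_X <- c(.AA20, "X")
.GAP_CHARS <- c("-", ".")
.DOMAINS <- c("Eukaryota", "Eubacteria", "Archaea", "Virus")
.DEFAULT_SUPERGROUPS <- c("Opisthokonta", "Amoebozoa", "SAR",
                          "Excavata", "Archaeplastida")
.NONEUK_GROUPS <- c("Eubacteria", "Archaea", "Virus")

#' Multiple protein alignment with HMM-style column states
#'
#' Equal-length aligned rows plus a per-column state label. Columns are
#' `"match"` (consensus positions, gaps written `-`), `"insert"` (columns
#' where at least one row carries a lowercase residue or a `.` gap), or
#' `"flank"` (maximal runs of insert columns touching either end of the
#' alignment, i.e. the N-/C-terminal non-consensus states of a profile).
#'
#' @slot ids character vector of unique row identifiers.
#' @slot rows character vector of aligned strings, one per id, all the same
#'   number of characters.
#' @slot colStates character vector, one of `"match"`, `"insert"`, `"flank"`
#'   per column.
#' @aliases StateAlignment-class
#' @exportClass StateAlignment
setClass("StateAlignment",
         slots = c(ids = "character", rows = "character",
                   colStates = "character"))

setValidity("StateAlignment", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@rows))
    msg <- c(msg, "ids and rows must have the same length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf("duplicate row id: %s",
                          object@ids[duplicated(object@ids)][1L]))
  if (length(object@rows)) {
    w <- nchar(object@rows)
    if (length(unique(w)) > 1L)
      msg <- c(msg, "all rows must have the same number of columns")
    if (length(object@colStates) != w[1L])
      msg <- c(msg, "colStates length must equal the column count")
  }
  if (length(object@colStates) &&
      !all(object@colStates %in% .COL_STATES))
    msg <- c(msg, "colStates entries must be 'match', 'insert' or 'flank'")
  if (length(msg)) msg else TRUE
})

#' Taxonomy map: sequence id to species to lineage group
#'
#' Three nested lookups: sequence id to species token, species to lineage
#' group (a eukaryotic supergroup, or Eubacteria / Archaea / Virus), and
#' group to domain of life. Every group maps to exactly one domain; the
#' eukaryotic supergroup set is configurable and defaults to Opisthokonta,
#' Amoebozoa, SAR, Excavata and Archaeplastida.
#'
#' @slot seqSpecies named character vector: id -> species.
#' @slot speciesGroup named character vector: species -> group.
#' @slot groupDomain named character vector: group -> one of `"Eukaryota"`,
#'   `"Eubacteria"`, `"Archaea"`, `"Virus"`.
#' @aliases TaxonomyMap-class
#' @exportClass TaxonomyMap
setClass("TaxonomyMap",
         slots = c(seqSpecies = "character", speciesGroup = "character",
                   groupDomain = "character"))

setValidity("TaxonomyMap", function(object) {
  msg <- character()
  if (length(object@seqSpecies) && is.null(names(object@seqSpecies)))
    msg <- c(msg, "seqSpecies must be named by sequence id")
  if (anyDuplicated(names(object@seqSpecies)))
    msg <- c(msg, "a sequence id is mapped more than once")
  if (anyDuplicated(names(object@speciesGroup)))
    msg <- c(msg, "a species is mapped to more than one group")
  if (anyDuplicated(names(object@groupDomain)))
    msg <- c(msg, "a group is mapped to more than one domain")
  if (length(object@groupDomain) &&
      !all(object@groupDomain %in% .DOMAINS))
    msg <- c(msg, sprintf("domains must be one of: %s",
                          paste(.DOMAINS, collapse = ", ")))
  bad <- setdiff(unique(object@speciesGroup), names(object@groupDomain))
  if (length(bad))
    msg <- c(msg, sprintf("group without a domain: %s", bad[1L]))
  if (length(msg)) msg else TRUE
})

#' Families-by-lineage-groups presence/absence matrix
#'
#' Boolean phylogenetic profile: one row per protein family, one column per
#' lineage group (eukaryotic supergroups plus Eubacteria, Archaea, Virus).
#' Families may carry a category tag (e.g. `"DNase"`, `"AIF"`) used for
#' summary counts.
#'
#' @slot presence logical matrix; rownames are family tokens, colnames are
#'   group tokens, no `NA` cells.
#' @slot categories named character vector (family -> category), possibly
#'   empty.
#' @aliases PresenceMatrix-class
#' @exportClass PresenceMatrix
setClass("PresenceMatrix",
         slots = c(presence = "matrix", categories = "character"))

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  m <- object@presence
  if (!is.logical(m)) msg <- c(msg, "presence must be a logical matrix")
  if (anyNA(m)) msg <- c(msg, "every cell must be TRUE or FALSE")
  if ((nrow(m) > 0L && is.null(rownames(m))) ||
      (ncol(m) > 0L && is.null(colnames(m))))
    msg <- c(msg, "presence must have family rownames and group colnames")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate family token")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate group token")
  if (length(object@categories)) {
    bad <- setdiff(names(object@categories), rownames(m))
    if (length(bad))
      msg <- c(msg, sprintf("category for unknown family: %s", bad[1L]))
  }
  if (length(msg)) msg else TRUE
})

#' Origin call for a protein family
#'
#' Classification of a family's evolutionary origin from the placement of
#' its eukaryotic members in a gene tree: `"eubacterial"` when the minimal
#' clade holding the eukaryotic members (or its sister) contains eubacterial
#' but no archaeal leaves, `"archaeal"` for the converse, `"eukaryote_only"`
#' when neither prokaryotic domain is represented there, `"ambiguous"`
#' otherwise.
#'
#' @slot family family token.
#' @slot call one of `"eubacterial"`, `"archaeal"`, `"eukaryote_only"`,
#'   `"ambiguous"`.
#' @slot cladeLeaves leaf ids of the minimal clade containing the eukaryotic
#'   family members.
#' @slot neighborLeaves non-eukaryotic leaf ids found in the clade or its
#'   sister, named by their domain.
#' @aliases OriginCall-class
#' @exportClass OriginCall
setClass("OriginCall",
         slots = c(family = "character", call = "character",
                   cladeLeaves = "character", neighborLeaves = "character"))

setValidity("OriginCall", function(object) {
  msg <- character()
  ok <- c("eubacterial", "archaeal", "eukaryote_only", "ambiguous")
  if (length(object@call) != 1L || !object@call %in% ok)
    msg <- c(msg, sprintf("call must be one of: %s",
                          paste(ok, collapse = ", ")))
  if (object@call %in% c("eubacterial", "archaeal")) {
    doms <- names(object@neighborLeaves)
    want <- if (object@call == "eubacterial") "Eubacteria" else "Archaea"
    avoid <- if (object@call == "eubacterial") "Archaea" else "Eubacteria"
    if (!want %in% doms)
      msg <- c(msg, sprintf("%s call without a %s neighbor",
                            object@call, want))
    if (avoid %in% doms)
      msg <- c(msg, sprintf("%s call with a %s neighbor", object@call, avoid))
  }
  if (length(msg)) msg else TRUE
})

#' Ancestral-repertoire report
#'
#' Per-family reconstruction of presence in the last eukaryotic common
#' ancestor: the multi-supergroup parsimony rule call, the Dollo parsimony
#' root state and minimal loss count on the supergroup tree, and (when
#' available) the tree-based origin call, plus per-category summary counts.
#'
#' @slot calls data.frame with one row per family (columns `family`,
#'   `category`, `nEukGroups`, `prokaryote`, `ancestral`, `dolloRoot`,
#'   `dolloLosses`, `origin`).
#' @slot categorySummary data.frame of per-category family and ancestral
#'   counts.
#' @slot k the "several supergroups" threshold used by the rule.
#' @aliases AncestralReport-class
#' @exportClass AncestralReport
setClass("AncestralReport",
         slots = c(calls = "data.frame", categorySummary = "data.frame",
                   k = "numeric"))

setValidity("AncestralReport", function(object) {
  need <- c("family", "category", "nEukGroups", "prokaryote", "ancestral",
            "dolloRoot", "dolloLosses", "origin")
  if (!all(need %in% names(object@calls)))
    return(sprintf("calls is missing column(s): %s",
                   paste(setdiff(need, names(object@calls)), collapse = ", ")))
  if (anyDuplicated(object@calls$family))
    return("duplicate family in calls")
  TRUE
})
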