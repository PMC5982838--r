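## Accessors and show methods.

#' @importFrom methods new validObject is show setMethod setGeneric
NULL

#' Construct a StateAlignment
#'
#' When `colStates` is omitted, columns are classified from the rows: a
#' column is an insert column if any row has a lowercase residue or a `.`
#' there; maximal runs of insert columns touching either alignment end are
#' relabelled flank; everything else is a match column.
#'
#' @param ids character vector of row ids.
#' @param rows character vector of aligned strings (same length each).
#' @param colStates optional explicit per-column states.
#' @return A [StateAlignment-class] object.
#' @export
#' @examples
#' StateAlignment(c("a", "b"), c("AC.dE-", "ACx.E-"))
StateAlignment <- function(ids, rows, colStates = NULL) {
  ids <- as.character(ids)
  rows <- as.character(rows)
  if (is.null(colStates)) colStates <- classifyColumns(rows)
  new("StateAlignment", ids = ids, rows = rows, colStates = colStates)
}

#' Classify alignment columns into match/insert/flank states
#'
#' @param rows character vector of equal-length aligned strings.
#' @return character vector of per-column states.
#' @export
classifyColumns <- function(rows) {
  if (!length(rows)) return(character())
  w <- unique(nchar(rows))
  if (length(w) > 1L) stop("rows of unequal length")
  if (w == 0L) return(character())
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  isInsert <- apply(m, 2L, function(col) {
    any(col == "." | (col %in% letters))
  })
  states <- ifelse(isInsert, "insert", "match")
  ## flank: maximal insert runs touching either end
  r <- rle(isInsert)
  idx <- cumsum(r$lengths)
  if (r$values[1L]) states[seq_len(r$lengths[1L])] <- "flank"
  nr <- length(r$values)
  if (nr > 1L && r$values[nr])
    states[(idx[nr - 1L] + 1L):idx[nr]] <- "flank"
  states
}

#' @describeIn StateAlignment-class row identifiers.
#' @param x,object a `StateAlignment`.
#' @export
setGeneric("alnIds", function(x) standardGeneric("alnIds"))
#' @export
setMethod("alnIds", "StateAlignment", function(x) x@ids)

#' @describeIn StateAlignment-class aligned rows as a named character vector.
#' @export
setGeneric("alnRows", function(x) standardGeneric("alnRows"))
#' @export
setMethod("alnRows", "StateAlignment",
          function(x) stats::setNames(x@rows, x@ids))

#' @describeIn StateAlignment-class per-column state labels.
#' @export
setGeneric("colStates", function(x) standardGeneric("colStates"))
#' @export
setMethod("colStates", "StateAlignment", function(x) x@colStates)

#' @describeIn StateAlignment-class column count.
#' @export
setGeneric("alnWidth", function(x) standardGeneric("alnWidth"))
#' @export
setMethod("alnWidth", "StateAlignment",
          function(x) if (length(x@rows)) nchar(x@rows[1L]) else 0L)

#' @describeIn StateAlignment-class alignment as a character matrix
#'   (rows x columns).
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))
#' @export
setMethod("alnMatrix", "StateAlignment", function(x) {
  if (!length(x@rows))
    return(matrix(character(), 0L, alnWidth(x)))
  m <- do.call(rbind, strsplit(x@rows, "", fixed = TRUE))
  rownames(m) <- x@ids
  m
})

setMethod("show", "StateAlignment", function(object) {
  st <- table(factor(object@colStates, levels = .COL_STATES))
  cat(sprintf("StateAlignment: %d rows x %d columns (%d match, %d insert, %d flank)\n",
              length(object@ids), alnWidth(object),
              st[["match"]], st[["insert"]], st[["flank"]]))
  n <- min(3L, length(object@ids))
  for (i in seq_len(n)) {
    r <- object@rows[i]
    if (nchar(r) > 50L) r <- paste0(substr(r, 1L, 47L), "...")
    cat(sprintf("  %s  %s\n", format(object@ids[i], width = 12L), r))
  }
  if (length(object@ids) > n) cat(sprintf("  ... %d more rows\n",
                                          length(object@ids) - n))
})

#' Subset the columns of a StateAlignment
#'
#' @param x a `StateAlignment`.
#' @param cols integer or logical column index.
#' @return A `StateAlignment` with the selected columns, in order.
#' @export
alnSubsetColumns <- function(x, cols) {
  stopifnot(is(x, "StateAlignment"))
  if (is.logical(cols)) cols <- which(cols)
  rows <- vapply(strsplit(x@rows, "", fixed = TRUE),
                 function(ch) paste(ch[cols], collapse = ""), character(1L))
  new("StateAlignment", ids = x@ids, rows = rows,
      colStates = x@colStates[cols])
}

## ---- TaxonomyMap ----------------------------------------------------------

#' Construct a TaxonomyMap
#'
#' @param seqSpecies named character vector (sequence id -> species).
#' @param speciesGroup named character vector (species -> group).
#' @param groupDomain named character vector (group -> domain); groups
#'   absent from this map default to `"Eukaryota"` when they belong to
#'   `eukGroups`, and to themselves for Eubacteria/Archaea/Virus.
#' @param eukGroups character vector of eukaryotic supergroup tokens.
#' @return A [TaxonomyMap-class] object.
#' @export
TaxonomyMap <- function(seqSpecies = character(),
                        speciesGroup = character(),
                        groupDomain = NULL,
                        eukGroups = .DEFAULT_SUPERGROUPS) {
  if (is.null(groupDomain)) {
    grp <- unique(unname(speciesGroup))
    dom <- as.character(ifelse(grp %in% eukGroups, "Eukaryota", grp))
    groupDomain <- stats::setNames(dom, grp)
  }
  new("TaxonomyMap", seqSpecies = seqSpecies, speciesGroup = speciesGroup,
      groupDomain = groupDomain)
}

#' Look up the lineage group of sequence ids
#'
#' @param tax a [TaxonomyMap-class].
#' @param ids sequence ids; every id must be present.
#' @return character vector of group tokens.
#' @export
taxGroup <- function(tax, ids) {
  stopifnot(is(tax, "TaxonomyMap"))
  sp <- tax@seqSpecies[ids]
  if (anyNA(sp))
    stop(sprintf("sequence id not found in taxonomy: %s",
                 ids[is.na(sp)][1L]))
  g <- tax@speciesGroup[sp]
  if (anyNA(g))
    stop(sprintf("species without a group: %s", sp[is.na(g)][1L]))
  unname(g)
}

#' Look up the domain of life of sequence ids
#'
#' @inheritParams taxGroup
#' @return character vector of domains (`Eukaryota`, `Eubacteria`,
#'   `Archaea`, `Virus`).
#' @export
taxDomain <- function(tax, ids) {
  unname(tax@groupDomain[taxGroup(tax, ids)])
}

#' Eukaryotic supergroups known to a taxonomy
#'
#' @param tax a [TaxonomyMap-class].
#' @return character vector of groups whose domain is Eukaryota.
#' @export
eukGroups <- function(tax) {
  stopifnot(is(tax, "TaxonomyMap"))
  names(tax@groupDomain)[tax@groupDomain == "Eukaryota"]
}

setMethod("show", "TaxonomyMap", function(object) {
  cat(sprintf("TaxonomyMap: %d sequences, %d species, %d groups\n",
              length(object@seqSpecies), length(object@speciesGroup),
              length(object@groupDomain)))
  tb <- table(object@groupDomain)
  cat("  domains:", paste(sprintf("%s (%d groups)", names(tb), tb),
                          collapse = ", "), "\n")
})

## ---- PresenceMatrix -------------------------------------------------------

#' Construct a PresenceMatrix
#'
#' @param presence logical matrix, family rownames, group colnames.
#' @param categories optional named character vector (family -> category).
#' @return A [PresenceMatrix-class] object.
#' @export
PresenceMatrix <- function(presence, categories = character()) {
  mode(presence) <- "logical"
  new("PresenceMatrix", presence = presence, categories = categories)
}

#' @describeIn PresenceMatrix-class family tokens.
#' @param x,object a `PresenceMatrix`.
#' @export
setGeneric("pmFamilies", function(x) standardGeneric("pmFamilies"))
#' @export
setMethod("pmFamilies", "PresenceMatrix",
          function(x) rownames(x@presence))

#' @describeIn PresenceMatrix-class lineage-group tokens.
#' @export
setGeneric("pmGroups", function(x) standardGeneric("pmGroups"))
#' @export
setMethod("pmGroups", "PresenceMatrix", function(x) colnames(x@presence))

#' @describeIn PresenceMatrix-class the logical matrix itself.
#' @export
setGeneric("pmMatrix", function(x) standardGeneric("pmMatrix"))
#' @export
setMethod("pmMatrix", "PresenceMatrix", function(x) x@presence)

#' @describeIn PresenceMatrix-class family -> category tags.
#' @export
setGeneric("pmCategories", function(x) standardGeneric("pmCategories"))
#' @export
setMethod("pmCategories", "PresenceMatrix", function(x) x@categories)

setMethod("show", "PresenceMatrix", function(object) {
  cat(sprintf("PresenceMatrix: %d families x %d groups\n",
              nrow(object@presence), ncol(object@presence)))
  if (length(object@categories)) {
    tb <- table(object@categories)
    cat("  categories:", paste(sprintf("%s (%d)", names(tb), tb),
                               collapse = ", "), "\n")
  }
})

## ---- OriginCall -----------------------------------------------------------

#' @describeIn OriginCall-class the call token.
#' @param x,object an `OriginCall`.
#' @export
setGeneric("originCall", function(x) standardGeneric("originCall"))
#' @export
setMethod("originCall", "OriginCall", function(x) x@call)

setMethod("show", "OriginCall", function(object) {
  cat(sprintf("OriginCall [%s]: %s\n", object@family, object@call))
  cat(sprintf("  clade: %d leaves; non-eukaryotic neighbors: %s\n",
              length(object@cladeLeaves),
              if (length(object@neighborLeaves))
                paste(sprintf("%s (%s)", object@neighborLeaves,
                              names(object@neighborLeaves)), collapse = ", ")
              else "none"))
})

## ---- AncestralReport ------------------------------------------------------

#' @describeIn AncestralReport-class per-family call table.
#' @param x,object an `AncestralReport`.
#' @export
setGeneric("reportCalls", function(x) standardGeneric("reportCalls"))
#' @export
setMethod("reportCalls", "AncestralReport", function(x) x@calls)

#' @describeIn AncestralReport-class per-category summary counts.
#' @export
setGeneric("categorySummary", function(x) standardGeneric("categorySummary"))
#' @export
setMethod("categorySummary", "AncestralReport",
          function(x) x@categorySummary)

#' @describeIn AncestralReport-class tokens of families called ancestral.
#' @export
setGeneric("ancestralFamilies",
           function(x) standardGeneric("ancestralFamilies"))
#' @export
setMethod("ancestralFamilies", "AncestralReport",
          function(x) x@calls$family[x@calls$ancestral])

setMethod("show", "AncestralReport", function(object) {
  cat(sprintf("AncestralReport: %d families, %d ancestral (k = %d)\n",
              nrow(object@calls), sum(object@calls$ancestral),
              as.integer(object@k)))
  if (nrow(object@categorySummary)) {
    s <- object@categorySummary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-12s %d of %d ancestral\n",
                  s$category[i], s$nAncestral[i], s$nFamilies[i]))
  }
})
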