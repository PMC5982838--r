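## Readers/writers: FASTA (via Biostrings), Stockholm (hand parser,
## residue lines only), Newick (via ape), taxonomy TSV.

#' Read unaligned protein sequences from FASTA
#'
#' Wrapped lines are concatenated, residues are uppercased, and any letter
#' outside the 20 amino acids plus X is converted to X with a warning.
#' Headers may carry a second whitespace-separated token, stored as the
#' species of the record. Gap characters are rejected: this reader is for
#' unaligned sequences (use [readAlignedFasta()] for alignments).
#'
#' @param file path to a FASTA file, or a character scalar of FASTA text.
#' @return An [Biostrings::AAStringSet] named by id, with a `species`
#'   metadata column (NA where absent).
#' @export
readProteinFasta <- function(file) {
  txt <- .asText(file)
  if (!nzchar(trimws(txt)))
    return(.proteinSet(character(), character()))
  bs <- .readFastaText(txt)
  headers <- names(bs)
  ids <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("\\s", headers),
                    sub("^\\S+\\s+", "", headers), NA_character_)
  seqs <- toupper(as.character(bs))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id: %s", ids[duplicated(ids)][1L]))
  if (any(!nzchar(seqs)))
    stop(sprintf("empty sequence: %s", ids[!nzchar(seqs)][1L]))
  if (any(grepl("[-.]", seqs)))
    stop("gap characters found; use readAlignedFasta() for alignments")
  seqs <- .sanitizeResidues(seqs)
  .proteinSet(stats::setNames(seqs, ids), species)
}

.proteinSet <- function(seqs, species = rep(NA_character_, length(seqs))) {
  x <- Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(species = species)
  x
}

.sanitizeResidues <- function(seqs) {
  pat <- sprintf("[^%s]", paste(.AA_ALPHABET_X, collapse = ""))
  nbad <- sum(vapply(gregexpr(pat, seqs),
                     function(g) sum(g > 0L), integer(1L)))
  if (nbad > 0L) {
    warning(sprintf("%d non-standard residue(s) converted to X", nbad))
    seqs <- gsub(pat, "X", seqs)
  }
  seqs
}

.readFastaText <- function(txt) {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  Biostrings::readBStringSet(tf, format = "fasta")
}

.asText <- function(file) {
  if (length(file) == 1L && !grepl("[\n>();]", file) && file.exists(file))
    return(paste(readLines(file, warn = FALSE), collapse = "\n"))
  paste(file, collapse = "\n")
}

#' Write protein sequences to FASTA
#'
#' Sequences are written unwrapped, one line per record; a species metadata
#' column, when present, is appended to the header.
#'
#' @param x an `AAStringSet` (or named character vector).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeProteinFasta <- function(x, file) {
  ids <- names(x)
  if (is.null(ids)) stop("sequences must be named")
  seqs <- as.character(x)
  species <- rep(NA_character_, length(seqs))
  mc <- tryCatch(S4Vectors::mcols(x), error = function(e) NULL)
  if (!is.null(mc) && "species" %in% colnames(mc) &&
      nrow(mc) == length(seqs))
    species <- as.character(mc$species)
  headers <- ifelse(is.na(species) | !nzchar(species), ids,
                    paste(ids, species))
  writeLines(paste0(">", headers, "\n", seqs), file, sep = "\n")
  invisible(file)
}

#' Species annotations of a protein set
#'
#' @param x an `AAStringSet` produced by [readProteinFasta()].
#' @return character vector of species tokens (NA where unknown).
#' @export
proteinSpecies <- function(x) {
  mc <- S4Vectors::mcols(x)
  if (!is.null(mc) && "species" %in% colnames(mc))
    as.character(mc$species)
  else rep(NA_character_, length(x))
}

#' Read a Stockholm alignment
#'
#' Parses the residue lines of a single-alignment Stockholm file.
#' Annotation lines (`#=GF`, `#=GC`, ...) are ignored; sequence rows split
#' over several blocks are concatenated. Lowercase residues and `.` mark
#' HMM insert states and drive the match/insert/flank column classification
#' (see [classifyColumns()]).
#'
#' @param file path to a Stockholm file, or Stockholm text.
#' @return A [StateAlignment-class].
#' @export
readStockholm <- function(file) {
  txt <- .asText(file)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  ids <- character()
  parts <- list()
  terminated <- FALSE
  for (ln in lines) {
    ln <- sub("\r$", "", ln)
    if (grepl("^\\s*//", ln)) { terminated <- TRUE; break }
    if (!nzchar(trimws(ln)) || grepl("^#", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) != 2L)
      stop(sprintf("malformed Stockholm sequence line: '%s'", ln))
    id <- f[1L]
    if (!id %in% ids) { ids <- c(ids, id); parts[[id]] <- character() }
    parts[[id]] <- c(parts[[id]], f[2L])
  }
  if (!terminated && length(ids))
    warning("Stockholm alignment without '//' terminator")
  rows <- vapply(ids, function(id) paste(parts[[id]], collapse = ""),
                 character(1L))
  if (length(rows) && length(unique(nchar(rows))) > 1L)
    stop("Stockholm rows of unequal length")
  StateAlignment(ids, unname(rows))
}

#' Read an aligned FASTA file as a StateAlignment
#'
#' Column states are derived from residue case and `.` gaps exactly as for
#' Stockholm input; a fully uppercase `-`-gapped alignment yields all-match
#' columns.
#'
#' @param file path to an aligned FASTA file, or FASTA text.
#' @return A [StateAlignment-class].
#' @export
readAlignedFasta <- function(file) {
  txt <- .asText(file)
  if (!nzchar(trimws(txt))) return(StateAlignment(character(), character()))
  bs <- .readFastaText(txt)
  ids <- sub("\\s.*$", "", names(bs))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id: %s", ids[duplicated(ids)][1L]))
  rows <- as.character(bs)
  if (length(unique(nchar(rows))) > 1L)
    stop("aligned FASTA rows of unequal length")
  StateAlignment(ids, unname(rows))
}

#' Write a StateAlignment to aligned FASTA
#'
#' @param aln a [StateAlignment-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeAlignedFasta <- function(aln, file) {
  stopifnot(is(aln, "StateAlignment"))
  writeLines(paste0(">", aln@ids, "\n", aln@rows), file, sep = "\n")
  invisible(file)
}

#' Read a Newick tree
#'
#' Internal node labels that parse as numbers are interpreted as bootstrap
#' support values in \[0, 100\]; labels that all lie in \[0, 1\] are rescaled
#' to percentages with a warning. Unbalanced parentheses are reported with
#' their character position.
#'
#' @param x path to a Newick file, or a Newick string.
#' @return An `ape::phylo`; supports, if any, are in `node.label` and can be
#'   read with [nodeSupports()].
#' @export
readNewickTree <- function(x) {
  txt <- trimws(.asText(x))
  .checkParens(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick text")
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    num <- !is.na(sup)
    if (any(num)) {
      if (max(sup[num]) <= 1) {
        warning("support values in [0, 1] rescaled to percentages")
        sup[num] <- sup[num] * 100
        tr$node.label[num] <- as.character(sup[num])
      }
      if (any(sup[num] < 0 | sup[num] > 100))
        stop("support values outside [0, 100]")
    }
  }
  tr
}

.checkParens <- function(txt) {
  ch <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") depth <- depth + 1L
    if (ch[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced parenthesis at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("unbalanced parentheses: %d unclosed", depth))
  invisible(TRUE)
}

#' Write a tree as Newick text
#'
#' @param tree an `ape::phylo`.
#' @param file optional output path; when `NULL` the Newick string is
#'   returned.
#' @param digits significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to a file).
#' @export
writeNewickTree <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Numeric bootstrap supports of internal nodes
#'
#' @param tree an `ape::phylo` with supports in `node.label`.
#' @return numeric vector, one entry per internal node (NA where no numeric
#'   label is present).
#' @export
nodeSupports <- function(tree) {
  if (is.null(tree$node.label))
    return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Load a taxonomy table
#'
#' Reads a three-column tab-separated table (sequence id, species, group;
#' `#` comment lines ignored) into a [TaxonomyMap-class]. Group tokens must
#' come from `eukGroups` or be `Eubacteria`, `Archaea` or `Virus`.
#'
#' @param file path to a TSV file, or TSV text.
#' @param eukGroups eukaryotic supergroup tokens accepted as groups.
#' @return A [TaxonomyMap-class].
#' @export
loadTaxonomy <- function(file, eukGroups = .DEFAULT_SUPERGROUPS) {
  txt <- .asText(file)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(TaxonomyMap(eukGroups = eukGroups))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 3L)
  if (length(bad))
    stop(sprintf("taxonomy line %d does not have 3 tab-separated fields",
                 bad[1L]))
  tab <- do.call(rbind, f)
  ids <- tab[, 1L]; species <- tab[, 2L]; groups <- tab[, 3L]
  valid <- c(eukGroups, .NONEUK_GROUPS)
  if (!all(groups %in% valid))
    stop(sprintf("unknown group '%s'; valid groups: %s",
                 setdiff(groups, valid)[1L], paste(valid, collapse = ", ")))
  dup <- duplicated(ids)
  if (any(dup)) {
    prev <- match(ids[dup], ids)
    if (any(species[dup] != species[prev]))
      stop(sprintf("id '%s' mapped to two species",
                   ids[dup][species[dup] != species[prev]][1L]))
  }
  firstSp <- match(unique(species), species)
  conf <- tapply(groups, species, function(g) length(unique(g)) > 1L)
  if (any(conf))
    stop(sprintf("species '%s' mapped to two groups",
                 names(conf)[conf][1L]))
  TaxonomyMap(
    seqSpecies = stats::setNames(species[!dup], ids[!dup]),
    speciesGroup = stats::setNames(groups[firstSp], species[firstSp]),
    eukGroups = eukGroups)
}
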