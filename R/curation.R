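## Family curation: column stripping, pairwise identity/coverage,
## redundancy and novelty filters, and profile merging of novel members.
##
## Identity and coverage are computed from an exact global pairwise
## alignment (match +1, mismatch 0, linear gap -1) rather than a heuristic
## database search: deterministic and adequate at the scale of curated
## family alignments, while keeping the 90%-identity / 50%-coverage
## semantics of a BLAST-based screen.

#' Curation thresholds
#'
#' @param identityThreshold candidates at or above this identity to a
#'   database sequence are not novel (default 0.90).
#' @param coverageThreshold minimum fraction of the candidate's residues
#'   aligned against residues of its best-identity hit (default 0.50).
#' @param redundancyThreshold sequences at or above this identity to a
#'   database sequence are redundant (default 0.90).
#' @return A validated list of class `CurationConfig`.
#' @export
curationConfig <- function(identityThreshold = 0.90,
                           coverageThreshold = 0.50,
                           redundancyThreshold = 0.90) {
  for (v in c(identityThreshold, coverageThreshold, redundancyThreshold))
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop("curation thresholds must be single numbers in (0, 1]")
  structure(list(identityThreshold = identityThreshold,
                 coverageThreshold = coverageThreshold,
                 redundancyThreshold = redundancyThreshold),
            class = "CurationConfig")
}

#' Keep only match columns of an alignment
#'
#' Removes every insert and flank column (the HMM insertion states and the
#' N-/C-terminal states of a profile alignment), preserving row ids and the
#' order of the surviving columns. Idempotent.
#'
#' @param aln a [StateAlignment-class].
#' @return A `StateAlignment` of the match columns only.
#' @export
stripNonmatchColumns <- function(aln) {
  stopifnot(is(aln, "StateAlignment"))
  keep <- colStates(aln) == "match"
  out <- alnSubsetColumns(aln, keep)
  out@rows <- toupper(out@rows)
  out
}

#' Drop every column in which at least one row has a gap
#'
#' Applied after match-column extraction, this leaves only positions
#' covered by every sequence. Idempotent and deterministic.
#'
#' @param aln a [StateAlignment-class] (match columns).
#' @return A `StateAlignment` of the all-residue columns.
#' @export
stripGappedColumns <- function(aln) {
  stopifnot(is(aln, "StateAlignment"))
  if (!length(aln@ids) || alnWidth(aln) == 0L) return(aln)
  m <- alnMatrix(aln)
  keep <- colSums(matrix(m %in% .GAP_CHARS, nrow(m), ncol(m))) == 0L
  alnSubsetColumns(aln, keep)
}

.identityScoreMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- .AA_ALPHABET_X
      m <- diag(1, length(letters))
      dimnames(m) <- list(letters, letters)
      cache <<- m
    }
    cache
  }
})

#' Pairwise identity and coverage of two protein sequences
#'
#' Globally aligns `a` against `b` (match +1, mismatch 0, linear gap -1)
#' and reports identity over the aligned region (identical pairs divided
#' by columns where both sequences place a residue) and query-side
#' coverage (residues of `a` placed opposite residues of `b`, divided by
#' the length of `a`). Identity is symmetric; coverage is a property of
#' the query.
#'
#' @param a,b `AAString`/character sequences (no gaps).
#' @return list with `identity`, `coverage` and `alignedColumns`.
#' @export
#' @examples
#' pairwiseIdentity("AAAAAAAAAA", "AAAAAAAATT")$identity  # 0.8
pairwiseIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .identityScoreMatrix(),
    gapOpening = 0, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  bothRes <- pat != "-" & sub != "-"
  aligned <- sum(bothRes)
  identity <- if (aligned > 0L) sum(pat[bothRes] == sub[bothRes]) / aligned
              else 0
  list(identity = identity,
       coverage = aligned / nchar(a),
       alignedColumns = aligned)
}

.bestHit <- function(seq, dbSeqs) {
  ## best-identity database hit for one query; first hit wins ties
  best <- list(identity = -Inf, coverage = 0, alignedColumns = 0L)
  for (j in seq_along(dbSeqs)) {
    r <- pairwiseIdentity(seq, dbSeqs[[j]])
    if (r$identity > best$identity) best <- r
  }
  best
}

#' Remove sequences redundant with a database
#'
#' Drops every new sequence whose identity to some database sequence is at
#' or above the redundancy threshold; order of the survivors is preserved.
#'
#' @param newSeqs,dbSeqs `AAStringSet`s (or named character vectors).
#' @param cfg a [curationConfig()].
#' @return The non-redundant subset of `newSeqs`.
#' @export
removeRedundant <- function(newSeqs, dbSeqs, cfg = curationConfig()) {
  if (!length(newSeqs)) return(newSeqs)
  db <- as.character(dbSeqs)
  keep <- vapply(seq_along(newSeqs), function(i) {
    s <- as.character(newSeqs[[i]])
    for (d in db)
      if (pairwiseIdentity(s, d)$identity >= cfg$redundancyThreshold)
        return(FALSE)
    TRUE
  }, logical(1L))
  newSeqs[keep]
}

#' Select novel family members among candidate sequences
#'
#' A candidate is novel when its maximal identity to any database sequence
#' is below the identity threshold *and* its coverage against the
#' best-identity hit is at least the coverage threshold. With an empty
#' database all candidates are kept, with a warning.
#'
#' @param candidates,dbSeqs `AAStringSet`s (or named character vectors).
#' @param cfg a [curationConfig()].
#' @return The novel subset of `candidates`, order preserved.
#' @export
findNovel <- function(candidates, dbSeqs, cfg = curationConfig()) {
  if (!length(candidates)) return(candidates)
  if (!length(dbSeqs)) {
    warning("empty database: all candidates treated as novel")
    return(candidates)
  }
  keep <- vapply(seq_along(candidates), function(i) {
    best <- .bestHit(as.character(candidates[[i]]), as.character(dbSeqs))
    best$identity < cfg$identityThreshold &&
      best$coverage >= cfg$coverageThreshold
  }, logical(1L))
  candidates[keep]
}

## ---- profile merging ------------------------------------------------------

.profileFromAlignment <- function(aln) {
  ## per-column residue frequencies with pseudocount 1/20, as log-odds
  ## scores against a uniform background; X and gaps contribute nothing
  m <- alnMatrix(aln)
  w <- ncol(m)
  scores <- matrix(0, nrow = 20L, ncol = w, dimnames = list(.AA20, NULL))
  for (c in seq_len(w)) {
    col <- m[, c]
    counts <- table(factor(col[col %in% .AA20], levels = .AA20))
    f <- (as.numeric(counts) + 1 / 20) / (sum(counts) + 1)
    scores[, c] <- log(f * 20)
  }
  scores
}

.alignToProfile <- function(seq, scores, gapOpen = -2, gapExtend = -1) {
  ## Global affine alignment of a sequence against profile columns.
  ## States: M residue-in-column, U residue as insertion (gap in profile),
  ## L column skipped (gap in sequence). Tie preference M > U > L.
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(res); w <- ncol(scores)
  sc <- matrix(0, 21L, w, dimnames = list(c(.AA20, "X"), NULL))
  sc[seq_len(20L), ] <- scores          # X scores 0 everywhere
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, w + 1L)
  U <- matrix(NEG, n + 1L, w + 1L)
  L <- matrix(NEG, n + 1L, w + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L)
    U[i, 1L] <- gapOpen + gapExtend * (i - 2L)
  for (j in seq_len(w) + 1L)
    L[1L, j] <- gapOpen + gapExtend * (j - 2L)
  ptrM <- matrix(0L, n + 1L, w + 1L)  # 1=M 2=U 3=L
  ptrU <- matrix(0L, n + 1L, w + 1L)
  ptrL <- matrix(0L, n + 1L, w + 1L)
  ptrU[-1L, 1L] <- 2L; ptrU[2L, 1L] <- 1L
  ptrL[1L, -1L] <- 3L; ptrL[1L, 2L] <- 1L
  for (i in seq_len(n) + 1L) {
    ri <- res[i - 1L]
    for (j in seq_len(w) + 1L) {
      s <- sc[ri, j - 1L]
      cand <- c(M[i - 1L, j - 1L], U[i - 1L, j - 1L], L[i - 1L, j - 1L])
      k <- which.max(cand)
      M[i, j] <- cand[k] + s; ptrM[i, j] <- k
      cand <- c(M[i - 1L, j] + gapOpen, U[i - 1L, j] + gapExtend,
                L[i - 1L, j] + gapOpen)
      k <- which.max(cand)
      U[i, j] <- cand[k]; ptrU[i, j] <- k
      cand <- c(M[i, j - 1L] + gapOpen, U[i, j - 1L] + gapOpen,
                L[i, j - 1L] + gapExtend)
      k <- which.max(cand)
      L[i, j] <- cand[k]; ptrL[i, j] <- k
    }
  }
  i <- n + 1L; j <- w + 1L
  state <- which.max(c(M[i, j], U[i, j], L[i, j]))
  out <- rep("-", w)      # residue per profile column
  inserted <- 0L
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      out[j - 1L] <- res[i - 1L]
      state <- ptrM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      inserted <- inserted + 1L
      state <- ptrU[i, j]; i <- i - 1L
    } else {
      state <- ptrL[i, j]; j <- j - 1L
    }
  }
  list(row = paste(out, collapse = ""),
       placed = sum(out != "-"), inserted = inserted)
}

#' Merge novel sequences into a master alignment via its profile
#'
#' Each novel sequence is globally aligned against the position-specific
#' profile of the master alignment (per-column residue frequencies with a
#' 1/20 pseudocount, log-odds scores against a uniform background, affine
#' gaps: open -2, extend -1). Residues that cannot be assigned to a match
#' column are treated as insertions and dropped, so the result keeps the
#' master's column count; the master's own rows are never modified. Novel
#' sequences placing fewer than `cfg$coverageThreshold` of their residues
#' into match columns are skipped with a warning.
#'
#' @param novel an `AAStringSet` (or named character vector) of unaligned
#'   novel members.
#' @param master a match-column [StateAlignment-class] (apply
#'   [stripNonmatchColumns()] first if needed).
#' @param cfg a [curationConfig()].
#' @return A `StateAlignment` with the accepted novel rows appended.
#' @export
mergeIntoProfile <- function(novel, master, cfg = curationConfig()) {
  stopifnot(is(master, "StateAlignment"))
  if (!all(colStates(master) == "match"))
    stop("master must contain match columns only; see stripNonmatchColumns()")
  if (alnWidth(master) == 0L)
    stop("master alignment has no match columns")
  if (!length(novel)) return(master)
  ids <- names(novel)
  seqs <- stats::setNames(as.character(novel), ids)
  if (is.null(ids)) stop("novel sequences must be named")
  scores <- .profileFromAlignment(master)
  newIds <- master@ids; newRows <- master@rows
  for (i in seq_along(seqs)) {
    al <- .alignToProfile(toupper(seqs[i]), scores)
    if (al$placed / nchar(seqs[i]) < cfg$coverageThreshold) {
      warning(sprintf(
        "sequence '%s' places only %.0f%% of its residues in match columns; skipped",
        ids[i], 100 * al$placed / nchar(seqs[i])))
      next
    }
    newIds <- c(newIds, ids[i]); newRows <- c(newRows, al$row)
  }
  new("StateAlignment", ids = newIds, rows = newRows,
      colStates = rep("match", alnWidth(master)))
}
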