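## Orchestration: configuration, per-family curation -> tree -> origin ->
## reconstruction, deterministic JSON reporting.

#' Assemble a pipeline configuration
#'
#' @param families list of family definitions; each element is a list with
#'   `name`, optional `category`, and either an `alignment` (path to a
#'   Stockholm/aligned-FASTA file, or a [StateAlignment-class]) with
#'   optional `candidates` (path to a FASTA of candidate members, or an
#'   `AAStringSet`), or a precomputed `members` character vector of
#'   sequence ids.
#' @param taxonomy a [TaxonomyMap-class] or path to a taxonomy TSV.
#' @param presenceMatrix optional [PresenceMatrix-class] (or path to a
#'   matrix TSV): when supplied without `families`, the pipeline runs the
#'   reconstruction stage only.
#' @param supergroupTree rooted supergroup tree (`phylo` or Newick path);
#'   default the five-supergroup star.
#' @param identityThreshold,coverageThreshold,redundancyThreshold curation
#'   thresholds, see [curationConfig()].
#' @param k "several supergroups" threshold for the ancestral rule.
#' @param bootstrapReplicates bootstrap replicates per family tree.
#' @param seed integer seed governing all randomness.
#' @param outDir optional directory for per-family artifacts (curated
#'   FASTA, Newick tree, JSON report).
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(families = list(), taxonomy = NULL,
                           presenceMatrix = NULL, supergroupTree = NULL,
                           identityThreshold = 0.90,
                           coverageThreshold = 0.50,
                           redundancyThreshold = 0.90,
                           k = 2, bootstrapReplicates = 100, seed = 1,
                           outDir = NULL) {
  structure(list(families = families, taxonomy = taxonomy,
                 presenceMatrix = presenceMatrix,
                 supergroupTree = supergroupTree,
                 identityThreshold = identityThreshold,
                 coverageThreshold = coverageThreshold,
                 redundancyThreshold = redundancyThreshold,
                 k = k, bootstrapReplicates = bootstrapReplicates,
                 seed = seed, outDir = outDir),
            class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Returns findings instead of raising: an empty character vector means the
#' configuration is runnable.
#'
#' @param cfg a [pipelineConfig()].
#' @return character vector of findings, each naming the offending field.
#' @export
validateConfig <- function(cfg) {
  findings <- character()
  chk01 <- function(v, name) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      sprintf("%s out of range (0, 1]: %s", name, paste(v, collapse = ","))
    else character()
  }
  findings <- c(findings,
                chk01(cfg$identityThreshold, "identity_threshold"),
                chk01(cfg$coverageThreshold, "coverage_threshold"),
                chk01(cfg$redundancyThreshold, "redundancy_threshold"))
  if (!is.numeric(cfg$k) || cfg$k < 1)
    findings <- c(findings, "k must be a count >= 1")
  if (!is.numeric(cfg$bootstrapReplicates) || cfg$bootstrapReplicates < 1)
    findings <- c(findings, "bootstrap_replicates must be >= 1")
  if (is.character(cfg$taxonomy) && !file.exists(cfg$taxonomy))
    findings <- c(findings,
                  sprintf("taxonomy path does not exist: %s", cfg$taxonomy))
  for (fam in cfg$families) {
    nm <- if (!is.null(fam$name)) fam$name else "<unnamed>"
    if (is.null(fam$name))
      findings <- c(findings, "family without a name")
    if (is.character(fam$alignment) && !file.exists(fam$alignment))
      findings <- c(findings,
                    sprintf("alignment path missing for family %s: %s",
                            nm, fam$alignment))
    if (is.character(fam$candidates) && !file.exists(fam$candidates))
      findings <- c(findings,
                    sprintf("candidates path missing for family %s: %s",
                            nm, fam$candidates))
  }
  nms <- vapply(cfg$families, function(f)
    if (is.null(f$name)) "" else f$name, character(1L))
  if (anyDuplicated(nms[nzchar(nms)]))
    findings <- c(findings, sprintf("duplicate family name: %s",
                                    nms[duplicated(nms)][1L]))
  findings
}

.loadFamilyAlignment <- function(x) {
  if (is(x, "StateAlignment")) return(x)
  if (grepl("\\.(sto|stk|stockholm)$", x, ignore.case = TRUE))
    readStockholm(x)
  else readAlignedFasta(x)
}

.loadCandidates <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(readProteinFasta(x))
  x
}

.degapRows <- function(aln) {
  rows <- gsub("[-.]", "", toupper(alnRows(aln)))
  rows[nzchar(rows)]
}

#' Run the full ancestral-reconstruction pipeline
#'
#' For each configured family: read and preprocess the alignment
#' (match-column extraction, then removal of any column with a gap), screen
#' candidate sequences for novel members and merge them into the profile,
#' build the NJ tree with bootstrap supports, classify the family's origin
#' against the taxonomy, and collapse the membership to the supergroup
#' presence profile. All families are then combined into an
#' [AncestralReport-class]. A family whose stage fails is logged, listed as
#' failed in the report, and does not abort the run. Two runs with the same
#' configuration and seed produce byte-identical JSON reports.
#'
#' @param cfg a [pipelineConfig()].
#' @param quiet suppress per-stage log lines.
#' @return list with `report` (an `AncestralReport`), `presence` (the
#'   [PresenceMatrix-class] used), `trees` (named list of annotated
#'   `phylo`), `origins` (named list of [OriginCall-class]), `failed`
#'   (named character vector of error messages), and `json` (the
#'   deterministic JSON report text).
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  findings <- validateConfig(cfg)
  if (length(findings))
    stop(sprintf("invalid configuration: %s", findings[1L]))
  say <- function(...) if (!quiet) message(sprintf(...))
  ccfg <- curationConfig(cfg$identityThreshold, cfg$coverageThreshold,
                         cfg$redundancyThreshold)
  taxonomy <- cfg$taxonomy
  if (is.character(taxonomy)) taxonomy <- loadTaxonomy(taxonomy)
  tree <- cfg$supergroupTree
  if (is.null(tree)) tree <- supergroupStarTree()
  if (is.character(tree)) tree <- readNewickTree(tree)

  trees <- list(); origins <- list(); members <- list()
  failed <- character(); categories <- character()
  for (i in seq_along(cfg$families)) {
    fam <- cfg$families[[i]]
    nm <- fam$name
    if (!is.null(fam$category)) categories[nm] <- fam$category
    res <- tryCatch({
      if (!is.null(fam$members)) {
        members[[nm]] <- fam$members
        say("family %s: %d members supplied", nm, length(fam$members))
      } else {
        aln <- .loadFamilyAlignment(fam$alignment)
        say("family %s: alignment %d rows x %d columns", nm,
            length(alnIds(aln)), alnWidth(aln))
        aln <- stripNonmatchColumns(aln)
        cand <- .loadCandidates(fam$candidates)
        if (!is.null(cand) && length(cand)) {
          db <- .degapRows(aln)
          novel <- findNovel(cand, db, ccfg)
          say("family %s: %d of %d candidates novel", nm,
              length(novel), length(cand))
          if (length(novel))
            aln <- mergeIntoProfile(novel, aln, ccfg)
        }
        aln <- stripGappedColumns(aln)
        say("family %s: curated to %d rows x %d gap-free match columns",
            nm, length(alnIds(aln)), alnWidth(aln))
        members[[nm]] <- alnIds(aln)
        if (length(alnIds(aln)) >= 3L && alnWidth(aln) >= 1L) {
          tr <- bootstrapSupport(aln, replicates = cfg$bootstrapReplicates,
                                 seed = cfg$seed + i)
          trees[[nm]] <- tr
          if (!is.null(taxonomy)) {
            oc <- tryCatch(
              classifyFamilyOrigin(tr, alnIds(aln), taxonomy, family = nm),
              error = function(e) NULL)
            if (!is.null(oc)) {
              origins[[nm]] <- oc
              say("family %s: origin call %s", nm, oc@call)
            }
          }
        }
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res)) {
      failed[nm] <- res
      say("family %s: FAILED (%s)", nm, res)
    }
  }

  pm <- cfg$presenceMatrix
  if (is.character(pm)) pm <- apoptosisPresence(pm)
  if (is.null(pm)) {
    ok <- setdiff(names(members), names(failed))
    if (is.null(taxonomy)) {
      if (length(ok))
        stop("a taxonomy is required to collapse members to groups")
      groups <- c(tree$tip.label, .NONEUK_GROUPS)
      pm <- PresenceMatrix(matrix(logical(), 0L, length(groups),
                                  dimnames = list(character(), groups)))
    } else {
      ## collapse families one by one so a bad membership only fails
      ## its own family
      rows <- list()
      for (nm in ok) {
        r <- tryCatch(
          collapseToGroups(members[nm], taxonomy),
          error = function(e) conditionMessage(e))
        if (is.character(r)) {
          failed[nm] <- r
          say("family %s: FAILED (%s)", nm, r)
        } else rows[[nm]] <- pmMatrix(r)
      }
      ok <- names(rows)
      groups <- c(eukGroups(taxonomy), .NONEUK_GROUPS)
      mat <- if (length(rows)) do.call(rbind, rows)
             else matrix(logical(), 0L, length(groups),
                         dimnames = list(character(), groups))
      rownames(mat) <- ok
      pm <- PresenceMatrix(mat,
                           categories[intersect(names(categories), ok)])
    }
  }
  report <- reconstructRepertoire(pm, tree = tree,
                                  originCalls = origins, k = cfg$k)
  json <- .reportJson(report, failed)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    writeLines(json, file.path(cfg$outDir, "report.json"))
    for (nm in names(trees))
      writeNewickTree(trees[[nm]],
                      file.path(cfg$outDir, paste0(nm, ".nwk")))
    utils::write.table(
      data.frame(family = pmFamilies(pm),
                 pmMatrix(pm) * 1L, check.names = FALSE),
      file.path(cfg$outDir, "presence.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(report = report, presence = pm, trees = trees, origins = origins,
       failed = failed, json = json)
}

.reportJson <- function(report, failed) {
  calls <- reportCalls(report)
  payload <- list(
    k = as.integer(report@k),
    nFamilies = nrow(calls),
    nAncestral = sum(calls$ancestral),
    families = calls,
    categorySummary = categorySummary(report),
    failed = as.list(failed))
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10,
                                na = "null", pretty = TRUE))
}
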