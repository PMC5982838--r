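test_that("match-column extraction removes inserts and flanks, idempotently", {
  a <- StateAlignment(c("r1", "r2"), c("ACDE", "ACDE"))
  expect_equal(alnRows(stripNonmatchColumns(a)), alnRows(a))

  b <- StateAlignment(c("r1", "r2"), c("AC.dE-", "ACx.E-"))
  s <- stripNonmatchColumns(b)
  ## manual deletion of the two insert columns (3, 4)
  expect_equal(unname(alnRows(s)), c("ACE-", "ACE-"))
  expect_equal(alnWidth(s), 4L)
  expect_equal(alnRows(stripNonmatchColumns(s)), alnRows(s))

  allIns <- StateAlignment(c("r1", "r2"), c("ac", "ac"))
  expect_equal(alnWidth(stripNonmatchColumns(allIns)), 0L)
})

test_that("gapped-column stripping keeps exactly the all-residue columns", {
  a <- StateAlignment(c("r1", "r2"), c("AC-D", "ACED"))
  s <- stripGappedColumns(a)
  expect_equal(unname(alnRows(s)), c("ACD", "ACD"))

  g <- StateAlignment(c("r1", "r2"), c("ACDE", "ACDE"))
  expect_equal(alnRows(stripGappedColumns(g)), alnRows(g))

  allGap <- StateAlignment(c("r1", "r2"), c("----", "ACDE"))
  expect_equal(alnWidth(stripGappedColumns(allGap)), 0L)

  ## idempotence
  expect_equal(alnRows(stripGappedColumns(s)), alnRows(s))
})

test_that("pairwise identity and coverage follow the alignment definition", {
  self <- pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(self$identity, 1.0)
  expect_equal(self$coverage, 1.0)

  ## forced gapless alignment: 8 of 10 columns identical
  r <- pairwiseIdentity("AAAAAAAAAA", "AAAAAAAATT")
  expect_equal(r$identity, 0.8)

  ## exact substring: every query residue lands on a subject residue
  sub <- pairwiseIdentity("ACDEF", "KKACDEFKKK")
  expect_equal(sub$coverage, 1.0)
  expect_equal(sub$identity, 1.0)
})

test_that("identity is symmetric, coverage is query-sided", {
  set.seed(21)
  seqs <- randomProteins(6, len = 25)
  for (i in 1:3) {
    a <- seqs[[2 * i - 1]]; b <- seqs[[2 * i]]
    expect_equal(pairwiseIdentity(a, b)$identity,
                 pairwiseIdentity(b, a)$identity, tolerance = 1e-12)
  }
  long <- paste0(seqs[[1]], seqs[[2]])
  expect_gt(pairwiseIdentity(seqs[[1]], long)$coverage,
            pairwiseIdentity(long, seqs[[1]])$coverage)
})

test_that("redundancy filter drops near-identical sequences only", {
  db <- c(d1 = "ACDEFGHIKLMNPQRSTVWY")
  new <- c(n1 = "ACDEFGHIKLMNPQRSTVWY",      # identical -> dropped
           n2 = "WYWYWYWYWYWYACDACDAC")      # dissimilar -> kept
  kept <- removeRedundant(new, db)
  expect_equal(names(kept), "n2")

  ## empty database keeps everything
  expect_equal(names(removeRedundant(new, character())), names(new))
})

test_that("novelty filter applies both thresholds on the constructed fixtures", {
  db <- c(d1 = "AAAAAAAATT", d2 = "ACDE")
  cands <- c(keep = "AAAAAAAAAA",   # identity 0.8, coverage 1.0 -> novel
             dupl = "AAAAAAAATT",   # identity 1.0 -> excluded
             shrt = "WWWWWWACDF")   # best hit d2: identity 0.75, coverage 0.4
  novel <- findNovel(cands, db)
  expect_equal(names(novel), "keep")
  expect_warning(all <- findNovel(cands, character()), "empty database")
  expect_equal(names(all), names(cands))
})

test_that("novelty implies non-redundancy at equal thresholds", {
  set.seed(31)
  db <- randomProteins(4, len = 30)
  cands <- c(randomProteins(4, len = 30, seed = 32),
             mut = paste0(substr(db[[1]], 1, 28), "AA"))
  cfg <- curationConfig(identityThreshold = 0.9, coverageThreshold = 0.5,
                        redundancyThreshold = 0.9)
  expect_true(all(names(findNovel(cands, db, cfg)) %in%
                  names(removeRedundant(cands, db, cfg))))
})

test_that("profile merging appends rows without touching the master", {
  m <- StateAlignment(c("r1", "r2", "r3"),
                      c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEYGHIKL"))
  ## novel equal to a master row comes back unchanged
  out <- mergeIntoProfile(c(nov = "ACDEFGHIKL"), m)
  expect_equal(unname(alnRows(out)["nov"]), "ACDEFGHIKL")
  expect_equal(alnRows(out)[alnIds(m)], alnRows(m))
  expect_equal(alnWidth(out), alnWidth(m))

  ## one internal extra residue is dropped as an insertion
  out2 <- mergeIntoProfile(c(nov = "ACDEFWGHIKL"), m)
  expect_equal(unname(alnRows(out2)["nov"]), "ACDEFGHIKL")
  expect_equal(alnWidth(out2), alnWidth(m))

  ## empty novel list is the identity
  expect_equal(alnRows(mergeIntoProfile(character(), m)), alnRows(m))
})

test_that("profile merging skips low-coverage sequences with a warning", {
  m <- StateAlignment(c("r1", "r2"), c("ACDEF", "ACDEF"))
  expect_warning(
    out <- mergeIntoProfile(c(bad = "ACWWWWWWWWWWWWWWWWWWWW"), m),
    "skipped")
  expect_false("bad" %in% alnIds(out))
})
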