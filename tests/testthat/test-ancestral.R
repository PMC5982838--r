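test_that("collapsing memberships marks exactly the observed groups", {
  tax <- fixtureTaxonomy(c(y1 = "Opisthokonta", d1 = "Amoebozoa",
                           e1 = "Eubacteria"))
  pm <- collapseToGroups(list(F1 = "y1", F2 = character()), tax,
                         groups = c("Opisthokonta", "Amoebozoa", "SAR",
                                    "Excavata", "Archaeplastida",
                                    "Eubacteria", "Archaea", "Virus"))
  expect_true(pmMatrix(pm)["F1", "Opisthokonta"])
  expect_equal(sum(pmMatrix(pm)["F1", ]), 1)
  expect_equal(sum(pmMatrix(pm)["F2", ]), 0)

  expect_error(collapseToGroups(list(F1 = "unknown_id"), tax), "unknown_id")

  ## random memberships against a per-cell brute count
  set.seed(43)
  ids <- sprintf("s%02d", 1:20)
  grp <- sample(c("Opisthokonta", "SAR", "Eubacteria"), 20, TRUE)
  tax2 <- fixtureTaxonomy(stats::setNames(grp, ids))
  fams <- list(A = sample(ids, 7), B = sample(ids, 3))
  pm2 <- collapseToGroups(fams, tax2)
  for (f in names(fams)) for (g in pmGroups(pm2)) {
    expect_equal(pmMatrix(pm2)[f, g],
                 any(grp[match(fams[[f]], ids)] == g))
  }
})

test_that("the several-supergroups rule fires on k groups or prokaryotes", {
  groups <- c("Opisthokonta", "Amoebozoa", "SAR", "Excavata",
              "Archaeplastida", "Eubacteria", "Archaea", "Virus")
  row <- stats::setNames(rep(FALSE, 8), groups)

  one <- row; one["Opisthokonta"] <- TRUE
  expect_false(ancestralByRule(one))

  two <- row; two[c("Opisthokonta", "SAR")] <- TRUE
  expect_true(ancestralByRule(two))
  expect_false(ancestralByRule(two, k = 3))

  bact <- row; bact["Eubacteria"] <- TRUE
  expect_true(ancestralByRule(bact))

  ## viral presence alone never triggers
  vir <- row; vir[c("Opisthokonta", "Virus")] <- TRUE
  expect_false(ancestralByRule(vir))
})

test_that("Dollo reconstruction on the star matches hand counts", {
  st <- supergroupStarTree()
  all5 <- stats::setNames(rep(TRUE, 5), st$tip.label)
  d <- dolloReconstruct(all5, st)
  expect_true(d$rootState)
  expect_equal(d$losses, 0L)

  two <- stats::setNames(st$tip.label %in% c("Opisthokonta", "Excavata"),
                         st$tip.label)
  d2 <- dolloReconstruct(two, st)
  expect_true(d2$rootState)
  expect_equal(d2$losses, 3L)

  one <- stats::setNames(st$tip.label == "Opisthokonta", st$tip.label)
  d3 <- dolloReconstruct(one, st)
  expect_false(d3$rootState)
  expect_equal(d3$losses, 0L)
  expect_equal(d3$gainNode, match("Opisthokonta", st$tip.label))

  none <- stats::setNames(rep(FALSE, 5), st$tip.label)
  d4 <- dolloReconstruct(none, st)
  expect_false(d4$rootState)
  expect_false(any(d4$nodeStates))
})

test_that("Dollo equals the exhaustive single-gain oracle on small trees", {
  ## full check over every presence row of a 5-leaf and a 6-leaf tree
  for (tree in dolloFixtureTrees()[c("cat5", "bal6")]) {
    tab <- dolloBruteForceTable(tree)
    tips <- tree$tip.label
    root <- length(tips) + 1L
    for (pat in seq_len(2^length(tips)) - 1L) {
      present <- tips[bitwAnd(bitwShiftL(1L, seq_along(tips) - 1L), pat) != 0]
      row <- stats::setNames(tips %in% present, tips)
      d <- dolloReconstruct(row, tree)
      if (!length(present)) {
        expect_equal(d$losses, 0L)
        next
      }
      expect_equal(d$losses, as.integer(tab$losses[pat + 1L]))
      expect_equal(d$rootState, root %in% tab$gains[[pat + 1L]])
    }
  }
})

test_that("rule with k=2 equals the Dollo root state on the star", {
  st <- supergroupStarTree()
  tips <- st$tip.label
  for (pat in seq_len(32) - 1L) {
    present <- tips[bitwAnd(bitwShiftL(1L, 0:4), pat) != 0]
    row <- stats::setNames(tips %in% present, tips)
    expect_equal(ancestralByRule(row, k = 2),
                 dolloReconstruct(row, st)$rootState,
                 info = paste(present, collapse = "+"))
  }
})

test_that("repertoire reconstruction combines rule, Dollo and origin", {
  pm <- apoptosisPresence()
  rep <- reconstructRepertoire(pm)
  calls <- reportCalls(rep)

  ## ENDOG: four supergroups + eubacteria -> ancestral
  endog <- calls[calls$family == "ENDOG", ]
  expect_true(endog$ancestral)
  expect_true(endog$prokaryote)

  ## monotonicity: adding a present group never flips TRUE -> FALSE
  m <- pmMatrix(pm)
  for (f in rownames(m)[1:4]) {
    row <- m[f, ]
    if (!ancestralByRule(row)) next
    row2 <- row; row2[which(!row2)[1]] <- TRUE
    expect_true(ancestralByRule(row2))
  }

  ## family-order invariance
  perm <- rev(pmFamilies(pm))
  pm2 <- PresenceMatrix(pmMatrix(pm)[perm, ], pmCategories(pm)[perm])
  rep2 <- reconstructRepertoire(pm2)
  c1 <- reportCalls(rep)[order(reportCalls(rep)$family), ]
  c2 <- reportCalls(rep2)[order(reportCalls(rep2)$family), ]
  rownames(c1) <- rownames(c2) <- NULL
  expect_equal(c1, c2)

  ## origin calls are carried through
  rep3 <- reconstructRepertoire(pm, originCalls = list(ENDOG = "eubacterial"))
  expect_equal(reportCalls(rep3)$origin[reportCalls(rep3)$family == "ENDOG"],
               "eubacterial")

  empty <- PresenceMatrix(matrix(FALSE, 0, 5,
    dimnames = list(character(), supergroupStarTree()$tip.label)))
  expect_equal(nrow(reportCalls(reconstructRepertoire(empty))), 0)
})
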