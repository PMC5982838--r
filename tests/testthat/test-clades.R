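test_that("bipartition test matches literals and edge enumeration", {
  tr <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(bipartitionPresent(tr, c("A", "B")))
  expect_false(bipartitionPresent(tr, c("A", "C")))
  expect_error(bipartitionPresent(tr, c("A", "Z")), "not in tree")
  expect_error(bipartitionPresent(tr, c("A", "B", "C", "D")), "proper")

  ## random trees: agree with explicit enumeration of every edge's split
  set.seed(13)
  for (i in 1:10) {
    gen <- ape::rtree(8)
    sides <- lapply(ape::prop.part(gen), function(ix)
      sort(gen$tip.label[ix]))
    leafset <- sample(gen$tip.label, sample(2:6, 1))
    target <- sort(leafset)
    comp <- sort(setdiff(gen$tip.label, leafset))
    oracle <- any(vapply(sides, function(s)
      identical(s, target) || identical(s, comp), logical(1))) ||
      length(leafset) == 1
    expect_equal(bipartitionPresent(gen, leafset), oracle)
  }
})

test_that("sister leaves follow the MRCA sibling", {
  expect_equal(sisterLeaves(readNewickTree("((A:1,B:1):1,C:1);"),
                            c("A", "B")), "C")
  expect_equal(sisterLeaves(readNewickTree("(((A:1,B:1):1,C:1):1,D:1);"),
                            c("A", "B")), "C")
  expect_error(sisterLeaves(readNewickTree("((A:1,C:1):1,(B:1,D:1):1);"),
                            c("A", "B")), "monophyletic")

  ## random trees against an explicit MRCA/sibling walk
  set.seed(17)
  for (i in 1:10) {
    tr <- ape::rtree(9)
    node <- sample((length(tr$tip.label) + 2):(length(tr$tip.label) + tr$Nnode), 1)
    clade <- tr$tip.label[phangorn::Descendants(tr, node, "tips")[[1]]]
    parent <- tr$edge[tr$edge[, 2] == node, 1]
    sib <- setdiff(tr$edge[tr$edge[, 1] == parent, 2], node)
    oracle <- sort(tr$tip.label[unlist(phangorn::Descendants(tr, sib, "tips"))])
    expect_equal(sisterLeaves(tr, clade), oracle)
  }
})

test_that("origin classification encodes the eubacterial-not-archaeal rule", {
  tax <- fixtureTaxonomy(c(Yeast = "Opisthokonta", Human = "Opisthokonta",
                           PlantA = "Archaeplastida", AmoebaA = "Amoebozoa",
                           Ecoli1 = "Eubacteria", ArchA = "Archaea"))
  tr <- readNewickTree("(((Yeast:1,Human:1):1,Ecoli1:1):1,ArchA:1);")
  oc <- classifyFamilyOrigin(tr, c("Yeast", "Human"), tax)
  expect_equal(originCall(oc), "eubacterial")
  expect_true("Ecoli1" %in% oc@neighborLeaves)

  tr2 <- readNewickTree("((Yeast:1,Human:1):1,(PlantA:1,AmoebaA:1):1);")
  expect_equal(originCall(classifyFamilyOrigin(
    tr2, c("Yeast", "Human", "PlantA", "AmoebaA"), tax)), "eukaryote_only")

  ## both prokaryotic domains in the neighborhood -> ambiguous
  tr3 <- readNewickTree("(((Yeast:1,Human:1):1,(Ecoli1:1,ArchA:1):1):1,PlantA:5);")
  expect_equal(originCall(classifyFamilyOrigin(
    tr3, c("Yeast", "Human"), tax, rooted = TRUE)), "ambiguous")

  expect_error(classifyFamilyOrigin(tr, c("Yeast", "Nope"), tax), "Nope")
})

test_that("origin classification is invariant to leaf order", {
  scn <- simulateEndosymbiosis(seed = 23)
  o1 <- classifyFamilyOrigin(scn$tree, scn$familyLeaves, scn$taxonomy)
  o2 <- classifyFamilyOrigin(scn$tree, rev(scn$familyLeaves), scn$taxonomy)
  expect_equal(originCall(o1), originCall(o2))
})

test_that("predates test mirrors the paralog-vs-eubacteria pattern", {
  tax <- fixtureTaxonomy(c(HumanOMI = "Opisthokonta", YeastOMI = "Opisthokonta",
                           Bact1 = "Eubacteria", Bact2 = "Eubacteria",
                           Bact3 = "Eubacteria", Bact4 = "Eubacteria"))
  sep <- readNewickTree(
    "(((HumanOMI:1,Bact1:1):1,Bact2:1):1,((YeastOMI:1,Bact3:1):1,Bact4:1):1);")
  expect_true(predatesEukaryogenesis(sep, "HumanOMI", "YeastOMI", tax))
  ## symmetry
  expect_true(predatesEukaryogenesis(sep, "YeastOMI", "HumanOMI", tax))

  tog <- readNewickTree("(((HumanOMI:1,YeastOMI:1):1,Bact1:1):1,Bact2:1);")
  expect_false(predatesEukaryogenesis(tog, "HumanOMI", "YeastOMI", tax))

  noBact <- readNewickTree("((HumanOMI:1,YeastOMI:1):1,Extra:1);")
  tax2 <- fixtureTaxonomy(c(HumanOMI = "Opisthokonta",
                            YeastOMI = "Opisthokonta", Extra = "SAR"))
  expect_error(predatesEukaryogenesis(noBact, "HumanOMI", "YeastOMI", tax2),
               "undefined")
})

test_that("predates decisions equal the brute-force patristic oracle", {
  set.seed(29)
  for (i in 1:15) {
    tr <- ape::rtree(10)
    tips <- tr$tip.label
    groups <- stats::setNames(
      sample(c("Opisthokonta", "SAR", "Eubacteria"), length(tips),
             replace = TRUE, prob = c(0.3, 0.3, 0.4)), tips)
    if (sum(groups == "Eubacteria") < 1) groups[tips[1]] <- "Eubacteria"
    euk <- tips[groups != "Eubacteria"]
    if (length(euk) < 2) next
    a <- euk[1]; b <- euk[2]
    tax <- fixtureTaxonomy(groups)
    expect_equal(predatesEukaryogenesis(tr, a, b, tax),
                 predatesOracle(tr, a, b, tax))
  }
})

test_that("chronology orders splits by node height, root split first", {
  ch <- chronology(readNewickTree("((A:1,B:1):1,(C:2,D:2):0);"))
  expect_equal(ch$height, c(2, 2, 1))
  expect_equal(ch$node[1], 5)           # root, by preorder tie-break
  expect_setequal(unlist(ch[1, c("clade1", "clade2")]), c("A", "B", "C", "D"))

  two <- chronology(readNewickTree("(A:1,B:2);"))
  expect_equal(nrow(two), 1)

  ## scale invariance
  tr <- ape::rcoal(8)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 7
  expect_equal(chronology(tr)$node, chronology(tr2)$node)

  ## on clock-like trees the root split is always the first event
  set.seed(37)
  for (i in 1:10) {
    tr <- ape::rcoal(7)
    ch <- chronology(tr)
    expect_equal(ch$node[1], length(tr$tip.label) + 1)
    expect_true(all(diff(ch$height) <= 1e-12))
  }

  noLen <- ape::read.tree(text = "((A,B),C);")
  expect_error(chronology(noLen), "branch lengths")
})
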