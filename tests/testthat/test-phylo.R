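test_that("p-distances count mismatches over comparable columns", {
  a <- StateAlignment(c("x", "y"), c("AAAA", "AAAT"))
  expect_equal(pDistanceMatrix(a)["x", "y"], 0.25)

  b <- StateAlignment(c("x", "y"), c("ACDE", "ACDE"))
  expect_equal(pDistanceMatrix(b)["x", "y"], 0)

  ## pairwise deletion against a per-column brute count
  set.seed(41)
  rows <- replicate(4, paste(sample(c("A", "C", "D", "-"), 60, TRUE),
                             collapse = ""))
  aln <- StateAlignment(letters[1:4], rows)
  D <- pDistanceMatrix(aln)
  m <- alnMatrix(aln)
  for (i in 1:3) for (j in (i + 1):4) {
    both <- m[i, ] != "-" & m[j, ] != "-"
    expect_equal(D[i, j], sum(m[i, both] != m[j, both]) / sum(both))
  }

  expect_error(pDistanceMatrix(
    StateAlignment(c("x", "y"), c("A-", "-A"))), "comparable")
})

test_that("Poisson correction matches the closed form and clamps saturation", {
  expect_equal(poissonDistance(0), 0)
  expect_equal(poissonDistance(0.5), 0.693147, tolerance = 1e-6)
  expect_warning(d <- poissonDistance(1), "clamped")
  expect_equal(d, 10)
})

test_that("NJ solves the three-taxon case in closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ is consistent on a known additive four-taxon matrix", {
  gen <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):0);")
  D <- patristicDistances(gen)
  tr <- neighborJoining(D)
  expect_true(bipartitionPresent(tr, c("A", "B")))
  tipLen <- stats::setNames(
    tr$edge.length[tr$edge[, 2] <= 4], tr$tip.label[tr$edge[, 2][tr$edge[, 2] <= 4]])
  expect_equal(tipLen[c("A", "B", "C", "D")],
               c(A = 1, B = 1, C = 1, D = 1), tolerance = 1e-9)
  internal <- tr$edge.length[tr$edge[, 2] > 4 + 1]
  expect_equal(sum(internal), 2, tolerance = 1e-9)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(51)
  for (i in 1:20) {
    gen <- ape::rtree(12)
    D <- patristicDistances(gen)
    est <- neighborJoining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), est)), 0)
    d2 <- patristicDistances(est)[rownames(D), colnames(D)]
    expect_lt(max(abs(d2 - D)), 1e-9)
    ## independent cross-check of the topology against ape's NJ
    expect_equal(as.numeric(ape::dist.topo(ape::nj(D), est)), 0)
  }
})

test_that("NJ validates its input matrix", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighborJoining(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(neighborJoining(D3), "symmetric")
})

test_that("distance pipeline is invariant to row order up to relabeling", {
  scn <- simulateEndosymbiosis(seed = 61)
  aln <- simulateAlignment(scn$tree, 500, seed = 62)
  perm <- sample(seq_along(alnIds(aln)))
  aln2 <- StateAlignment(alnIds(aln)[perm], unname(alnRows(aln))[perm])
  t1 <- njTree(aln)
  t2 <- njTree(aln2)
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("bootstrap saturates at 100 when every column supports one split", {
  set.seed(71)
  colsA <- paste(sample(c("A", "C", "D", "E"), 200, TRUE), collapse = "")
  colsC <- paste(sample(c("F", "G", "H", "I"), 200, TRUE), collapse = "")
  aln <- StateAlignment(c("A", "B", "C", "D"),
                        c(colsA, colsA, colsC, colsC))
  bt <- suppressWarnings(bootstrapSupport(aln, replicates = 100, seed = 5))
  sup <- nodeSupports(bt)
  expect_equal(sup[!is.na(sup)], 100)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("bootstrap is seed-reproducible and quantized at one replicate", {
  scn <- simulateEndosymbiosis(seed = 81)
  aln <- simulateAlignment(scn$tree, 300, seed = 82)
  b1 <- bootstrapSupport(aln, replicates = 20, seed = 9)
  b2 <- bootstrapSupport(aln, replicates = 20, seed = 9)
  expect_identical(writeNewickTree(b1), writeNewickTree(b2))

  b3 <- bootstrapSupport(aln, replicates = 1, seed = 3)
  sup <- nodeSupports(b3)
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("rooting preserves patristic distances", {
  tr <- readNewickTree("(A:1,B:1);")
  expect_equal(rootTree(tr)$edge.length, c(1, 1))

  chain <- readNewickTree("(A:3,B:0);")
  expect_equal(rootTree(chain)$edge.length, c(1.5, 1.5))

  set.seed(91)
  tr <- ape::rtree(10)
  for (mode in c("midpoint", "outgroup")) {
    rooted <- if (mode == "midpoint") rootTree(tr, "midpoint")
              else rootTree(tr, "outgroup", "t1")
    d1 <- patristicDistances(tr)
    d2 <- patristicDistances(rooted)[rownames(d1), colnames(d1)]
    expect_lt(max(abs(d1 - d2)), 1e-9)
  }
  expect_error(
    rootTree(readNewickTree("((A:1,C:1):1,(B:1,D:1):1);"),
             "outgroup", c("A", "B")),
    "bipartition")
})
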