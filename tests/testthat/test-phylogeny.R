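test_that("character matrix encodes presence patterns with Nm all-absent", {
  v <- rbind(
    makeVariants(2, sample_id = "L1", role = "L", pos = c(10, 20)),
    makeVariants(2, sample_id = "G1", role = "G", pos = c(10, 30)),
    makeVariants(1, sample_id = "N1", role = "N", pos = 30))
  bcm <- buildCharacterMatrix(v)
  expect_equal(bcm@taxa, c("Nm", "N", "L", "G"))
  expect_equal(ncol(bcm@mat), 3L)
  shared <- bcm@mat[, grepl(":10:", colnames(bcm@mat))]
  expect_equal(unname(shared), c(0L, 0L, 1L, 1L))
  expect_true(all(bcm@mat["Nm", ] == 0L))
  # duplicate keys collapse
  v2 <- rbind(v, makeVariants(1, sample_id = "L1", role = "L", pos = 10))
  expect_equal(ncol(buildCharacterMatrix(v2)@mat), 3L)
  empty <- buildCharacterMatrix(v[0, ])
  expect_equal(ncol(empty@mat), 0L)
})

test_that("dominant shared signal yields the expected cherry and branch counts", {
  mat <- cbind(matrix(rep(c(0L, 0L, 1L, 1L), 50), nrow = 4),
               matrix(rep(c(0L, 0L, 1L, 0L), 5), nrow = 4),
               matrix(rep(c(0L, 0L, 0L, 1L), 5), nrow = 4))
  rownames(mat) <- c("Nm", "N", "L", "G")
  tr <- parsimonyTree(bcmFromMatrix(mat))
  expect_equal(parsimonyScore(tr), 60)
  expect_equal(tr@nTied, 1L)
  expect_equal(classifyTopology(tr), "TYPE1")
  bc <- branchCounts(tr)   # branch labels follow Nm/N/L/G role order
  expect_equal(unname(bc[["L+G"]]), 50)
  expect_equal(unname(bc[["L"]]), 5)
  expect_equal(unname(bc[["G"]]), 5)
})

test_that("a single character cannot resolve the topology", {
  mat <- matrix(c(0L, 0L, 1L, 1L), nrow = 4,
                dimnames = list(c("Nm", "N", "L", "G"), NULL))
  # {L,G} vs rest: scores 1 on the matching topology, 2 elsewhere: resolved
  tr <- parsimonyTree(bcmFromMatrix(mat))
  expect_equal(tr@nTied, 1L)
  # a private character scores 1 on every topology: tie -> unresolved
  mat2 <- matrix(c(0L, 0L, 1L, 0L), nrow = 4,
                 dimnames = list(c("Nm", "N", "L", "G"), NULL))
  tr2 <- parsimonyTree(bcmFromMatrix(mat2))
  expect_equal(tr2@nTied, 3L)
  expect_equal(classifyTopology(tr2), "UNRESOLVED")
})

test_that("search minimum equals the independent parsimony oracle", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  for (rep in 1:40) {
    nTaxa <- sample(4:5, 1)
    taxa <- c("Nm", "N", "L", "G", "X")[seq_len(nTaxa)]
    nChar <- sample(5:40, 1)
    mat <- matrix(rbinom(nTaxa * nChar, 1, 0.4), nrow = nTaxa,
                  dimnames = list(taxa, NULL))
    tr <- parsimonyTree(bcmFromMatrix(mat))
    dat <- phangorn::phyDat(mat, type = "USER", levels = c(0L, 1L))
    oracle <- min(vapply(phangorn::allTrees(nTaxa, tip.label = taxa),
                         function(t) phangorn::parsimony(t, dat),
                         numeric(1)))
    expect_equal(parsimonyScore(tr), oracle)
  }
})

test_that("tree search is invariant to taxon input order", {
  set.seed(33)
  mat <- matrix(rbinom(4 * 30, 1, 0.4), nrow = 4,
                dimnames = list(c("Nm", "N", "L", "G"), NULL))
  tr1 <- parsimonyTree(bcmFromMatrix(mat))
  perm <- c("G", "Nm", "L", "N")
  tr2 <- parsimonyTree(bcmFromMatrix(mat[perm, ]))
  expect_equal(parsimonyScore(tr1), parsimonyScore(tr2))
  expect_equal(classifyTopology(tr1), classifyTopology(tr2))
})

test_that("topology classification covers the three patterns and exclusions", {
  pat <- list(TYPE1 = c(0L, 0L, 1L, 1L), TYPE2 = c(0L, 1L, 1L, 0L),
              TYPE3 = c(0L, 1L, 0L, 1L))
  for (tt in names(pat)) {
    mat <- matrix(rep(pat[[tt]], 20), nrow = 4,
                  dimnames = list(c("Nm", "N", "L", "G"), NULL))
    expect_equal(classifyTopology(parsimonyTree(bcmFromMatrix(mat))), tt)
  }
  # no normal-gland sample: the direction cannot be resolved
  mat3 <- matrix(rep(c(0L, 1L, 1L), 10), nrow = 3,
                 dimnames = list(c("Nm", "L", "G"), NULL))
  expect_equal(classifyTopology(parsimonyTree(bcmFromMatrix(mat3))),
               "UNRESOLVED")
})

test_that("planted topologies are recovered across simulated cases", {
  hits <- 0L; total <- 0L
  for (tt in c("TYPE1", "TYPE2", "TYPE3")) {
    cfg <- simConfig(nCases = 8L, topologyType = tt, seed = 55L)
    for (i in seq_len(8L)) {
      cb <- simulateCase(cfg, i)
      som <- somaticVariants(variants(cb))
      got <- classifyTopology(parsimonyTree(buildCharacterMatrix(som)))
      hits <- hits + (got == tt); total <- total + 1L
    }
  }
  expect_equal(hits, total)
})

test_that("copy-number event characters produce a concordant tree", {
  ev <- rbind(
    makeEvent(sample_id = "L1", chrom = "chr1", start = 1, end = 1e6),
    makeEvent(sample_id = "G1", chrom = "chr1", start = 1, end = 1e6),
    makeEvent(sample_id = "G1", chrom = "chr2", start = 1, end = 1e6,
              event_type = "LOSS"),
    makeEvent(sample_id = "G1", chrom = "chr3", start = 1, end = 1e6,
              event_type = "LOSS"))
  roles <- c(L1 = "L", G1 = "G", N1 = "N")
  tr <- cnaEventTree(ev, roles)
  expect_equal(classifyTopology(tr), "TYPE1")
  expect_equal(tr@nCharacters, 3L)
  emptyTr <- cnaEventTree(ev[0, ], roles)
  expect_equal(classifyTopology(emptyTr), "UNRESOLVED")
})

test_that("shared VAF comparison reports means and a rank test", {
  v <- rbind(
    makeVariants(20, sample_id = "L1", role = "L", pos = 1:20,
                 alt_reads = 20L),
    makeVariants(20, sample_id = "G1", role = "G", pos = 1:20,
                 alt_reads = 40L))
  sc <- sharedVafComparison(v)
  expect_equal(sc$nShared, 20L)
  expect_equal(sc$meanA, 0.2)
  expect_equal(sc$meanB, 0.4)
  expect_lt(pValue(sc$test), 1e-5)
  # identical collections: equal means, maximal p
  vSame <- v; vSame$alt_reads <- 25L; vSame$vaf <- 0.25
  scSame <- sharedVafComparison(vSame)
  expect_equal(scSame$meanDifference, 0)
  expect_gt(pValue(scSame$test), 0.9)
  expect_error(sharedVafComparison(v[v$role == "L", ]), "no shared")
})

test_that("likelihood cross-check concurs on a clear topology", {
  skip_if_not_installed("phangorn")
  set.seed(8)
  mat <- cbind(matrix(rep(c(0L, 0L, 1L, 1L), 30), nrow = 4),
               matrix(rbinom(4 * 6, 1, 0.3), nrow = 4))
  rownames(mat) <- c("Nm", "N", "L", "G")
  bcm <- bcmFromMatrix(mat)
  pars <- classifyTopology(parsimonyTree(bcm))
  ml <- mlTopologyCheck(bcm)
  expect_equal(pars, "TYPE1")
  expect_equal(ml, "TYPE1")
})
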